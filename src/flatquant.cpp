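#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 8- or 4-connected component labeling of a logical matrix.
// Returns an integer matrix, 0 = background, components numbered from 1
// in raster-scan order of their first pixel (deterministic).
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb(const LogicalMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px, 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_zs_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = nb(img, r - 1, c),     p3 = nb(img, r - 1, c + 1);
          int p4 = nb(img, r, c + 1),     p5 = nb(img, r + 1, c + 1);
          int p6 = nb(img, r + 1, c),     p7 = nb(img, r + 1, c - 1);
          int p8 = nb(img, r, c - 1),     p9 = nb(img, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img[kill[i]] = false;
    }
  }
  // sequential pruning of redundant staircase pixels left by the parallel
  // passes: delete 8-simple, non-endpoint pixels (Yokoi connectivity
  // number C8 == 1); sequential order preserves topology and removes the
  // run-overlap pixels that inflate geodesic length at shallow angles
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!img(r, c)) continue;
        // x1 = E, then counter-clockwise
        int x[9];
        x[1] = nb(img, r, c + 1);     x[2] = nb(img, r - 1, c + 1);
        x[3] = nb(img, r - 1, c);     x[4] = nb(img, r - 1, c - 1);
        x[5] = nb(img, r, c - 1);     x[6] = nb(img, r + 1, c - 1);
        x[7] = nb(img, r + 1, c);     x[8] = nb(img, r + 1, c + 1);
        int B = x[1] + x[2] + x[3] + x[4] + x[5] + x[6] + x[7] + x[8];
        if (B < 2) continue;
        int C8 = 0;
        for (int k = 1; k <= 7; k += 2) {
          int xk = 1 - x[k];
          int xk1 = 1 - x[(k % 8) + 1];
          int xk2 = 1 - x[((k + 1) % 8) + 1];
          C8 += xk - xk * xk1 * xk2;
        }
        if (C8 != 1) continue;
        img(r, c) = false;
        changed = true;
      }
    }
  }
  return img;
}

// Median filter over a disc footprint of given radius (px), reflected edges.
// Matches ImageJ "Median..." semantics: pixel included if
// round(distance) <= radius is the classic ImageJ disc; here we use
// dx^2 + dy^2 <= r^2 which is the standard disc structuring element.
// [[Rcpp::export]]
NumericMatrix median_disc_cpp(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<int> drs, dcs;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius) {
        drs.push_back(dr); dcs.push_back(dc);
      }
  const int k = (int)drs.size();
  std::vector<double> buf(k);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int i = 0; i < k; ++i) {
        int r2 = r + drs[i], c2 = c + dcs[i];
        // reflect (mirror without repeating the border pixel when possible)
        if (r2 < 0) r2 = -r2 - 1; else if (r2 >= nr) r2 = 2 * nr - r2 - 1;
        if (c2 < 0) c2 = -c2 - 1; else if (c2 >= nc) c2 = 2 * nc - c2 - 1;
        if (r2 < 0) r2 = 0;
        if (r2 >= nr) r2 = nr - 1;
        if (c2 < 0) c2 = 0;
        if (c2 >= nc) c2 = nc - 1;
        buf[i] = img(r2, c2);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = 0.5 * (med + lo);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// 8-neighbour degree of every foreground pixel (0 elsewhere).
// [[Rcpp::export]]
IntegerMatrix pixel_degree_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix deg(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int d = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          d += nb(mask, r + dr, c + dc);
        }
      deg(r, c) = d;
    }
  return deg;
}
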
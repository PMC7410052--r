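# Independent brute-force oracles, deliberately naive and separate from the
# package's implementations.

# union-find over an edge list; returns component count among `nodes`
uf_components <- function(edges, nodes) {
  if (length(nodes) == 0) return(0L)
  parent <- seq_len(max(c(nodes, unlist(edges), 1)))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (length(edges)) for (e in edges) {
    a <- find(e[1]); b <- find(e[2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(nodes, find, integer(1))))
}

# union-find component count of a logical matrix under 8-connectivity
uf_mask_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  nr <- nrow(mask)
  edges <- list()
  for (i in idx) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    for (dc in 0:1) for (dr in -1:1) {
      if (dc == 0 && dr != 1) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(mask)) next
      j <- (c2 - 1) * nr + r2
      if (mask[j]) edges[[length(edges) + 1]] <- c(match(i, idx), match(j, idx))
    }
  }
  uf_components(edges, seq_along(idx))
}

# brute-force geodesic length: every 8-adjacent skeleton pixel pair once
brute_length <- function(mask, pixel_size = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  total <- 0
  for (i in seq_len(nrow(idx) - 1)) for (j in (i + 1):nrow(idx)) {
    dr <- abs(idx[i, 1] - idx[j, 1]); dc <- abs(idx[i, 2] - idx[j, 2])
    if (dr <= 1 && dc <= 1) total <- total + if (dr + dc == 2) sqrt(2) else 1
  }
  total * pixel_size
}

# naive per-pixel median over a disc footprint with reflected edges
brute_median_disc <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(v, n) { v <- ifelse(v < 1, 1 - v, v); ifelse(v > n, 2 * n - v + 1, v) }
  out <- img
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- refl(r + offs$dr, nr); cs <- refl(c + offs$dc, nc)
    out[r, c] <- median(img[cbind(rs, cs)])
  }
  out
}

# exhaustive Otsu: maximize between-class variance over 256 candidate cuts
brute_otsu <- function(img) {
  v <- as.vector(img)
  rng <- range(v)
  cuts <- seq(rng[1], rng[2], length.out = 258)[2:257]
  best <- cuts[1]; best_var <- -1
  for (t in cuts) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bv > best_var) { best_var <- bv; best <- t }
  }
  best
}

# rectangle mask helper (axis-aligned bar)
bar_mask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}
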
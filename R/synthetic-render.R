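#' Rendering configuration for synthetic flat-mounts
#'
#' @param pixel_size micrometres per pixel.
#' @param psf_sigma Gaussian point-spread blur, pixels (0 = none).
#' @param background_level baseline intensity on `[0, 1]`.
#' @param channel_gain foreground intensity added on top of background
#'   for the marker channels.
#' @param coliv_gain collagen IV foreground intensity (kept lower than
#'   the other channels so neovascular tufts, rendered near saturation,
#'   stand out by the bright-globular criterion).
#' @param gaussian_noise_sd additive Gaussian noise SD.
#' @param salt_noise_density fraction of pixels set to full scale.
#' @param rng_seed seed; identical seed + config give identical images.
#' @return a list of class `render_config`.
#' @export
render_config <- function(pixel_size = 1, psf_sigma = 0, background_level = 0.05,
                          channel_gain = 0.8, coliv_gain = 0.4,
                          gaussian_noise_sd = 0, salt_noise_density = 0,
                          rng_seed = 1) {
  abort_if(pixel_size <= 0, "pixel_size must be > 0")
  abort_if(gaussian_noise_sd < 0 || salt_noise_density < 0 || psf_sigma < 0,
           "noise and blur parameters must be >= 0")
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_level = background_level, channel_gain = channel_gain,
                 coliv_gain = coliv_gain, gaussian_noise_sd = gaussian_noise_sd,
                 salt_noise_density = salt_noise_density, rng_seed = rng_seed),
            class = "render_config")
}

# rasterize line segments as width-w ribbons (capsule distance <= w/2)
stamp_segments <- function(dim, pixel_size, x0, y0, x1, y1, width) {
  mask <- matrix(FALSE, dim[1], dim[2])
  for (k in seq_along(x0)) {
    hw <- width[k] / 2
    rmin <- max(1L, um_to_px(min(y0[k], y1[k]) - hw, pixel_size) - 1L)
    rmax <- min(dim[1], um_to_px(max(y0[k], y1[k]) + hw, pixel_size) + 1L)
    cmin <- max(1L, um_to_px(min(x0[k], x1[k]) - hw, pixel_size) - 1L)
    cmax <- min(dim[2], um_to_px(max(x0[k], x1[k]) + hw, pixel_size) + 1L)
    if (rmin > rmax || cmin > cmax) next
    ys <- (rmin:rmax - 0.5) * pixel_size
    xs <- (cmin:cmax - 0.5) * pixel_size
    dx <- x1[k] - x0[k]; dy <- y1[k] - y0[k]
    len2 <- dx^2 + dy^2
    px <- outer(rep(1, length(ys)), xs) - x0[k]
    py <- outer(ys, rep(1, length(xs))) - y0[k]
    t <- if (len2 == 0) 0 else pmin(pmax((px * dx + py * dy) / len2, 0), 1)
    d2 <- (px - t * dx)^2 + (py - t * dy)^2
    sub <- mask[rmin:rmax, cmin:cmax, drop = FALSE]
    mask[rmin:rmax, cmin:cmax] <- sub | (d2 <= hw^2)
  }
  mask
}

rasterize_edges <- function(net, idx, dim, pixel_size, extra_width = 0) {
  if (length(idx) == 0) return(matrix(FALSE, dim[1], dim[2]))
  a <- net$nodes[net$edges$from[idx], , drop = FALSE]
  b <- net$nodes[net$edges$to[idx], , drop = FALSE]
  stamp_segments(dim, pixel_size, a[, 1], a[, 2], b[, 1], b[, 2],
                 net$edges$width_um[idx] + extra_width)
}

# cut a gap across a ribbon: clear pixels whose along-branch coordinate
# (from the junction, towards the far node) is in [arc0, arc1] and whose
# perpendicular offset is within the ribbon width
cut_branch_gap <- function(mask, pixel_size, junction_xy, far_xy, arc0, arc1, width) {
  dxy <- far_xy - junction_xy
  len <- sqrt(sum(dxy^2))
  u <- dxy / len
  arc1 <- min(arc1, len)
  if (arc1 <= arc0) return(mask)
  ctr <- junction_xy + u * (arc0 + arc1) / 2
  half_span <- (arc1 - arc0) / 2
  reach <- half_span + width
  rmin <- max(1L, um_to_px(ctr[2] - reach, pixel_size)); rmax <- min(nrow(mask), um_to_px(ctr[2] + reach, pixel_size))
  cmin <- max(1L, um_to_px(ctr[1] - reach, pixel_size)); cmax <- min(ncol(mask), um_to_px(ctr[1] + reach, pixel_size))
  ys <- (rmin:rmax - 0.5) * pixel_size
  xs <- (cmin:cmax - 0.5) * pixel_size
  px <- outer(rep(1, length(ys)), xs) - junction_xy[1]
  py <- outer(ys, rep(1, length(xs))) - junction_xy[2]
  along <- px * u[1] + py * u[2]
  perp <- abs(-px * u[2] + py * u[1])
  cut <- along >= arc0 & along <= arc1 & perp <= width
  sub <- mask[rmin:rmax, cmin:cmax, drop = FALSE]
  mask[rmin:rmax, cmin:cmax] <- sub & !cut
  mask
}

stamp_ellipse <- function(mask, pixel_size, cx, cy, area_px2, ratio = 1.3, angle = 0) {
  a <- sqrt(area_px2 * ratio / pi) # semi-axes in px
  b <- area_px2 / (pi * a)
  reach <- a * pixel_size + 2
  rmin <- max(1L, um_to_px(cy - reach, pixel_size)); rmax <- min(nrow(mask), um_to_px(cy + reach, pixel_size))
  cmin <- max(1L, um_to_px(cx - reach, pixel_size)); cmax <- min(ncol(mask), um_to_px(cx + reach, pixel_size))
  ys <- (rmin:rmax - 0.5) * pixel_size
  xs <- (cmin:cmax - 0.5) * pixel_size
  px <- (outer(rep(1, length(ys)), xs) - cx) / pixel_size
  py <- (outer(ys, rep(1, length(xs))) - cy) / pixel_size
  xr <- px * cos(angle) + py * sin(angle)
  yr <- -px * sin(angle) + py * cos(angle)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  mask[rmin:rmax, cmin:cmax] <- mask[rmin:rmax, cmin:cmax, drop = FALSE] | inside
  mask
}

# irregular globular blob (disc with low-order radial wobble)
stamp_blob <- function(mask, pixel_size, cx, cy, radius_um, wobble = 0.15, phase = 0) {
  reach <- radius_um * (1 + wobble) + 2
  rmin <- max(1L, um_to_px(cy - reach, pixel_size)); rmax <- min(nrow(mask), um_to_px(cy + reach, pixel_size))
  cmin <- max(1L, um_to_px(cx - reach, pixel_size)); cmax <- min(ncol(mask), um_to_px(cx + reach, pixel_size))
  ys <- (rmin:rmax - 0.5) * pixel_size
  xs <- (cmin:cmax - 0.5) * pixel_size
  px <- outer(rep(1, length(ys)), xs) - cx
  py <- outer(ys, rep(1, length(xs))) - cy
  th <- atan2(py, px)
  rr <- radius_um * (1 + wobble * sin(3 * th + phase))
  inside <- px^2 + py^2 <= rr^2
  mask[rmin:rmax, cmin:cmax] <- mask[rmin:rmax, cmin:cmax, drop = FALSE] | inside
  mask
}

# sample points along a set of edges, uniform in length
sample_on_edges <- function(net, idx, n) {
  if (length(idx) == 0 || n == 0)
    return(cbind(x = numeric(0), y = numeric(0)))
  lens <- net$edges$length_um[idx]
  pick <- sample(length(idx), n, replace = TRUE, prob = lens)
  t <- runif(n)
  a <- net$nodes[net$edges$from[idx[pick]], , drop = FALSE]
  b <- net$nodes[net$edges$to[idx[pick]], , drop = FALSE]
  a + t * (b - a)
}

place_nuclei <- function(net, idx, n, min_spacing_um, inside = NULL, pixel_size = 1,
                         max_tries = 40) {
  placed <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(placed) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- sample_on_edges(net, idx, n * 2)
    for (i in seq_len(nrow(cand))) {
      if (nrow(placed) >= n) break
      p <- cand[i, ]
      if (!is.null(inside)) {
        r <- um_to_px(p[2], pixel_size); c <- um_to_px(p[1], pixel_size)
        if (r > nrow(inside) || c > ncol(inside) || !inside[r, c]) next
      }
      if (nrow(placed) > 0 &&
          min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) < min_spacing_um^2) next
      placed <- rbind(placed, p)
    }
  }
  placed
}

#' Render a synthetic network into a noisy multi-channel flat-mount
#'
#' Rasterizes edges as width-w ribbons into the canonical OIR staining
#' channels: `coliv` covers all edges (basement-membrane sleeves
#' persist after regression), `pecam` only `ec_present` edges, `icam`
#' EC edges with per-class junction gaps for closed side branches,
#' `lectin` only perfused EC edges. Adds `fli1` nuclei (non-overlapping
#' ellipses), a `phh3` subset, `casp3` apoptotic nuclei, a `pimo`
#' hypoxia field whose supra-threshold area over the central region
#' hits the requested fraction by construction, and bright globular
#' tufts on `coliv`. PSF blur and noise are applied last; intensities
#' are quantized to 16 bits.
#'
#' @param net a `vessel_network`.
#' @param extras list of cellular/field parameters: `n_nuclei`,
#'   `nucleus_area_px`, `n_distractors`, `distractor_area_px`,
#'   `prolif_fraction`, `n_apoptotic`, `hypoxic_fraction`, `n_tufts`,
#'   `tuft_radius_um`, `gap_tolerance_um`.
#' @param config a [render_config()].
#' @return a list of class `flatmount_sim`: `image` ([flatmount_image]),
#'   `truth` (`ground_truth`), `regions` ([region_set]), `masks`
#'   (noise-free ground-truth rasters), `nuclei` (tibble of planted
#'   nuclei).
#' @export
render_flatmount <- function(net, extras = list(), config = render_config()) {
  stopifnot(inherits(net, "vessel_network"))
  ex <- modifyList(list(n_nuclei = 120, nucleus_area_px = 64, n_distractors = 0,
                        distractor_area_px = 16, prolif_fraction = 0.2,
                        n_apoptotic = 12, hypoxic_fraction = 0.4, n_tufts = 0,
                        tuft_radius_um = 15, gap_tolerance_um = 5), extras)
  ps <- config$pixel_size
  field <- net$field_size_um
  dim <- rep(as.integer(round(field / ps)), 2)
  e <- net$edges

  masks <- list(
    coliv = rasterize_edges(net, seq_len(nrow(e)), dim, ps),
    pecam = rasterize_edges(net, which(e$ec_present), dim, ps),
    lectin = rasterize_edges(net, which(e$perfused & e$ec_present), dim, ps))
  icam <- rasterize_edges(net, which(e$ec_present), dim, ps)
  # junction-class ICAM2 gap geometry for closed side branches; gaps sit
  # beyond the artery half-width so they are visible outside the parent ribbon
  sb <- net$side_branches
  if (!is.null(sb) && nrow(sb)) {
    tol <- ex$gap_tolerance_um
    for (i in seq_len(nrow(sb))) {
      st <- sb$state[i]
      if (!st %in% c("disrupted", "detached")) next
      jn <- net$nodes[sb$junction_node[i], ]
      far <- net$nodes[other_end(e, sb$edge[i], sb$junction_node[i]), ]
      w <- e$width_um[sb$edge[i]]
      aw <- if (any(e$is_artery)) max(e$width_um[e$is_artery]) else 0
      off <- aw / 2 + 1
      if (st == "detached") {
        icam <- cut_branch_gap(icam, ps, jn, far, off, off + 2 * tol, w)
      } else {
        icam <- cut_branch_gap(icam, ps, jn, far, off, off + 0.5 * tol, w)
        icam <- cut_branch_gap(icam, ps, jn, far, off + 0.5 * tol + 3.5,
                               off + tol + 3.5, w)
      }
    }
  }
  masks$icam <- icam

  regions <- make_annulus_regions(dim, ps, r_central = 0.30 * field,
                                  r_whole = 0.48 * field)
  regions$regions$field <- matrix(TRUE, dim[1], dim[2])
  regions$arteries <- lapply(net$arteries, function(p)
    polyline_to_px(net$nodes[p, , drop = FALSE], ps))

  truth <- network_truth(net)
  withr::with_seed(config$rng_seed, {
    ec_idx <- which(e$ec_present)
    diam <- 2 * sqrt(ex$nucleus_area_px / pi) * ps
    nuc <- place_nuclei(net, ec_idx, ex$n_nuclei, 2 * diam)
    fli1 <- matrix(FALSE, dim[1], dim[2])
    if (nrow(nuc)) for (i in seq_len(nrow(nuc)))
      fli1 <- stamp_ellipse(fli1, ps, nuc[i, 1], nuc[i, 2], ex$nucleus_area_px,
                            angle = runif(1, 0, pi))
    distract <- place_nuclei(net, ec_idx, ex$n_distractors, 2 * diam)
    if (nrow(distract)) for (i in seq_len(nrow(distract)))
      fli1 <- stamp_ellipse(fli1, ps, distract[i, 1], distract[i, 2],
                            ex$distractor_area_px, angle = runif(1, 0, pi))
    n_prolif <- round(ex$prolif_fraction * nrow(nuc))
    phh3 <- matrix(FALSE, dim[1], dim[2])
    prolif_idx <- if (nrow(nuc)) sample(nrow(nuc), n_prolif) else integer(0)
    for (i in prolif_idx)
      phh3 <- stamp_ellipse(phh3, ps, nuc[i, 1], nuc[i, 2], ex$nucleus_area_px)
    # apoptotic ECs: extra caspase-3+ cells on vessels inside the central region
    ec_central <- ec_idx
    apo <- place_nuclei(net, ec_central, ex$n_apoptotic, 2 * diam,
                        inside = regions$regions$central, pixel_size = ps)
    casp3 <- matrix(FALSE, dim[1], dim[2])
    if (nrow(apo)) for (i in seq_len(nrow(apo)))
      casp3 <- stamp_ellipse(casp3, ps, apo[i, 1], apo[i, 2], ex$nucleus_area_px)

    # hypoxia: Gaussian-bump field thresholded at the quantile that hits
    # the requested central-region area fraction
    hyp <- hypoxia_mask(dim, ps, regions$regions$central, ex$hypoxic_fraction)

    # neovascular tufts: bright globular blobs in the periphery
    tufts <- matrix(FALSE, dim[1], dim[2])
    if (ex$n_tufts > 0) {
      ring <- which(regions$regions$peripheral, arr.ind = TRUE)
      pick <- ring[sample(nrow(ring), ex$n_tufts), , drop = FALSE]
      for (i in seq_len(ex$n_tufts))
        tufts <- stamp_blob(tufts, ps, (pick[i, 2] - 0.5) * ps,
                            (pick[i, 1] - 0.5) * ps, ex$tuft_radius_um,
                            phase = runif(1, 0, 2 * pi))
    }

    bg <- config$background_level; g <- config$channel_gain
    coliv_chan <- bg + config$coliv_gain * masks$coliv
    coliv_chan[tufts] <- 1
    chans <- list(
      pecam = bg + g * masks$pecam,
      coliv = coliv_chan,
      icam = bg + g * masks$icam,
      lectin = bg + g * masks$lectin,
      fli1 = bg + g * fli1,
      phh3 = bg + g * phh3,
      casp3 = bg + g * casp3,
      pimo = bg + 0.75 * hyp$soft)
    chans <- lapply(chans, function(m) {
      m <- matrix(pmin(pmax(m, 0), 1), dim[1], dim[2])
      if (config$psf_sigma > 0) m <- EBImage::gblur(m, sigma = config$psf_sigma)
      if (config$gaussian_noise_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, config$gaussian_noise_sd), dim[1], dim[2])
      if (config$salt_noise_density > 0) {
        ns <- rbinom(1, length(m), config$salt_noise_density)
        if (ns > 0) m[sample(length(m), ns)] <- 1
      }
      matrix(round(pmin(pmax(m, 0), 1) * 65535) / 65535, dim[1], dim[2])
    })
  })

  truth$n_nuclei <- nrow(nuc)
  truth$n_proliferating <- length(prolif_idx)
  truth$n_apoptotic <- nrow(apo)
  truth$hypoxic_fraction <- hyp$fraction
  truth$tuft_area_um2 <- sum(tufts) * ps^2
  masks$tufts <- tufts
  masks$hypoxia <- hyp$mask
  masks$fli1 <- fli1

  img <- flatmount_image(chans, ps,
                         metadata = list(synthetic = TRUE, seed = config$rng_seed))
  structure(list(image = img, truth = truth, regions = regions, masks = masks,
                 nuclei = tibble(x = nuc[, 1], y = nuc[, 2],
                                 proliferating = seq_len(nrow(nuc)) %in% prolif_idx),
                 config = config, extras = ex),
            class = "flatmount_sim")
}

hypoxia_mask <- function(dim, pixel_size, central, fraction, n_bumps = 5) {
  if (fraction <= 0)
    return(list(mask = matrix(FALSE, dim[1], dim[2]),
                soft = matrix(0, dim[1], dim[2]), fraction = 0))
  ctr_px <- which(central, arr.ind = TRUE)
  rc <- colMeans(ctr_px)
  rad <- sqrt(sum(central) / pi) # px
  f <- matrix(0, dim[1], dim[2])
  rows <- row(f); cols <- col(f)
  for (i in seq_len(n_bumps)) {
    th <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.7 * rad
    cy <- rc[1] + rr * sin(th); cx <- rc[2] + rr * cos(th)
    sig <- runif(1, 0.35, 0.6) * rad
    f <- f + runif(1, 0.5, 1) * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * sig^2))
  }
  if (fraction >= 1) {
    mask <- matrix(TRUE, dim[1], dim[2])
  } else {
    thr <- quantile(f[central], 1 - fraction, names = FALSE, type = 7)
    mask <- f >= thr
  }
  soft <- EBImage::gblur(mask * 1, sigma = 2)
  list(mask = mask, soft = soft, fraction = sum(mask & central) / sum(central))
}

polyline_to_px <- function(xy, pixel_size) {
  if (nrow(xy) < 2) return(cbind(row = integer(0), col = integer(0)))
  pts <- list()
  for (k in seq_len(nrow(xy) - 1)) {
    a <- xy[k, ]; b <- xy[k + 1, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / (0.5 * pixel_size)))
    t <- seq(0, 1, length.out = n)
    pts[[k]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  p <- do.call(rbind, pts)
  rc <- cbind(row = um_to_px(p[, 2], pixel_size), col = um_to_px(p[, 1], pixel_size))
  rc[!duplicated(rc), , drop = FALSE]
}

#' @export
print.flatmount_sim <- function(x, ...) {
  cat("<flatmount_sim>\n  ")
  print(x$image)
  t <- x$truth
  cat(sprintf("  truth: regression %.3f, %d EC component(s), %d nuclei, hypoxic %.3f\n",
              t$regression_fraction, t$n_components, t$n_nuclei, t$hypoxic_fraction))
  invisible(x)
}
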
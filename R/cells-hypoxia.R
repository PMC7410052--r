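particle_table <- function(mask, pixel_size, channels = list()) {
  lab <- cc_label_cpp(mask, 8L)
  n <- max(lab)
  if (n == 0) {
    return(tibble(particle = integer(0), area_px2 = numeric(0),
                  area_um2 = numeric(0), row = numeric(0), col = numeric(0)))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  rr <- (idx - 1) %% nrow(mask) + 1
  cc <- (idx - 1) %/% nrow(mask) + 1
  out <- tibble(
    particle = seq_len(n),
    area_px2 = tabulate(l, n),
    row = vapply(split(rr, l), mean, numeric(1)),
    col = vapply(split(cc, l), mean, numeric(1)))
  out$area_um2 <- out$area_px2 * pixel_size^2
  for (nm in names(channels)) {
    v <- channels[[nm]][idx]
    out[[paste0("mean_", nm)]] <- vapply(split(v, l), mean, numeric(1))
  }
  attr(out, "labels") <- lab
  out
}

#' Count endothelial nuclei
#'
#' The particle-analysis nucleus count: median filter (radius 2),
#' despeckle, threshold, 8-connected particle labeling, then keep
#' particles strictly larger than `min_area_px` whose centroid lies on
#' the (2 px dilated) vessel mask.
#'
#' @param nuclear_channel FLI1/ERG intensity matrix.
#' @param vessel_mask endothelial mask (matrix or [binary_mask]); nuclei
#'   outside it are not endothelial and are excluded. `NULL` disables
#'   the containment test.
#' @param min_area_px particle-area floor in square pixels (strict `>`).
#' @param pixel_size micrometres per pixel.
#' @param threshold manual threshold; default Otsu.
#' @param extra_channels named list of intensity matrices whose mean
#'   per particle is recorded (e.g. pHH3 for [proliferation_fraction()]).
#' @return list with `count` and `particles` (tibble).
#' @export
count_nuclei <- function(nuclear_channel, vessel_mask = NULL, min_area_px = 20,
                         pixel_size = 1, threshold = NULL, extra_channels = list()) {
  img <- despeckle(median_filter(nuclear_channel, 2))
  bm <- if (is.null(threshold)) binarize(img, "otsu", pixel_size = pixel_size)
        else binarize(img, "manual", value = threshold, pixel_size = pixel_size)
  parts <- particle_table(bm$pixels, pixel_size,
                          channels = c(list(nuclear = nuclear_channel), extra_channels))
  keep <- parts$area_px2 > min_area_px
  if (!is.null(vessel_mask)) {
    vm <- dilate_px(as_logical_matrix(vessel_mask), 2)
    inside <- vm[cbind(pmin(pmax(round(parts$row), 1), nrow(vm)),
                       pmin(pmax(round(parts$col), 1), ncol(vm)))]
    keep <- keep & inside
  }
  particles <- parts[keep, , drop = FALSE]
  attr(particles, "labels") <- attr(parts, "labels")
  list(count = nrow(particles), particles = particles)
}

#' Fraction of proliferating (pHH3+) endothelial nuclei
#'
#' Nuclei are positive when their mean pHH3 intensity exceeds the
#' threshold (default: Otsu over the per-nucleus mean intensities).
#'
#' @param phh3_channel pHH3 intensity matrix.
#' @param nuclei particle tibble from [count_nuclei()] (its `labels`
#'   attribute is used to average pHH3 over each nucleus footprint).
#' @param positivity_threshold manual threshold on mean intensity.
#' @return fraction in `[0, 1]`.
#' @export
proliferation_fraction <- function(phh3_channel, nuclei, positivity_threshold = NULL) {
  particles <- if (is.list(nuclei) && !is.data.frame(nuclei)) nuclei$particles else nuclei
  abort_if(nrow(particles) == 0, "no nuclei to score")
  lab <- attr(particles, "labels")
  abort_if(is.null(lab), "particle table lacks its label matrix")
  idx <- which(lab > 0)
  l <- lab[idx]
  sel <- l %in% particles$particle
  means <- vapply(split(phh3_channel[idx][sel], l[sel]), mean, numeric(1))
  means <- means[as.character(particles$particle)]
  thr <- positivity_threshold
  if (is.null(thr)) {
    if (var(means) == 0) return(0) # no signal contrast: nothing scored positive
    thr <- otsu_threshold(matrix(means, nrow = 1))
  }
  mean(means > thr)
}

#' Apoptotic-EC density
#'
#' Active caspase-3 particles (same filter/threshold/size recipe as
#' nuclei) that overlap the endothelial mask and whose centroid is
#' enclosed by collagen IV (centroid inside the 1-px-closed collagen IV
#' mask), normalized to region area.
#'
#' @param casp3_channel active caspase-3 intensity matrix.
#' @param ec_mask endothelial mask.
#' @param coliv_mask collagen IV mask.
#' @param region normalization region (mask or [region_set], `central`).
#' @param min_area_px particle-area floor (strict `>`).
#' @param pixel_size micrometres per pixel.
#' @param threshold manual threshold; default Otsu.
#' @return list with `count`, `density_per_mm2`, `particles`.
#' @export
count_apoptotic_ecs <- function(casp3_channel, ec_mask, coliv_mask, region,
                                min_area_px = 20, pixel_size = 1, threshold = NULL) {
  r <- region_mask(region)
  abort_if(!any(r), "region is empty")
  img <- despeckle(median_filter(casp3_channel, 2))
  bm <- if (is.null(threshold)) binarize(img, "otsu", pixel_size = pixel_size)
        else binarize(img, "manual", value = threshold, pixel_size = pixel_size)
  parts <- particle_table(bm$pixels, pixel_size)
  lab <- attr(parts, "labels")
  ec <- as_logical_matrix(ec_mask)
  cv_closed <- close_px(as_logical_matrix(coliv_mask), 1)
  keep <- logical(nrow(parts))
  for (i in seq_len(nrow(parts))) {
    if (parts$area_px2[i] <= min_area_px) next
    foot <- lab == parts$particle[i]
    ctr <- cbind(pmin(pmax(round(parts$row[i]), 1), nrow(ec)),
                 pmin(pmax(round(parts$col[i]), 1), ncol(ec)))
    keep[i] <- any(foot & ec) && cv_closed[ctr] && r[ctr]
  }
  particles <- parts[keep, , drop = FALSE]
  area_mm2 <- sum(r) * pixel_size^2 / 1e6
  list(count = nrow(particles), density_per_mm2 = nrow(particles) / area_mm2,
       particles = particles)
}

#' Hypoxic-area fraction
#'
#' Pimonidazole channel: median filter (radius 20 px), threshold
#' (manual or Otsu), area of supra-threshold signal inside the region
#' over region area.
#'
#' @param pimo_channel pimonidazole intensity matrix.
#' @param region region (mask or [region_set], `central`).
#' @param threshold manual threshold; default Otsu. A degenerate
#'   (constant) filtered channel yields an empty mask.
#' @param pixel_size micrometres per pixel.
#' @param median_radius_px pre-threshold median filter radius.
#' @return fraction in `[0, 1]`.
#' @export
hypoxic_area_fraction <- function(pimo_channel, region, threshold = NULL,
                                  pixel_size = 1, median_radius_px = 20) {
  r <- region_mask(region)
  abort_if(!any(r), "region is empty")
  img <- median_filter(pimo_channel, median_radius_px)
  bm <- if (is.null(threshold)) binarize(img, "otsu", pixel_size = pixel_size)
        else binarize(img, "manual", value = threshold, pixel_size = pixel_size)
  sum(bm$pixels & r) / sum(r)
}

poly_area <- function(x, y) abs(sum(x * (c(y[-1], y[1])) - c(x[-1], x[1]) * y)) / 2

component_solidity <- function(idx, nr) {
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  # hull over pixel corners so single pixels get area 1
  xs <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  ys <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  h <- grDevices::chull(xs, ys)
  length(idx) / poly_area(xs[h], ys[h])
}

#' Neovascular tuft area fraction
#'
#' Neovascular lesions image as bright, globular collagen IV-positive
#' structures. Candidates are pixels brighter than `intensity_factor`
#' times the median collagen IV intensity over the normal vessel mask;
#' connected candidates are kept as lesions when they are large enough
#' and solid (convex) enough to be globular rather than ribbon- or
#' network-shaped.
#'
#' @param coliv_channel collagen IV intensity matrix.
#' @param vessel_mask normal-vessel mask used for the reference median.
#' @param region normalization region (mask or [region_set], `whole`).
#' @param pixel_size micrometres per pixel.
#' @param intensity_factor brightness multiple of the vessel median.
#' @param min_area_um2 minimum lesion area.
#' @param min_solidity minimum area/convex-hull-area ratio.
#' @return list with `fraction`, `total_area_um2` and `lesions` tibble.
#' @export
neovascular_area <- function(coliv_channel, vessel_mask, region, pixel_size = 1,
                             intensity_factor = 2, min_area_um2 = 100,
                             min_solidity = 0.85) {
  r <- region_mask(region, "whole")
  abort_if(!any(r), "region is empty")
  vm <- as_logical_matrix(vessel_mask)
  ref <- median(coliv_channel[vm])
  cand <- coliv_channel > intensity_factor * ref
  lab <- cc_label_cpp(cand, 8L)
  n <- max(lab)
  lesions <- list()
  if (n > 0) {
    splits <- split(which(lab > 0), lab[lab > 0])
    for (k in names(splits)) {
      idx <- splits[[k]]
      area <- length(idx) * pixel_size^2
      if (area < min_area_um2) next
      sol <- component_solidity(idx, nrow(cand))
      if (sol < min_solidity) next
      lesions[[length(lesions) + 1]] <-
        tibble(lesion = as.integer(k), area_um2 = area, solidity = sol)
    }
  }
  lesions <- if (length(lesions)) dplyr::bind_rows(lesions) else
    tibble(lesion = integer(0), area_um2 = numeric(0), solidity = numeric(0))
  total <- sum(lesions$area_um2)
  list(fraction = total / (sum(r) * pixel_size^2), total_area_um2 = total,
       lesions = lesions)
}
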
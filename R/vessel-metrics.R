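dilate_px <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  EBImage::dilate(mask * 1, k) > 0
}

erode_px <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  EBImage::erode(mask * 1, k) > 0
}

close_px <- function(mask, r) erode_px(dilate_px(mask, r), r)

region_mask <- function(region, which = "central") {
  if (inherits(region, "region_set")) return(region$regions[[which]])
  as_logical_matrix(region)
}

#' Vessel area fraction of a region
#'
#' Vessel-mask area inside the region divided by region area.
#'
#' @param vessel_mask logical matrix or [binary_mask].
#' @param region logical matrix, [binary_mask], or [region_set] (its
#'   `central` region is used).
#' @return unitless fraction in `[0, 1]`.
#' @export
vessel_area_fraction <- function(vessel_mask, region) {
  v <- as_logical_matrix(vessel_mask)
  r <- region_mask(region)
  abort_if(!any(r), "region is empty")
  sum(v & r) / sum(r)
}

#' Vessel regression ratio from endothelial and basement-membrane masks
#'
#' Regressed vessel segments retain their collagen IV basement-membrane
#' sleeve after losing endothelial (PECAM1) signal. The regressing mask
#' is the collagen IV mask minus the (1 px dilated) endothelial mask;
#' both the regressing mask and the collagen IV mask are skeletonized
#' independently and the ratio of their skeleton lengths taken:
#' `regressing_over_coliv = L(regressing) / L(coliv)` and
#' `ec_over_coliv = 1 - regressing_over_coliv`, both clamped to
#' `[0, 1]`. The dilation suppresses 1-px registration slivers along
#' intact vessels.
#'
#' Thinning erodes every free mask end by about the local vessel
#' half-width, and the subtraction itself cuts each sleeve fragment
#' back by the EC cap plus the dilation, so a naive length ratio is
#' biased low in proportion to how fragmented the regressing mask is.
#' The regressing length is therefore end-corrected: each skeleton
#' endpoint adds back the local mask radius (distance transform), and
#' endpoints abutting the EC mask additionally add the EC-side cap
#' radius and the dilation. The correction is computed from the masks
#' themselves and involves no tuned constants.
#'
#' @param ec_mask endothelial-marker mask (PECAM1, or ICAM2 via
#'   [icam_regression_ratio()]).
#' @param coliv_mask collagen IV mask.
#' @param region optional region restriction (mask or [region_set]).
#' @param pixel_size micrometres per pixel.
#' @param dilate_ec_px pre-subtraction dilation of the EC mask, pixels.
#' @return tibble with `ec_over_coliv`, `regressing_over_coliv`,
#'   `coliv_length_um`, `regressing_length_um`.
#' @export
regression_ratio <- function(ec_mask, coliv_mask, region = NULL,
                             pixel_size = NULL, dilate_ec_px = 1) {
  if (is.null(pixel_size) && inherits(coliv_mask, "binary_mask"))
    pixel_size <- coliv_mask$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1
  ec <- as_logical_matrix(ec_mask)
  cv <- as_logical_matrix(coliv_mask)
  if (!is.null(region)) {
    r <- region_mask(region)
    ec <- ec & r; cv <- cv & r
  }
  ec_dil <- if (dilate_ec_px > 0) dilate_px(ec, dilate_ec_px) else ec
  regressing <- cv & !ec_dil
  l_cv <- total_length(skeletonize(cv, pixel_size))
  abort_if(l_cv == 0, "zero collagen IV skeleton length: ratio undefined")
  skr <- skeletonize(regressing, pixel_size)
  l_reg <- total_length(skr)
  if (any(regressing)) {
    dt <- EBImage::distmap(regressing)
    endpoints <- which(skr$pixels & skr$degree <= 1)
    if (length(endpoints)) {
      near_ec <- dilate_px(ec_dil, dilate_ec_px + 2)
      cap <- dt[endpoints] +
        ifelse(near_ec[endpoints], dt[endpoints] + dilate_ec_px, 0)
      l_reg <- l_reg + sum(cap) * pixel_size
    }
  }
  reg <- min(max(l_reg / l_cv, 0), 1)
  tibble(ec_over_coliv = 1 - reg, regressing_over_coliv = reg,
         coliv_length_um = l_cv, regressing_length_um = l_reg)
}

#' ICAM2/collagen IV regression ratio
#'
#' Identical construction to [regression_ratio()] with the luminal
#' marker ICAM2 in place of PECAM1, measuring lumen loss rather than
#' endothelial loss.
#'
#' @inheritParams regression_ratio
#' @param icam_mask ICAM2 mask.
#' @return tibble as in [regression_ratio()].
#' @export
icam_regression_ratio <- function(icam_mask, coliv_mask, region = NULL,
                                  pixel_size = NULL, dilate_ec_px = 1) {
  regression_ratio(icam_mask, coliv_mask, region, pixel_size, dilate_ec_px)
}

#' Network fragmentation index
#'
#' Number of separate, independent vessel skeletons per mm^2 of region:
#' the image-side measure of how far a once-connected plexus has broken
#' into isolated fragments.
#'
#' @param vessel_mask logical matrix or [binary_mask].
#' @param region region restriction and normalization area.
#' @param pixel_size micrometres per pixel.
#' @param min_length_um minimum skeleton length counted (default 5 um).
#' @return skeletons per mm^2.
#' @export
fragmentation_index <- function(vessel_mask, region, pixel_size = NULL,
                                min_length_um = 5) {
  if (is.null(pixel_size) && inherits(vessel_mask, "binary_mask"))
    pixel_size <- vessel_mask$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1
  v <- as_logical_matrix(vessel_mask)
  r <- region_mask(region)
  abort_if(!any(r), "region is empty")
  sk <- skeletonize(v & r, pixel_size)
  n <- count_components(sk, min_length_um)
  n / (sum(r) * pixel_size^2 / 1e6)
}

#' Branch-point density
#'
#' Skeleton junctions (degree >= 3, merged) per mm^2 of region.
#'
#' @inheritParams fragmentation_index
#' @return branch points per mm^2.
#' @export
branch_density <- function(vessel_mask, region, pixel_size = NULL) {
  if (is.null(pixel_size) && inherits(vessel_mask, "binary_mask"))
    pixel_size <- vessel_mask$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1
  v <- as_logical_matrix(vessel_mask)
  r <- region_mask(region)
  abort_if(!any(r), "region is empty")
  sk <- skeletonize(v & r, pixel_size)
  count_branch_points(sk) / (sum(r) * pixel_size^2 / 1e6)
}

#' Mean vessel width
#'
#' Total vessel area divided by total skeleton length within the
#' region: the standard area-over-centerline-length width estimate.
#'
#' @inheritParams fragmentation_index
#' @return mean width in micrometres.
#' @export
mean_vessel_width <- function(vessel_mask, region = NULL, pixel_size = NULL) {
  if (is.null(pixel_size) && inherits(vessel_mask, "binary_mask"))
    pixel_size <- vessel_mask$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1
  v <- as_logical_matrix(vessel_mask)
  if (!is.null(region)) v <- v & region_mask(region)
  l <- total_length(skeletonize(v, pixel_size))
  abort_if(l == 0, "zero skeleton length: width undefined")
  (sum(v) * pixel_size^2) / l
}

#' Vaso-obliterated (avascular) area fraction
#'
#' Fraction of the region not covered by vasculature at the capillary
#' scale: the vessel mask is morphologically closed with a disc of
#' `closing_radius_um` (default 25 um, about one capillary mesh), so
#' normal intercapillary spaces close up and only genuinely avascular
#' zones remain in the complement.
#'
#' @param vessel_mask logical matrix or [binary_mask].
#' @param region normalization region (typically the whole retina).
#' @param pixel_size micrometres per pixel.
#' @param closing_radius_um closing radius in micrometres.
#' @return avascular fraction in `[0, 1]`.
#' @export
vaso_obliterated_area <- function(vessel_mask, region, pixel_size = NULL,
                                  closing_radius_um = 25) {
  if (is.null(pixel_size) && inherits(vessel_mask, "binary_mask"))
    pixel_size <- vessel_mask$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1
  v <- as_logical_matrix(vessel_mask)
  r <- region_mask(region, "whole")
  abort_if(!any(r), "region is empty")
  closed <- close_px(v, max(1L, as.integer(round(closing_radius_um / pixel_size))))
  sum(r & !closed) / sum(r)
}

#' All vessel metrics for one mask/region pair
#'
#' Convenience wrapper returning one tidy row per region with the
#' standard central-retina vessel metrics.
#'
#' @param ec_mask,coliv_mask endothelial and collagen IV masks.
#' @param regions a [region_set].
#' @param pixel_size micrometres per pixel.
#' @param region_names regions to measure.
#' @param min_length_um fragment-length floor for fragmentation.
#' @return tibble, one row per region.
#' @export
vessel_metrics <- function(ec_mask, coliv_mask, regions, pixel_size = NULL,
                           region_names = "central", min_length_um = 5) {
  if (is.null(pixel_size)) pixel_size <- regions$pixel_size
  purrr::map_dfr(region_names, function(rn) {
    r <- regions$regions[[rn]]
    rr <- regression_ratio(ec_mask, coliv_mask, r, pixel_size)
    tibble(
      region = rn,
      vessel_area_fraction = vessel_area_fraction(ec_mask, r),
      ec_over_coliv = rr$ec_over_coliv,
      regressing_over_coliv = rr$regressing_over_coliv,
      fragmentation_index = fragmentation_index(ec_mask, r, pixel_size, min_length_um),
      branch_density = branch_density(ec_mask, r, pixel_size),
      mean_vessel_width = tryCatch(mean_vessel_width(ec_mask, r, pixel_size),
                                   error = function(e) NA_real_))
  })
}
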
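#' Calibrated multi-channel flat-mount image
#'
#' Container for a set of co-registered 2D intensity channels (maximum
#' intensity projections), an isotropic pixel size in micrometres, and
#' free-form metadata. All channels must share dimensions; channel names
#' must be unique.
#'
#' @param channels named list of numeric matrices (intensities; any range).
#' @param pixel_size micrometres per pixel (> 0, isotropic).
#' @param metadata optional named list (sample id, condition, seed, ...).
#' @return an object of class `flatmount_image`.
#' @export
flatmount_image <- function(channels, pixel_size, metadata = list()) {
  abort_if(!is.list(channels) || length(channels) == 0, "channels must be a non-empty named list")
  nms <- names(channels)
  abort_if(is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms) > 0,
           "channel names must be unique and non-empty")
  dims <- lapply(channels, dim)
  abort_if(!all(vapply(channels, is.matrix, logical(1))), "each channel must be a matrix")
  abort_if(length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1,
           "all channels must share identical dimensions")
  abort_if(!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0,
           "pixel_size must be a single positive number")
  structure(list(channels = channels, pixel_size = pixel_size, metadata = metadata),
            class = "flatmount_image")
}

#' @export
print.flatmount_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<flatmount_image> %d x %d px @ %.3g um/px, %d channel(s): %s\n",
              d[1], d[2], x$pixel_size, length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.flatmount_image <- function(x) dim(x$channels[[1]])

#' Binary mask with segmentation provenance
#'
#' @param pixels logical matrix (TRUE = foreground).
#' @param pixel_size micrometres per pixel.
#' @param recipe list of segmentation steps that produced the mask.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size, recipe = list()) {
  abort_if(!is.matrix(pixels), "pixels must be a matrix")
  if (!is.logical(pixels)) pixels <- pixels > 0
  structure(list(pixels = pixels, pixel_size = pixel_size, recipe = recipe),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px @ %.3g um/px, %d fg px, %d recipe step(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(x$pixels), length(x$recipe)))
  invisible(x)
}

#' Named region-of-interest masks plus artery centerlines
#'
#' Regions are logical masks named `central`, `peripheral` and `whole`
#' (additional names are allowed). Artery centerlines are ordered pixel
#' paths, one matrix of (row, col) per artery.
#'
#' @param regions named list of logical matrices.
#' @param arteries list of 2-column integer matrices (row, col), ordered
#'   from the optic-nerve end outward.
#' @param pixel_size micrometres per pixel.
#' @return an object of class `region_set`.
#' @export
region_set <- function(regions, arteries = list(), pixel_size) {
  abort_if(!is.list(regions) || is.null(names(regions)), "regions must be a named list")
  regions <- lapply(regions, function(m) { if (!is.logical(m)) m <- m > 0; m })
  if (all(c("central", "peripheral") %in% names(regions))) {
    abort_if(any(regions$central & regions$peripheral),
             "central and peripheral regions must be disjoint")
  }
  if (all(c("central", "whole") %in% names(regions))) {
    abort_if(any(regions$central & !regions$whole),
             "central region must lie inside the whole-retina region")
  }
  structure(list(regions = regions, arteries = arteries, pixel_size = pixel_size),
            class = "region_set")
}

#' Concentric disc/annulus regions
#'
#' The paper-style central/peripheral demarcation is not algorithmically
#' defined for real retinas, so regions may be supplied as masks or
#' generated as concentric discs: `central` is a disc of `r_central`,
#' `peripheral` the annulus out to `r_whole`, `whole` their union.
#'
#' @param dim image dimensions, c(rows, cols).
#' @param pixel_size micrometres per pixel.
#' @param center disc centre (row, col) in pixels; default image centre.
#' @param r_central,r_whole radii in micrometres.
#' @return a [region_set].
#' @export
make_annulus_regions <- function(dim, pixel_size, r_central, r_whole,
                                 center = (dim + 1) / 2) {
  abort_if(r_central >= r_whole, "r_central must be smaller than r_whole")
  rr <- (row(matrix(0, dim[1], dim[2])) - center[1]) * pixel_size
  cc <- (col(matrix(0, dim[1], dim[2])) - center[2]) * pixel_size
  d2 <- rr^2 + cc^2
  central <- d2 <= r_central^2
  whole <- d2 <= r_whole^2
  region_set(list(central = central, peripheral = whole & !central, whole = whole),
             pixel_size = pixel_size)
}

#' Read a multi-page TIFF as a flat-mount image
#'
#' Channel names come from `channel_map` (one name per page, in page
#' order) or, if omitted, from the JSON sidecar written by
#' [write_flatmount()]. Pixel size must be given explicitly or found in
#' the sidecar: the analysis never guesses calibration.
#'
#' @param path TIFF path.
#' @param channel_map character vector of channel names, one per page.
#' @param pixel_size micrometres per pixel; overrides the sidecar value.
#' @return a [flatmount_image].
#' @export
read_flatmount <- function(path, channel_map = NULL, pixel_size = NULL) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  if (is.null(channel_map)) channel_map <- meta$channels
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  abort_if(is.null(channel_map), "no channel_map given and no sidecar channel list found")
  abort_if(is.null(pixel_size),
           "pixel size not given and not found in sidecar; calibration must be explicit")
  abort_if(length(pages) != length(channel_map),
           sprintf("channel-map mismatch: %d TIFF pages but %d channel names",
                   length(pages), length(channel_map)))
  dims <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), character(1))
  abort_if(length(unique(dims)) != 1, "TIFF pages have unequal dimensions")
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse grayscale-with-alpha
    unclass(p)
  })
  names(channels) <- channel_map
  md <- meta$metadata
  flatmount_image(channels, pixel_size, metadata = if (is.null(md)) list() else md)
}

#' Write a flat-mount image as a multi-page 16-bit TIFF plus JSON sidecar
#'
#' Intensities are clamped to `[0, 1]` and quantized to 16 bits, the
#' native depth of the microscope data the container emulates; a sidecar
#' `<path>.json` stores channel names, pixel size and metadata so that
#' [read_flatmount()] round-trips exactly.
#'
#' @param image a [flatmount_image].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_flatmount <- function(image, path) {
  stopifnot(inherits(image, "flatmount_image"))
  # snap to the 16-bit grid before writing: the TIFF writer truncates, so
  # values an epsilon below a grid point would otherwise lose one level
  pages <- lapply(image$channels,
                  function(m) round(pmin(pmax(m, 0), 1) * 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(channels = names(image$channels), pixel_size = image$pixel_size,
         metadata = image$metadata),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a region set as single-page TIFF masks + artery JSON
#' @param regions a [region_set].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_regions <- function(regions, dir) {
  stopifnot(inherits(regions, "region_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(regions$regions)) {
    tiff::writeTIFF(regions$regions[[nm]] * 1, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 8L, reduce = FALSE)
  }
  jsonlite::write_json(
    list(pixel_size = regions$pixel_size,
         arteries = lapply(regions$arteries, function(a) unname(as.matrix(a)))),
    file.path(dir, "arteries.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Area of a mask or region
#'
#' Foreground pixel count scaled by the squared pixel size.
#'
#' @param mask logical matrix or [binary_mask].
#' @param pixel_size micrometres per pixel (taken from the mask when it
#'   carries one).
#' @param units one of `"px2"`, `"um2"`, `"mm2"`.
#' @return scalar area.
#' @export
area_of <- function(mask, pixel_size = NULL, units = c("um2", "px2", "mm2")) {
  units <- match.arg(units)
  if (inherits(mask, "binary_mask")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  npx <- sum(mask > 0)
  if (units == "px2") return(npx)
  abort_if(is.null(pixel_size), "pixel_size needed for calibrated area")
  a <- npx * pixel_size^2
  if (units == "mm2") a <- a / 1e6
  a
}

metrics_schema <- c("sample", "region", "metric", "value", "units", "params_hash")

#' Write a metrics table as CSV with a stable schema
#'
#' @param records a data frame with columns sample, region, metric,
#'   value, units, params_hash (missing columns are added as NA).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(metrics_schema, names(records))) records[[col]] <- NA
  records <- records[, metrics_schema, drop = FALSE]
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Mean channel intensity over a mask
#' @param channel numeric matrix.
#' @param mask logical matrix or [binary_mask] (non-empty).
#' @return scalar mean intensity.
#' @export
mean_intensity_in_mask <- function(channel, mask) {
  m <- as_logical_matrix(mask)
  abort_if(!any(m), "mask is empty")
  abort_if(!all(dim(channel) == dim(m)), "channel and mask dimensions differ")
  mean(channel[m])
}
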
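abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Convert a micrometre coordinate to a pixel index
#'
#' Pixels are indexed 1-based, row-major; pixel `(r, c)` covers the square
#' `[(c-1), c) x [(r-1), r)` in pixel units. A point at `x` micrometres maps
#' into column `floor(x / pixel_size) + 1`.
#' @param x_um numeric coordinate in micrometres.
#' @param pixel_size pixel edge length, micrometres per pixel.
#' @return integer pixel index (>= 1).
#' @keywords internal
um_to_px <- function(x_um, pixel_size) pmax(1L, as.integer(floor(x_um / pixel_size)) + 1L)

#' Pixel centre positions in micrometres
#' @keywords internal
px_centers <- function(n, pixel_size) (seq_len(n) - 0.5) * pixel_size

as_logical_matrix <- function(x) {
  if (inherits(x, "binary_mask")) return(x$pixels)
  if (is.matrix(x)) return(x > 0)
  stop("expected a matrix or binary_mask", call. = FALSE)
}

# stable 8-char hash of a parameter list, for provenance columns
# (tiny polynomial rolling hash; avoids a digest dependency)
params_hash <- function(params) {
  s <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = 10)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}
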
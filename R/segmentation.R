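#' Disc median filter
#'
#' Replaces each pixel by the median over a disc of the given radius
#' (ImageJ "Median..." semantics, reflected edges). Radius 2 is the
#' standard pre-filter for vessel and nucleus channels in this pipeline.
#'
#' @param image numeric matrix.
#' @param radius_px disc radius in pixels (>= 1).
#' @return filtered matrix.
#' @export
median_filter <- function(image, radius_px) {
  abort_if(!is.numeric(radius_px) || radius_px < 1, "radius_px must be >= 1")
  median_disc_cpp(image, as.integer(radius_px))
}

#' Despeckle (3x3 median)
#'
#' The ImageJ "Despeckle" operation: a 3x3 square median filter,
#' reflected edges. Removes isolated single-pixel noise.
#'
#' @param image numeric matrix.
#' @return filtered matrix.
#' @export
despeckle <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  # pad by 1 with reflection, then median over the 9 shifted layers
  pr <- rbind(image[1, , drop = FALSE], image, image[nr, , drop = FALSE])
  pad <- cbind(pr[, 1, drop = FALSE], pr, pr[, nc, drop = FALSE])
  stack <- matrix(0, nr * nc, 9)
  k <- 0
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1
    stack[, k] <- as.vector(pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)])
  }
  matrix(apply(stack, 1, function(v) sort(v, partial = 5)[5]), nr, nc)
}

#' Otsu threshold over the observed intensity range
#'
#' 256-bin Otsu; returns the threshold value. Degenerate (constant)
#' images return the maximum so the mask comes out empty under the
#' strict `>` convention.
#'
#' @param image numeric matrix.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(image) {
  rng <- range(image, finite = TRUE)
  if (diff(rng) == 0) return(rng[2])
  EBImage::otsu(image, range = rng, levels = 256)
}

#' Binarize a channel
#'
#' Foreground is intensity strictly greater than the threshold; ties go
#' to background. With `method = "otsu"` the threshold is computed on a
#' 256-bin histogram over the observed range.
#'
#' @param image numeric matrix.
#' @param method `"otsu"` or `"manual"`.
#' @param value manual threshold (required for `method = "manual"`).
#' @param pixel_size micrometres per pixel recorded on the mask.
#' @return a [binary_mask] whose recipe records the threshold used.
#' @export
binarize <- function(image, method = c("otsu", "manual"), value = NULL,
                     pixel_size = 1) {
  method <- match.arg(method)
  if (method == "manual") {
    abort_if(is.null(value), "manual threshold requires a value")
    thr <- value
  } else {
    thr <- otsu_threshold(image)
  }
  binary_mask(image > thr, pixel_size,
              recipe = list(list(step = "threshold", method = method, value = thr)))
}

#' Run an ordered segmentation recipe
#'
#' A recipe is a list of steps, each `list(step = <name>, ...)` with the
#' names `median_filter(radius)`, `despeckle`, `threshold(method,
#' value)`, `pixel_classifier(model)`, `remove_small_objects(min_px)`,
#' `fill_holes(max_px)`. At least one binarizing step (threshold or
#' pixel_classifier) is required; the resulting mask carries the full
#' recipe, with resolved parameters, as provenance.
#'
#' @param image numeric matrix.
#' @param recipe list of steps.
#' @param pixel_size micrometres per pixel recorded on the mask.
#' @return a [binary_mask].
#' @export
run_recipe <- function(image, recipe, pixel_size = 1) {
  abort_if(!is.list(recipe) || length(recipe) == 0, "recipe must be a non-empty list of steps")
  steps <- vapply(recipe, function(s) s$step %||% "", character(1))
  abort_if(!any(steps %in% c("threshold", "pixel_classifier")),
           "recipe has no binarizing step (threshold or pixel_classifier)")
  cur <- image; is_mask <- FALSE; prov <- list()
  for (s in recipe) {
    nm <- s$step
    if (nm == "median_filter") {
      cur <- median_filter(cur, s$radius)
      prov <- c(prov, list(s))
    } else if (nm == "despeckle") {
      cur <- despeckle(cur)
      prov <- c(prov, list(s))
    } else if (nm == "threshold") {
      bm <- binarize(cur, method = s$method %||% "otsu", value = s$value, pixel_size = pixel_size)
      cur <- bm$pixels; is_mask <- TRUE
      prov <- c(prov, bm$recipe)
    } else if (nm == "pixel_classifier") {
      bm <- classify_pixels(cur, s$model)
      cur <- bm$pixels; is_mask <- TRUE
      prov <- c(prov, list(list(step = "pixel_classifier", seed = s$model$seed)))
    } else if (nm == "remove_small_objects") {
      abort_if(!is_mask, "remove_small_objects requires a binary mask")
      lab <- cc_label_cpp(cur, 8L)
      keep <- which(tabulate(lab) >= s$min_px)
      cur <- matrix(lab %in% keep, nrow(cur), ncol(cur))
      prov <- c(prov, list(s))
    } else if (nm == "fill_holes") {
      abort_if(!is_mask, "fill_holes requires a binary mask")
      holes <- cc_label_cpp(!cur, 4L)
      sizes <- tabulate(holes)
      border <- unique(c(holes[1, ], holes[nrow(cur), ], holes[, 1], holes[, ncol(cur)]))
      fill <- setdiff(which(sizes <= (s$max_px %||% Inf)), border)
      cur <- cur | matrix(holes %in% fill, nrow(cur), ncol(cur))
      prov <- c(prov, list(s))
    } else {
      stop(sprintf("unknown recipe step: %s", nm), call. = FALSE)
    }
  }
  binary_mask(cur, pixel_size, recipe = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-pixel feature stack for the pixel classifier
pixel_features <- function(image, scales = c(1, 2, 4)) {
  feats <- list(raw = as.vector(image))
  for (s in scales) {
    feats[[paste0("gauss", s)]] <- as.vector(EBImage::gblur(image, sigma = s))
  }
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(image, kx)
  gy <- EBImage::filter2(image, t(kx))
  feats$grad <- as.vector(sqrt(gx^2 + gy^2))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  feats$laplace <- as.vector(EBImage::filter2(image, lap))
  do.call(cbind, feats)
}

#' Train a pixel classifier
#'
#' A random-forest pixel classifier over simple image features (raw
#' intensity, Gaussian blurs at several scales, Sobel gradient
#' magnitude, Laplacian). This is the reproducible stand-in for
#' interactive trainable segmentation: label some foreground and
#' background pixels, train once, reuse the model.
#'
#' @param images list of numeric matrices (or a single matrix).
#' @param label_masks list of integer/logical matrices; 1 = foreground,
#'   0 = background, NA = unlabeled. Must contain both classes.
#' @param scales Gaussian smoothing scales (px).
#' @param n_trees forest size; kept odd so binary majority votes cannot
#'   tie (ranger breaks prediction ties randomly).
#' @param max_pixels_per_class training pixels subsampled per class.
#' @param rng_seed seed controlling subsampling and forest growth.
#' @return a `pixel_classifier` model.
#' @export
train_pixel_classifier <- function(images, label_masks, scales = c(1, 2, 4),
                                   n_trees = 51, max_pixels_per_class = 5000,
                                   rng_seed = 1) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(label_masks)) label_masks <- list(label_masks)
  abort_if(length(images) != length(label_masks), "images and label_masks lengths differ")
  feats <- NULL; labs <- NULL
  for (i in seq_along(images)) {
    abort_if(!all(dim(images[[i]]) == dim(label_masks[[i]])),
             "feature/shape mismatch between image and labels")
    f <- pixel_features(images[[i]], scales)
    l <- as.vector(label_masks[[i]])
    keep <- !is.na(l)
    feats <- rbind(feats, f[keep, , drop = FALSE])
    labs <- c(labs, l[keep])
  }
  abort_if(length(unique(labs)) < 2, "labels must contain both classes")
  withr::with_seed(rng_seed, {
    idx <- unlist(lapply(unique(labs), function(cl) {
      w <- which(labs == cl)
      if (length(w) > max_pixels_per_class) sample(w, max_pixels_per_class) else w
    }))
    df <- as.data.frame(feats[idx, , drop = FALSE])
    df$.class <- factor(labs[idx])
    fit <- ranger::ranger(.class ~ ., data = df, num.trees = n_trees,
                          seed = rng_seed, num.threads = 1)
  })
  structure(list(fit = fit, scales = scales, seed = rng_seed),
            class = "pixel_classifier")
}

#' Classify pixels with a trained model
#' @param image numeric matrix.
#' @param model a `pixel_classifier` from [train_pixel_classifier()].
#' @param pixel_size micrometres per pixel recorded on the mask.
#' @return a [binary_mask] (predicted foreground).
#' @export
classify_pixels <- function(image, model, pixel_size = 1) {
  stopifnot(inherits(model, "pixel_classifier"))
  f <- as.data.frame(pixel_features(image, model$scales))
  pred <- predict(model$fit, data = f, num.threads = 1,
                  seed = model$seed)$predictions
  fg <- as.character(pred) %in% c("1", "TRUE")
  binary_mask(matrix(fg, nrow(image), ncol(image)), pixel_size,
              recipe = list(list(step = "pixel_classifier", seed = model$seed)))
}
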
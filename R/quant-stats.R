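eval_4pl <- function(a, d, c, b, x) d + (a - d) / (1 + (x / c)^b)

#' Fit a four-parameter logistic (4PL) standard curve
#'
#' Least-squares fit of the Hill-form 4PL
#' `y = d + (a - d) / (1 + (x / c)^b)` with `a` the response at zero
#' concentration, `d` the response at saturation, `c` the inflection
#' concentration (EC50) and `b` the slope. Deterministic initialization
#' (`a = min y`, `d = max y`, `c` = geometric mid of the positive
#' concentrations, `b = 1`); Levenberg-Marquardt refinement.
#'
#' @param standards data frame with columns `concentration` and
#'   `response` (>= 5 distinct concentrations).
#' @return an object of class `fourpl_fit`.
#' @export
fit_4pl <- function(standards) {
  standards <- as.data.frame(standards)
  abort_if(!all(c("concentration", "response") %in% names(standards)),
           "standards need concentration and response columns")
  x <- standards$concentration; y <- standards$response
  abort_if(any(!is.finite(x)) || any(!is.finite(y)), "standards must be finite")
  abort_if(length(unique(x)) < 5, "at least 5 distinct concentrations required")
  abort_if(var(y) == 0, "degenerate standards: constant response")
  start <- list(a = min(y), d = max(y),
                c = exp(mean(log(x[x > 0]))), b = 1)
  fit <- minpack.lm::nlsLM(
    response ~ d + (a - d) / (1 + (concentration / c)^b),
    data = standards, start = start,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 200))
  p <- as.list(coef(fit))
  structure(list(a = p$a, d = p$d, c = p$c, b = p$b,
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 n = length(x), range = range(x), fit = fit),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<4PL fit> a=%.4g d=%.4g c=%.4g b=%.4g (rss %.3g, n=%d)\n",
              x$a, x$d, x$c, x$b, x$rss, x$n))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.data.frame(newdata)) newdata$concentration else newdata
  abort_if(is.null(x), "supply concentrations to predict at")
  eval_4pl(object$a, object$d, object$c, object$b, x)
}

#' Tidy a 4PL fit
#' @param x a `fourpl_fit`.
#' @param ... unused.
#' @return tibble with one row per parameter.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(term = c("a", "d", "c", "b"),
         estimate = c(x$a, x$d, x$c, x$b),
         description = c("lower asymptote (zero-dose response)",
                         "upper asymptote", "inflection concentration (EC50)",
                         "slope"))
}

#' One-row fit summary
#' @param x a `fourpl_fit`.
#' @param ... unused.
#' @return tibble with rss, convergence flag and n.
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = isTRUE(x$converged), n = x$n)
}

#' Generic tidiers
#' @param x object to tidy.
#' @param ... passed on.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Invert a 4PL standard curve
#'
#' Back-calculates concentration from response:
#' `x = c * ((a - d) / (y - d) - 1)^(1 / b)`. Responses outside the
#' open interval between the asymptotes are unrecoverable and error;
#' concentrations outside the standard range are flagged as
#' extrapolated.
#'
#' @param fit a `fourpl_fit`.
#' @param response numeric responses.
#' @return concentrations, with attribute `extrapolated` (logical).
#' @export
invert_4pl <- function(fit, response) {
  lo <- min(fit$a, fit$d); hi <- max(fit$a, fit$d)
  abort_if(any(response <= lo | response >= hi),
           sprintf("response outside the open asymptote interval (%.4g, %.4g)", lo, hi))
  x <- fit$c * ((fit$a - fit$d) / (response - fit$d) - 1)^(1 / fit$b)
  attr(x, "extrapolated") <- x < fit$range[1] | x > fit$range[2]
  x
}

#' Assemble the final metrics report
#'
#' Binds per-module metric records into one tidy table and a run
#' manifest. Duplicate (sample, region, metric) combinations are a
#' schema conflict and error.
#'
#' @param ... tibbles/data frames of metric records (columns from
#'   `sample`, `region`, `metric`, `value`, `units`, `params_hash`,
#'   `seed`; missing ones are filled with NA).
#' @param config optional configuration echoed into the manifest.
#' @param seed optional global seed echoed into the manifest.
#' @return list with `table` (tibble) and `manifest` (list).
#' @export
assemble_report <- function(..., config = list(), seed = NULL) {
  recs <- list(...)
  recs <- recs[vapply(recs, function(x) !is.null(x) && nrow(x) > 0, logical(1))]
  cols <- c("sample", "region", "metric", "value", "units", "params_hash", "seed")
  tab <- if (length(recs) == 0) {
    as_tibble(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    tab <- dplyr::bind_rows(lapply(recs, function(x) {
      x <- as_tibble(x)
      for (cn in setdiff(cols, names(x))) x[[cn]] <- NA
      x[, cols]
    }))
    dup <- duplicated(tab[, c("sample", "region", "metric")])
    abort_if(any(dup), sprintf("duplicate metric rows: %s",
                               paste(unique(tab$metric[dup]), collapse = ", ")))
    tab
  }
  manifest <- list(
    package = "flatquant",
    version = as.character(utils::packageVersion("flatquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, config = config, n_metrics = nrow(tab))
  list(table = tab, manifest = manifest)
}
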
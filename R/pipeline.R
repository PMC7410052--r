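pipeline_schema <- list(
  top = c("sample_id", "seed", "output_dir", "save_masks", "simulate", "input",
          "regions", "segmentation", "measure"),
  simulate = c("field_size_um", "capillary_density", "n_arteries", "jitter",
               "width_capillary_um", "width_artery_um", "regression",
               "perfusion", "render", "extras"),
  regression = c("target_fraction", "mode", "n_clusters"),
  perfusion = c("n_closed", "detach_fractions"),
  input = c("path", "channel_map", "pixel_size"),
  regions = c("dir", "r_central_um", "r_whole_um"),
  segmentation = c("channels", "recipe"),
  measure = c("min_length_um", "gap_tolerance_um", "window_um",
              "closing_radius_um", "median_radius_px", "min_area_px",
              "intensity_factor", "min_area_um2", "min_solidity"))

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  abort_if(length(extra) > 0,
           sprintf("unknown config key(s) in %s: %s", where,
                   paste(extra, collapse = ", ")))
}

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration (list or YAML path) before any work:
#' unknown keys are rejected, required fields for the requested mode are
#' named in errors.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list, invisibly augmented with defaults.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(!is.list(config), "config must be a list or YAML path")
  check_keys(config, pipeline_schema$top, "config")
  for (blk in c("simulate", "input", "regions", "segmentation", "measure")) {
    if (!is.null(config[[blk]])) check_keys(config[[blk]], pipeline_schema[[blk]], blk)
  }
  if (!is.null(config$simulate)) {
    for (sub in c("regression", "perfusion"))
      if (!is.null(config$simulate[[sub]]))
        check_keys(config$simulate[[sub]], pipeline_schema[[sub]],
                   paste0("simulate$", sub))
  }
  abort_if(is.null(config$simulate) && is.null(config$input),
           "config needs either a simulate block or an input block")
  if (!is.null(config$input)) {
    abort_if(is.null(config$input$path), "missing required field: input$path")
    abort_if(is.null(config$regions),
             "missing required field: regions (mask dir or annulus radii)")
  }
  config$seed <- config$seed %||% 1
  config$sample_id <- config$sample_id %||% "sample1"
  invisible(config)
}

default_recipe <- function() {
  list(list(step = "median_filter", radius = 2),
       list(step = "despeckle"),
       list(step = "threshold", method = "otsu"))
}

#' Run the flat-mount quantification pipeline
#'
#' Orchestrates simulate -> segment -> measure -> report from a single
#' configuration. Synthetic runs write the rendered TIFF, ground truth
#' and regions; measurement writes a tidy metrics CSV, side-branch call
#' table and a JSON manifest. Everything is deterministic for a fixed
#' config and seed.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @param stages character vector from `c("simulate", "segment",
#'   "measure", "report")` or `"all"`.
#' @return list with `metrics`, `calls`, `truth` (if simulated) and
#'   output paths, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  config <- validate_config(config)
  if (identical(stages, "all"))
    stages <- c("simulate", "segment", "measure", "report")
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  sample_id <- config$sample_id
  sim <- NULL; img <- NULL; regions <- NULL; truth <- NULL

  if ("simulate" %in% stages && !is.null(config$simulate)) {
    sc <- config$simulate
    net <- generate_plexus(
      field_size_um = sc$field_size_um %||% 600,
      capillary_density = sc$capillary_density %||% 0.002,
      n_arteries = sc$n_arteries %||% 4,
      rng_seed = seed,
      jitter = sc$jitter %||% 0.15,
      width_capillary_um = sc$width_capillary_um %||% 6,
      width_artery_um = sc$width_artery_um %||% 12)
    if (!is.null(sc$perfusion)) {
      pf <- apply_perfusion_loss(net, sc$perfusion$n_closed %||% 0,
                                 detach_fractions = unlist(sc$perfusion$detach_fractions) %||%
                                   c(attached = 1/3, disrupted = 1/3, detached = 1/3),
                                 rng_seed = seed + 1)
      net <- pf$network
    }
    if (!is.null(sc$regression)) {
      rg <- apply_regression(net, sc$regression$target_fraction %||% 0,
                             mode = sc$regression$mode %||% "cluster-contraction",
                             n_clusters = sc$regression$n_clusters %||% 12,
                             rng_seed = seed + 2)
      net <- rg$network
    }
    rc <- do.call(render_config, c(sc$render %||% list(), list(rng_seed = seed + 3)))
    sim <- render_flatmount(net, extras = sc$extras %||% list(), config = rc)
    img <- sim$image; regions <- sim$regions; truth <- sim$truth
    write_flatmount(img, file.path(out_dir, paste0(sample_id, ".tif")))
    write_regions(regions, file.path(out_dir, paste0(sample_id, "_regions")))
    jsonlite::write_json(truth_as_list(truth),
                         file.path(out_dir, paste0(sample_id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (is.null(img) && !is.null(config$input)) {
    img <- read_flatmount(config$input$path,
                          channel_map = unlist(config$input$channel_map),
                          pixel_size = config$input$pixel_size)
    rg <- config$regions
    if (!is.null(rg$dir)) {
      regions <- read_regions(rg$dir, img$pixel_size)
    } else {
      abort_if(is.null(rg$r_central_um) || is.null(rg$r_whole_um),
               "missing required field: regions$r_central_um / regions$r_whole_um")
      regions <- make_annulus_regions(dim(img), img$pixel_size,
                                      rg$r_central_um, rg$r_whole_um)
      regions$regions$field <- matrix(TRUE, dim(img)[1], dim(img)[2])
    }
  }
  abort_if(is.null(img), "nothing to measure: no simulate block and no input")

  masks <- NULL
  if (any(c("segment", "measure") %in% stages)) {
    seg_channels <- config$segmentation$channels %||%
      intersect(c("pecam", "coliv", "icam", "lectin"), names(img$channels))
    recipe <- config$segmentation$recipe %||% default_recipe()
    masks <- lapply(setNames(seg_channels, seg_channels), function(ch)
      run_recipe(img$channels[[ch]], recipe, pixel_size = img$pixel_size))
    if (isTRUE(config$save_masks) && "segment" %in% stages) {
      for (ch in names(masks))
        tiff::writeTIFF(masks[[ch]]$pixels * 1,
                        file.path(out_dir, paste0(sample_id, "_mask_", ch, ".tif")),
                        bits.per.sample = 8L, reduce = FALSE)
    }
  }

  metrics <- NULL; calls <- NULL
  if ("measure" %in% stages) {
    mp <- config$measure %||% list()
    ps <- img$pixel_size
    ph <- params_hash(mp)
    rows <- list()
    add <- function(region, metric, value, units) {
      rows[[length(rows) + 1]] <<- tibble(
        sample = sample_id, region = region, metric = metric,
        value = value, units = units, params_hash = ph, seed = seed)
    }
    central <- regions$regions$central
    whole <- regions$regions$whole %||% central
    meas_region <- regions$regions$field %||% whole
    if (!is.null(masks$pecam) && !is.null(masks$coliv)) {
      vm <- vessel_metrics(masks$pecam, masks$coliv, regions, ps,
                           min_length_um = mp$min_length_um %||% 5)
      add("central", "vessel_area_fraction", vm$vessel_area_fraction, "fraction")
      add("central", "ec_over_coliv", vm$ec_over_coliv, "ratio")
      add("central", "regressing_over_coliv", vm$regressing_over_coliv, "ratio")
      add("field", "fragmentation_index",
          fragmentation_index(masks$pecam, meas_region, ps,
                              mp$min_length_um %||% 5), "skeletons/mm2")
      add("field", "branch_density",
          branch_density(masks$pecam, meas_region, ps), "junctions/mm2")
      add("central", "mean_vessel_width",
          tryCatch(mean_vessel_width(masks$pecam, central, ps),
                   error = function(e) NA_real_), "um")
      add("whole", "vaso_obliterated_area_fraction",
          vaso_obliterated_area(masks$pecam, whole, ps,
                                mp$closing_radius_um %||% 25), "fraction")
    }
    if (!is.null(masks$icam) && !is.null(masks$coliv)) {
      ir <- icam_regression_ratio(masks$icam, masks$coliv, central, ps)
      add("central", "icam_over_coliv", ir$ec_over_coliv, "ratio")
    }
    if ("fli1" %in% names(img$channels) && !is.null(masks$pecam)) {
      nuc <- count_nuclei(img$channels$fli1, masks$pecam,
                          min_area_px = mp$min_area_px %||% 20, pixel_size = ps)
      add("field", "ec_nuclei", nuc$count, "count")
      if ("phh3" %in% names(img$channels) && nuc$count > 0)
        add("field", "proliferation_fraction",
            proliferation_fraction(img$channels$phh3, nuc), "fraction")
    }
    if ("casp3" %in% names(img$channels) && !is.null(masks$pecam) &&
        !is.null(masks$coliv)) {
      apo <- count_apoptotic_ecs(img$channels$casp3, masks$pecam, masks$coliv,
                                 central, mp$min_area_px %||% 20, ps)
      add("central", "apoptotic_ec_density", apo$density_per_mm2, "cells/mm2")
    }
    if ("pimo" %in% names(img$channels)) {
      add("central", "hypoxic_area_fraction",
          hypoxic_area_fraction(img$channels$pimo, central, pixel_size = ps,
                                median_radius_px = mp$median_radius_px %||% 20),
          "fraction")
    }
    if ("coliv" %in% names(img$channels) && !is.null(masks$coliv)) {
      nv <- neovascular_area(img$channels$coliv, masks$coliv, whole, ps,
                             intensity_factor = mp$intensity_factor %||% 2,
                             min_area_um2 = mp$min_area_um2 %||% 100,
                             min_solidity = mp$min_solidity %||% 0.85)
      add("whole", "neovascular_area_fraction", nv$fraction, "fraction")
    }
    if (length(regions$arteries) > 0 && !is.null(masks$coliv)) {
      skc <- skeletonize(masks$coliv)
      calls <- purrr::map_dfr(seq_along(regions$arteries), function(ai) {
        br <- detect_side_branches(skc, regions$arteries[[ai]])
        if (nrow(br) == 0) return(NULL)
        cl <- classify_side_branches(
          br, masks$lectin %||% masks$pecam, masks$icam %||% masks$pecam,
          masks$coliv, ps, mp$gap_tolerance_um %||% 5, mp$window_um %||% 50)
        cl$artery <- ai
        cl
      })
      if (!is.null(calls) && nrow(calls) > 0)
        add("field", "perfused_branch_density",
            perfused_branch_density(calls, regions$arteries, ps), "branches/mm")
    }
    metrics <- dplyr::bind_rows(rows)
  }

  paths <- list()
  if ("report" %in% stages && !is.null(metrics)) {
    rep <- assemble_report(metrics, config = config, seed = seed)
    paths$metrics <- file.path(out_dir, paste0(sample_id, "_metrics.csv"))
    write.csv(rep$table, paths$metrics, row.names = FALSE)
    paths$manifest <- file.path(out_dir, paste0(sample_id, "_manifest.json"))
    jsonlite::write_json(rep$manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    if (!is.null(calls) && nrow(calls) > 0) {
      paths$calls <- file.path(out_dir, paste0(sample_id, "_calls.csv"))
      write.csv(calls[, setdiff(names(calls), "path")], paths$calls,
                row.names = FALSE)
    }
  }
  invisible(list(metrics = metrics, calls = calls, truth = truth,
                 regions = regions, masks = masks, image = img, paths = paths))
}

truth_as_list <- function(truth) {
  t <- unclass(truth)
  t$side_branch_class_counts <- as.list(t$side_branch_class_counts)
  t
}

#' Read a region directory written by [write_regions()]
#' @param dir directory with `<name>.tif` masks and `arteries.json`.
#' @param pixel_size micrometres per pixel.
#' @return a [region_set].
#' @export
read_regions <- function(dir, pixel_size) {
  tifs <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  abort_if(length(tifs) == 0, sprintf("no region masks found in %s", dir))
  regions <- lapply(setNames(tifs, tools::file_path_sans_ext(basename(tifs))),
                    function(p) tiff::readTIFF(p) > 0.5)
  arteries <- list()
  aj <- file.path(dir, "arteries.json")
  if (file.exists(aj)) {
    meta <- jsonlite::read_json(aj)
    if (length(meta$arteries))
      arteries <- lapply(meta$arteries, function(a) {
        m <- do.call(rbind, lapply(a, function(p) as.integer(unlist(p))))
        colnames(m) <- c("row", "col")
        m
      })
    pixel_size <- meta$pixel_size %||% pixel_size
  }
  region_set(regions, arteries, pixel_size)
}
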
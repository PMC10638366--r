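#' Pipeline run configuration
#'
#' @param pixel_size micrometers per pixel for input images.
#' @param method "classical" or "learned" segmentation.
#' @param seg a \code{\link{seg_config}}.
#' @param window ROI area window, square micrometers.
#' @param out_dir output directory, or NULL to keep results in memory.
#' @param seed integer seed (synthetic inputs and any stochastic stage).
#' @param model a \code{pore_model}, required for method "learned".
#' @param correct_artifacts remove ground-truth debris pixels from the
#'   segmentation before measuring (synthetic inputs only).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(pixel_size = 0.6, method = c("classical", "learned"),
                       seg = seg_config(), window = c(50000, 70000),
                       out_dir = NULL, seed = 1L, model = NULL,
                       correct_artifacts = FALSE) {
  method <- match.arg(method)
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  if (window[1] >= window[2]) stopf("window lower bound must be < upper")
  if (method == "learned" && is.null(model))
    stopf("method 'learned' needs a trained model")
  structure(list(pixel_size = pixel_size, method = method, seg = seg,
                 window = window, out_dir = out_dir, seed = as.integer(seed),
                 model = model,
                 correct_artifacts = isTRUE(correct_artifacts)),
            class = "run_config")
}

measure_specimen <- function(image, chambers, config, truth = NULL) {
  lm <- if (config$method == "classical")
    segment_pores_classical(image, config$seg)
  else segment_pores_learned(image, config$model, config$seg)
  if (config$correct_artifacts && !is.null(truth))
    lm <- remove_artifacts(lm, truth$debris_mask, image$pixel_size,
                           config$seg)
  roi <- select_roi(chambers, window = config$window,
                    pixel_size = image$pixel_size)
  recs <- measure_pores(lm, roi, image$pixel_size)
  specimen_params(recs, roi, specimen_id = image$id)
}

#' Run the measurement pipeline over a set of specimens
#'
#' Executes segment -> (optional artifact removal) -> chamber ordering
#' and ROI selection -> pore measurement for each specimen, and collects
#' per-specimen pore parameters. Specimens that fail the size screen
#' (total area below the ROI window) or any other per-specimen error are
#' recorded as failures, not fatal. Inputs are either a synthetic cohort
#' request \code{list(preset =, n =)} or a list of
#' \code{list(image = sem_image, chambers = chamber_map)} entries (plus
#' optional \code{truth} for artifact correction).
#'
#' @param config a \code{\link{run_config}}.
#' @param inputs input specification, see Details.
#' @return list with \code{results} (per-specimen data.frame),
#'   \code{failures} (specimen id + error message), and \code{manifest}
#'   (config snapshot, seeds, per-stage timings, package version). When
#'   \code{config$out_dir} is set, results and manifest are written
#'   there.
#' @export
run_pipeline <- function(config, inputs) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  synthetic <- is.list(inputs) && !is.null(inputs$preset)
  if (synthetic) {
    base <- if (!is.null(inputs$base_spec)) inputs$base_spec
            else synthetic_spec(pixel_size = config$pixel_size)
    cohort <- generate_cohort(inputs$n, inputs$preset, seed = config$seed,
                              base_spec = base)
    specimens <- lapply(cohort, function(s)
      list(image = s$image, chambers = s$truth$chamber_map,
           truth = s$truth))
    timings$generate <- proc.time()[["elapsed"]] - t0
  } else {
    specimens <- inputs
  }
  if (length(specimens) == 0L) stopf("no inputs")
  t1 <- proc.time()[["elapsed"]]
  rows <- list()
  failures <- data.frame(specimen_id = character(0), error = character(0),
                         stringsAsFactors = FALSE)
  for (s in specimens) {
    row <- tryCatch(
      measure_specimen(s$image, s$chambers, config, s$truth),
      error = function(e) e)
    if (inherits(row, "error")) {
      warnf("specimen '%s' skipped: %s", s$image$id, conditionMessage(row))
      failures <- rbind(failures,
                        data.frame(specimen_id = s$image$id,
                                   error = conditionMessage(row),
                                   stringsAsFactors = FALSE))
    } else rows[[length(rows) + 1L]] <- row
  }
  results <- if (length(rows)) do.call(rbind, rows)
             else data.frame()
  timings$measure <- proc.time()[["elapsed"]] - t1
  manifest <- list(
    tool = "poremorph",
    version = as.character(utils::packageVersion("poremorph")),
    config = list(pixel_size = config$pixel_size, method = config$method,
                  window = config$window,
                  min_pore_area = config$seg$min_pore_area,
                  max_pore_area = config$seg$max_pore_area,
                  threshold_method = config$seg$threshold_method,
                  split_touching = config$seg$split_touching,
                  solidity_min = config$seg$solidity_min,
                  correct_artifacts = config$correct_artifacts),
    seed = config$seed,
    specimen_seeds = if (synthetic)
      vapply(seq_along(specimens), function(i) child_seed(config$seed, i), 0L)
      else integer(0),
    inputs = vapply(specimens, function(s) s$image$id, ""),
    n_measured = nrow(results), n_failed = nrow(failures),
    timings_s = timings)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_specimen_csv(results, file.path(config$out_dir, "specimens.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, failures = failures, manifest = manifest)
}
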
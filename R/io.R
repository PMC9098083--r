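#' Write simulated encounters to CSV with a metadata sidecar
#'
#' Writes one row per simulated encounter (RFC-4180 CSV, '.' decimal
#' separator, UTF-8) and a JSON sidecar `<path>.json` recording the seed,
#' the full configuration and the package version, so a run can be
#' reproduced exactly from its artifacts.
#'
#' @param samples Tibble from [simulate_sensitivity_grid()] or
#'   [simulate_slope_window_data()].
#' @param path Output CSV path.
#' @param config The configuration object used to generate `samples`.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(samples, path, config = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("Output directory does not exist: %s", dir))
  }
  readr::write_csv(samples, path, progress = FALSE)
  meta <- list(
    tool = "fidsim",
    version = as.character(utils::packageVersion("fidsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_rows = nrow(samples),
    seed = if (!is.null(config)) config$seed,
    config = if (!is.null(config)) unclass(config)[names(config) != "seed"]
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read simulated encounters back from CSV
#'
#' Validates the header against the two encounter schemas (sensitivity
#' grid: `iteration`, `slope`, `speed`, `ad`, `fid`; slope window:
#' `iteration`, `slope`, `speed_kmh`, `speed_mps`, `ad`, `fid`).
#'
#' @param path CSV path written by [write_encounters()].
#' @return A tibble.
#' @export
read_encounters <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  grid_cols <- c("iteration", "slope", "speed", "ad", "fid")
  window_cols <- c("iteration", "slope", "speed_kmh", "speed_mps", "ad", "fid")
  if (!(all(grid_cols %in% names(out)) || all(window_cols %in% names(out)))) {
    abort("Unrecognized encounter CSV header.")
  }
  if (any(out$fid < 0) || any(out$fid > out$ad + 1e-9)) {
    abort("Corrupt encounter file: FID outside [0, AD].")
  }
  out
}

#' Read the metadata sidecar of an encounter CSV
#'
#' @param path The CSV path (the sidecar is `<path>.json`).
#' @return A list with the run metadata.
#' @export
read_run_metadata <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) abort(sprintf("No metadata sidecar: %s", side))
  jsonlite::read_json(side, simplifyVector = TRUE)
}

#' Run a full sensitivity analysis and write its tables
#'
#' Orchestrates one model's sensitivity analysis end to end: takes (or
#' simulates) the encounter grid, runs the model's per-slope effect-size
#' estimation, summarizes the three escape-rule regions, and writes
#' `sensitivity.csv` and `regions.csv` into `out_dir`.
#'
#' @param model One of `"fear"`, `"looming"`, `"bayesian"`.
#' @param samples Optional pre-simulated grid; simulated from `config`
#'   when omitted.
#' @param config A [sensitivity_config()] used when `samples` is missing
#'   and recorded in the sidecar.
#' @param out_dir Output directory (must exist).
#' @param ... Passed on to the model's sensitivity function
#'   ([fear_sensitivity()], [looming_sensitivity()],
#'   [bayesian_sensitivity()]).
#' @return Invisibly, a list with `sensitivity` and `regions` tibbles.
#' @export
run_sensitivity <- function(model = c("fear", "looming", "bayesian"),
                            samples = NULL, config = sensitivity_config(),
                            out_dir = ".", ...) {
  model <- match.arg(model)
  if (!dir.exists(out_dir)) abort(sprintf("No such directory: %s", out_dir))
  if (is.null(samples)) samples <- simulate_sensitivity_grid(config)
  if (nrow(samples) == 0L) abort("Empty encounter table.")
  res <- switch(model,
                fear = fear_sensitivity(samples, ...),
                looming = looming_sensitivity(samples, ...),
                bayesian = bayesian_sensitivity(samples, ...))
  reg <- summarize_regions(res)
  readr::write_csv(as_tibble(res), file.path(out_dir, "sensitivity.csv"),
                   progress = FALSE)
  readr::write_csv(reg, file.path(out_dir, "regions.csv"), progress = FALSE)
  invisible(list(sensitivity = res, regions = reg))
}

#' Predict FID from any of the quantitative escape models
#'
#' Single entry point over the five quantitative models. Each model needs
#' its own parameters; missing ones raise an error naming them.
#'
#' @param model One of `"perceptual"`, `"fear"`, `"looming"`,
#'   `"visual_cue"`, `"bayesian"`.
#' @param ... Model parameters:
#'   * perceptual: `acuity`, `object_width`
#'   * fear: `alert_distances`, `fids`
#'   * looming: `base_fid`, `latency`, `approach_speed`
#'   * visual_cue: `params` ([visual_cue_params()]), `object_width`
#'   * bayesian: `alert_distance`, `approach_speed`, `species`, and
#'     optionally `risk`, `cost_flee`, `cost_remain`
#' @return A one-row tibble with `model`, `fid_m`, and the echoed
#'   parameterization as a list-column `params`.
#' @examples
#' predict_fid("perceptual", acuity = 4.82, object_width = 1.73)
#' @export
predict_fid <- function(model = c("perceptual", "fear", "looming",
                                  "visual_cue", "bayesian"), ...) {
  model <- match.arg(model)
  args <- list(...)
  need <- function(keys) {
    missing <- setdiff(keys, names(args))
    if (length(missing)) {
      abort(sprintf("Missing parameters for the %s model: %s",
                    model, paste(missing, collapse = ", ")))
    }
  }
  fid <- switch(model,
    perceptual = {
      need(c("acuity", "object_width"))
      perceptual_limit_fid(args$acuity, args$object_width)
    },
    fear = {
      need(c("alert_distances", "fids"))
      fear_predicted_fid(args$alert_distances, args$fids)
    },
    looming = {
      need(c("base_fid", "latency", "approach_speed"))
      looming_fid(args$base_fid, args$latency, args$approach_speed)
    },
    visual_cue = {
      need(c("params", "object_width"))
      visual_cue_fid(args$params, args$object_width)
    },
    bayesian = {
      need(c("alert_distance", "approach_speed", "species"))
      do.call(bayesian_fid, args)
    })
  tibble(model = model, fid_m = fid, params = list(args))
}
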
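#' Slope window of the spatial margin of safety
#'
#' Determines which slopes of the FID-vs-approach-speed relationship are
#' operationally indistinguishable from zero. For every (slope, iteration)
#' cell of a slope-window simulation, FID is regressed on approach-speed
#' treatment as a categorical factor -- mirroring controlled approach
#' experiments, where speed is a treatment, not a continuum -- and the
#' overall F-test p-value recorded. Per-slope mean p-values above `alpha`
#' mark slopes whose speed effect would, on average, not be detected; the
#' window is the contiguous run of such slopes containing zero.
#'
#' @param data Tibble from [simulate_slope_window_data()].
#' @param alpha Significance level.
#' @return A `fid_slope_window` object: list with `lower`, `upper`,
#'   `alpha`, and `per_slope` (tibble of slope, mean_p, n_iterations).
#' @examples
#' cfg <- slope_window_config(slopes = c(-0.5, 0, 0.5), n_iterations = 20,
#'                            seed = 1)
#' slope_window(simulate_slope_window_data(cfg))
#' @export
slope_window <- function(data, alpha = 0.05) {
  needed <- c("iteration", "slope", "speed_kmh", "fid")
  if (!all(needed %in% names(data))) {
    abort("`data` must come from `simulate_slope_window_data()`.")
  }
  if (length(unique(data$speed_kmh)) < 2L) {
    abort("At least 2 speed treatments are required for the F-test.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  per_cell <- data |>
    group_by(.data$slope, .data$iteration) |>
    summarise(p = anova_p(.data$fid, .data$speed_kmh), .groups = "drop")
  per_slope <- per_cell |>
    group_by(.data$slope) |>
    summarise(mean_p = mean(.data$p), n_iterations = n(), .groups = "drop") |>
    arrange(.data$slope)
  if (!any(per_slope$slope == 0)) {
    abort("The slope grid must contain 0 to anchor the window.")
  }
  pass <- per_slope$mean_p > alpha
  i0 <- which(per_slope$slope == 0)
  if (!pass[i0]) {
    warn("Mean p at slope 0 is below alpha; the window collapses to [0, 0].")
    lower <- upper <- 0
  } else {
    lo <- i0
    while (lo > 1L && pass[lo - 1L]) lo <- lo - 1L
    hi <- i0
    while (hi < nrow(per_slope) && pass[hi + 1L]) hi <- hi + 1L
    lower <- per_slope$slope[lo]
    upper <- per_slope$slope[hi]
  }
  structure(list(lower = lower, upper = upper, alpha = alpha,
                 per_slope = per_slope),
            class = "fid_slope_window")
}

# One-way ANOVA overall F-test p-value; groups need not be balanced.
anova_p <- function(y, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- length(y)
  if (k < 2L || n <= k) return(NA_real_)
  gm <- tapply(y, group, mean)
  gn <- tapply(y, group, length)
  ssb <- sum(gn * (gm - mean(y))^2)
  ssw <- sum((y - gm[group])^2)
  if (ssw <= 0) return(if (ssb > 0) 0 else NA_real_)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' @export
print.fid_slope_window <- function(x, ...) {
  cat("<fid_slope_window>\n")
  cat(sprintf("  spatial-margin window: [%.3g, %.3g] (mean p > %.3g)\n",
              x$lower, x$upper, x$alpha))
  cat(sprintf("  slopes evaluated: %d, iterations per slope: %d\n",
              nrow(x$per_slope), x$per_slope$n_iterations[1]))
  invisible(x)
}

#' Classify a slope into an escape rule
#'
#' Slopes inside the spatial-margin window are classed `spatial` (FID
#' constant with speed); slopes above it `temporal` (FID grows with speed,
#' a fixed time margin); slopes below it `delayed` (FID shrinks with
#' speed, delayed escape).
#'
#' @param slope Slope(s) of the FID-vs-speed relationship, m per m/s.
#' @param window A `fid_slope_window` from [slope_window()].
#' @return Character vector of `"delayed"`, `"spatial"`, `"temporal"`.
#' @examples
#' w <- structure(list(lower = -0.1, upper = 0.1), class = "fid_slope_window")
#' classify_escape_rule(c(-5, 0.05, 5), w)
#' @export
classify_escape_rule <- function(slope, window) {
  stopifnot(inherits(window, "fid_slope_window"))
  case_when(slope < window$lower ~ "delayed",
            slope > window$upper ~ "temporal",
            TRUE ~ "spatial")
}
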
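#' @title Internal: effect sizes per (slope, iteration) cell
#' @description Computes Cohen's f2 of approach speed on a per-sample
#'   prediction, for every (slope, iteration) cell of a balanced simulation
#'   grid, via closed-form simple regression on the shared speed grid.
#' @noRd
cell_f2_table <- function(samples, pred) {
  df <- samples
  df$.pred <- pred
  df <- arrange(df, .data$slope, .data$iteration, .data$speed)
  speeds <- sort(unique(df$speed))
  n_sp <- length(speeds)
  if (nrow(df) %% n_sp != 0L) {
    abort("Simulation grid is unbalanced: every cell needs the full speed grid.")
  }
  m <- matrix(df$.pred, nrow = n_sp)
  xc <- speeds - mean(speeds)
  sxx <- sum(xc^2)
  sxy <- as.numeric(crossprod(m, xc))
  syy <- colSums(m^2) - n_sp * colMeans(m)^2
  degenerate <- syy <= sxx * 1e-14
  if (any(degenerate)) {
    warn("Degenerate regression in some cells (constant prediction); f2 set to 0.")
  }
  r2 <- ifelse(degenerate, 0, sxy^2 / (sxx * syy))
  r2 <- pmin(r2, 1 - 1e-12)
  idx <- seq(1L, nrow(df), by = n_sp)
  tibble(slope = df$slope[idx], iteration = df$iteration[idx],
         f2 = r2 / (1 - r2))
}

new_fid_sensitivity <- function(tbl, model, effect) {
  structure(tbl, class = c("fid_sensitivity", class(tbl)),
            model = model, effect = effect)
}

#' FEAR-hypothesis sensitivity to approach speed
#'
#' For every (slope, iteration) cell of a simulated grid, computes the phi
#' index over that cell's AD/FID pairs across approach speeds, together
#' with its Monte-Carlo significance against the uniform null, then
#' averages both over iterations per slope. Slopes where the mean phi
#' exceeds 0.5 with mean p below 0.05 indicate that escape behavior tracks
#' alert distance as the FEAR hypothesis predicts -- and hence that the
#' phi-based test is sensitive to approach speed there.
#'
#' @param samples Tibble from [simulate_sensitivity_grid()].
#' @param n_phi_sim Monte-Carlo replicates per significance test.
#' @return A `fid_sensitivity` tibble with one row per slope: `model`,
#'   `slope`, `extra_param` (NA), `mean_effect`, `sd_effect`, `mean_p`,
#'   `n_iterations`.
#' @examples
#' s <- simulate_sensitivity_grid(sensitivity_config(n_iterations = 2,
#'                                                   slopes = c(-5, 0, 5),
#'                                                   seed = 1))
#' fear_sensitivity(s, n_phi_sim = 50)
#' @export
fear_sensitivity <- function(samples, n_phi_sim = 1000) {
  if (nrow(samples) == 0L) abort("`samples` is empty.")
  cells <- samples |>
    group_by(.data$slope, .data$iteration) |>
    summarise(phi = phi_index(.data$ad, .data$fid),
              m = n(), .groups = "drop")
  # Under FID ~ Uniform(0, AD) the per-observation ratios are Uniform(0, 1),
  # so the null phi is a mean of m standard uniforms for every cell.
  cells$p <- vapply(seq_len(nrow(cells)), function(i) {
    phi_null <- rowMeans(matrix(runif(n_phi_sim * cells$m[i]),
                                nrow = n_phi_sim))
    mean(phi_null >= cells$phi[i])
  }, numeric(1))
  out <- cells |>
    group_by(.data$slope) |>
    summarise(mean_effect = mean(.data$phi),
              sd_effect = sd(.data$phi),
              mean_p = mean(.data$p),
              n_iterations = n(), .groups = "drop") |>
    mutate(model = "fear", extra_param = NA_real_) |>
    dplyr::select("model", "slope", "extra_param", "mean_effect",
                  "sd_effect", "mean_p", "n_iterations")
  new_fid_sensitivity(out, "fear", "phi")
}

#' Looming-stimulus sensitivity to approach speed
#'
#' Applies the neuronal-latency correction `max(0, FID - latency * speed)`
#' to every simulated FID, regresses the corrected prediction on approach
#' speed within each (slope, latency, iteration) cell, converts the R2 to
#' Cohen's f2, and averages over iterations. The default latency grid is
#' 25 even values across 0.05--0.1 s, the range of looming-neuron latencies
#' measured in the rock pigeon; the grid midpoint 0.075 s is the
#' conventional 2-D summary.
#'
#' @inheritParams fear_sensitivity
#' @param latencies Neuronal latency values, s.
#' @return A `fid_sensitivity` tibble with one row per (slope, latency);
#'   `extra_param` holds the latency.
#' @examples
#' s <- simulate_sensitivity_grid(sensitivity_config(n_iterations = 2,
#'                                                   slopes = c(-5, 0, 5),
#'                                                   seed = 1))
#' looming_sensitivity(s, latencies = 0.075)
#' @export
looming_sensitivity <- function(samples,
                                latencies = seq(0.05, 0.1, length.out = 25)) {
  if (nrow(samples) == 0L) abort("`samples` is empty.")
  if (any(latencies < 0)) abort("Latencies must be non-negative.")
  out <- purrr::map_dfr(latencies, function(lat) {
    pred <- looming_fid(samples$fid, lat, samples$speed)
    cell_f2_table(samples, pred) |>
      group_by(.data$slope) |>
      summarise(mean_effect = mean(.data$f2),
                sd_effect = sd(.data$f2),
                n_iterations = n(), .groups = "drop") |>
      mutate(extra_param = lat)
  })
  out <- out |>
    mutate(model = "looming", mean_p = NA_real_) |>
    dplyr::select("model", "slope", "extra_param", "mean_effect",
                  "sd_effect", "mean_p", "n_iterations")
  new_fid_sensitivity(out, "looming", "f2")
}

#' Default body-mass grid of the sensitivity analysis
#'
#' 50 values evenly spaced on the log scale from 11.5 g to 6.22 kg, the
#' body-mass range of the 50-species review; the geometric mean is 267.4 g.
#'
#' @param n Number of masses.
#' @param min_g,max_g Range in grams.
#' @return Body masses in grams.
#' @export
body_mass_grid <- function(n = 50, min_g = 11.5, max_g = 6220) {
  exp(seq(log(min_g), log(max_g), length.out = n))
}

#' Bayesian optimal-escape sensitivity to approach speed
#'
#' For each body mass, builds a species profile from allometry (escape
#' speed via [escape_speed_allometry()], escape cost via [escape_cost()],
#' energy budget via [daily_energy_expenditure()]), predicts the Bayesian
#' optimal-escape FID at every sample's alert distance and approach speed,
#' regresses the prediction on speed within each (slope, iteration) cell,
#' and converts to Cohen's f2. The conventional 2-D summary uses the
#' geometric-mean body mass of the species review, 267.4 g.
#'
#' @inheritParams fear_sensitivity
#' @param body_masses Body masses in grams; defaults to [body_mass_grid()].
#' @param risk A [bayes_risk()] specification.
#' @param step Distance-scan resolution of [bayesian_fid()], m.
#' @return A `fid_sensitivity` tibble with one row per (slope, mass);
#'   `extra_param` holds the body mass in grams.
#' @examples
#' s <- simulate_sensitivity_grid(sensitivity_config(
#'   n_iterations = 1, slopes = 0, speeds = c(10, 50, 90), seed = 1))
#' bayesian_sensitivity(s, body_masses = 267.4)
#' @export
bayesian_sensitivity <- function(samples, body_masses = body_mass_grid(),
                                 risk = bayes_risk(), step = 0.01) {
  if (nrow(samples) == 0L) abort("`samples` is empty.")
  if (any(body_masses <= 0)) abort("Body masses must be positive (g).")
  out <- purrr::map_dfr(body_masses, function(mass_g) {
    mass_kg <- mass_g / 1000
    sp <- species_profile(
      body_mass = mass_kg,
      escape_speed = escape_speed_allometry(mass_kg)
    )
    cf <- escape_cost(sp)
    cr <- daily_energy_expenditure(mass_g)
    pred <- vapply(seq_len(nrow(samples)), function(i) {
      bayesian_fid(samples$ad[i], samples$speed[i], sp, risk = risk,
                   cost_flee = cf, cost_remain = cr, step = step)
    }, numeric(1))
    cell_f2_table(samples, pred) |>
      group_by(.data$slope) |>
      summarise(mean_effect = mean(.data$f2),
                sd_effect = sd(.data$f2),
                n_iterations = n(), .groups = "drop") |>
      mutate(extra_param = mass_g)
  })
  out <- out |>
    mutate(model = "bayesian", mean_p = NA_real_) |>
    dplyr::select("model", "slope", "extra_param", "mean_effect",
                  "sd_effect", "mean_p", "n_iterations")
  new_fid_sensitivity(out, "bayesian", "f2")
}

#' Summarize sensitivity over the three escape-rule slope regions
#'
#' Pools per-slope effect sizes over the three slope regions tied to the
#' escape rules: negative slopes (delayed margin of safety), slope zero
#' (spatial margin of safety) and positive slopes (temporal margin of
#' safety). The region mean averages the per-slope mean effects; the region
#' SD combines within-slope (across-iteration) and between-slope variance.
#' f2-based models get a Cohen class; the phi-based FEAR model gets a
#' support flag (mean phi > 0.5 and mean p < 0.05).
#'
#' @param results A `fid_sensitivity` tibble.
#' @param extra_param For 3-D results (looming, Bayesian), the value of the
#'   extra parameter to summarize at; defaults to the value closest to the
#'   conventional summary (latency 0.075 s, body mass 267.4 g).
#' @return A tibble with one row per region: `model`, `region`,
#'   `escape_rule`, `extra_param`, `mean_effect`, `sd_effect`, and
#'   `cohen_class` or `fear_support`.
#' @export
summarize_regions <- function(results, extra_param = NULL) {
  stopifnot(inherits(results, "fid_sensitivity"))
  model <- attr(results, "model")
  effect <- attr(results, "effect")
  tbl <- as_tibble(results)
  if (!all(is.na(tbl$extra_param))) {
    target <- if (is.null(extra_param)) {
      default <- if (model == "looming") 0.075 else 267.4
      vals <- unique(tbl$extra_param)
      vals[which.min(abs(vals - default))]
    } else {
      extra_param
    }
    tbl <- filter(tbl, abs(.data$extra_param - target) < 1e-9)
    if (nrow(tbl) == 0L) abort("No rows at the requested `extra_param`.")
  }
  if (!any(tbl$slope < 0) || !any(tbl$slope == 0) || !any(tbl$slope > 0)) {
    warn("Slope grid does not cover all three regions; summary is partial.")
  }
  out <- tbl |>
    mutate(region = case_when(.data$slope < 0 ~ "negative",
                              .data$slope == 0 ~ "zero",
                              TRUE ~ "positive")) |>
    group_by(.data$region) |>
    summarise(
      extra_param = .data$extra_param[1],
      mean_p = mean(.data$mean_p),
      mean_effect_out = mean(.data$mean_effect),
      sd_effect_out = sqrt(mean(.data$sd_effect^2) +
                             ifelse(n() > 1, stats::var(.data$mean_effect), 0)),
      .groups = "drop"
    ) |>
    mutate(
      model = model,
      escape_rule = case_when(.data$region == "negative" ~ "delayed",
                              .data$region == "zero" ~ "spatial",
                              TRUE ~ "temporal"),
      mean_effect = .data$mean_effect_out,
      sd_effect = .data$sd_effect_out
    )
  out <- out[order(factor(out$region, levels = c("negative", "zero",
                                                 "positive"))), ]
  base <- dplyr::select(out, "model", "region", "escape_rule", "extra_param",
                        "mean_effect", "sd_effect")
  if (effect == "phi") {
    base$mean_p <- out$mean_p
    base$fear_support <- base$mean_effect > 0.5 & base$mean_p < 0.05
  } else {
    base$cohen_class <- classify_effect(base$mean_effect)
  }
  base
}
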
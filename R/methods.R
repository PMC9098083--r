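#' @export
print.fid_sensitivity <- function(x, ...) {
  cat(sprintf("<fid_sensitivity: %s model, %s effect>\n",
              attr(x, "model"),
              if (attr(x, "effect") == "phi") "phi-index" else "Cohen's f2"))
  NextMethod()
}

#' Tidy a sensitivity result
#'
#' Returns the per-slope (and, for 3-D results, per-extra-parameter) effect
#' sizes as a plain tibble.
#'
#' @param x A `fid_sensitivity` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fid_sensitivity
#' @export
tidy.fid_sensitivity <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a sensitivity result
#'
#' @param x A `fid_sensitivity` object.
#' @param ... Passed to [summarize_regions()].
#' @return A one-row tibble with the model, effect type, number of slopes,
#'   and the three region means.
#' @method glance fid_sensitivity
#' @export
glance.fid_sensitivity <- function(x, ...) {
  reg <- summarize_regions(x, ...)
  tibble(
    model = attr(x, "model"),
    effect = attr(x, "effect"),
    n_slopes = length(unique(x$slope)),
    n_iterations = x$n_iterations[1],
    negative_mean = reg$mean_effect[reg$region == "negative"],
    zero_mean = reg$mean_effect[reg$region == "zero"],
    positive_mean = reg$mean_effect[reg$region == "positive"]
  )
}

#' Tidy a slope window
#'
#' @param x A `fid_slope_window` object.
#' @param ... Unused.
#' @return The per-slope tibble of mean p-values.
#' @method tidy fid_slope_window
#' @export
tidy.fid_slope_window <- function(x, ...) {
  x$per_slope
}

#' One-row summary of a slope window
#'
#' @param x A `fid_slope_window` object.
#' @param ... Unused.
#' @return A one-row tibble with `lower`, `upper`, `alpha`, `n_slopes`.
#' @method glance fid_slope_window
#' @export
glance.fid_slope_window <- function(x, ...) {
  tibble(lower = x$lower, upper = x$upper, alpha = x$alpha,
         n_slopes = nrow(x$per_slope))
}

#' Plot a sensitivity curve
#'
#' Draws the mean effect size against the slope of the FID-vs-speed
#' relationship; 3-D results (looming, Bayesian) are drawn at the
#' conventional summary value of the extra parameter unless `extra_param`
#' picks another one. Phi-based results show the 0.5 FEAR support line;
#' f2-based results show Cohen's small/medium/large anchors.
#'
#' @param object A `fid_sensitivity` object.
#' @param extra_param Optional extra-parameter value to plot at.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fid_sensitivity
#' @export
autoplot.fid_sensitivity <- function(object, extra_param = NULL, ...) {
  model <- attr(object, "model")
  effect <- attr(object, "effect")
  tbl <- as_tibble(object)
  if (!all(is.na(tbl$extra_param))) {
    target <- if (is.null(extra_param)) {
      default <- if (model == "looming") 0.075 else 267.4
      vals <- unique(tbl$extra_param)
      vals[which.min(abs(vals - default))]
    } else {
      extra_param
    }
    tbl <- filter(tbl, abs(.data$extra_param - target) < 1e-9)
  }
  ylab <- if (effect == "phi") "mean phi index" else "mean Cohen's f2"
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$slope,
                                         y = .data$mean_effect)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_effect - .data$sd_effect,
                                      ymax = .data$mean_effect + .data$sd_effect),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "slope of FID vs. approach speed (m per m/s)",
                  y = ylab, title = sprintf("%s model", model)) +
    ggplot2::theme_minimal()
  if (effect == "phi") {
    p <- p + ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed")
  } else {
    p <- p + ggplot2::geom_hline(yintercept = c(0.02, 0.15, 0.35),
                                 linetype = "dotted")
  }
  p
}

#' Plot a slope window
#'
#' Mean regression p-value per slope with the significance level and the
#' detected spatial-margin window.
#'
#' @param object A `fid_slope_window` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fid_slope_window
#' @export
autoplot.fid_slope_window <- function(object, ...) {
  ggplot2::ggplot(object$per_slope,
                  ggplot2::aes(x = .data$slope, y = .data$mean_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::annotate("rect", xmin = object$lower, xmax = object$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::labs(x = "slope of FID vs. approach speed (m per m/s)",
                  y = "mean F-test p-value") +
    ggplot2::theme_minimal()
}
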
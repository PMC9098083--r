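#' Cohen's f-squared from R-squared
#'
#' \eqn{f^2 = R^2 / (1 - R^2)}: the effect size used to judge how much of
#' the variation in predicted FID is accounted for by approach speed.
#'
#' @param r_squared Coefficient of determination in `[0, 1)`. Vectorized.
#' @return Cohen's f-squared (non-negative).
#' @examples
#' f_squared(0.5) # 1
#' @export
f_squared <- function(r_squared) {
  if (any(r_squared < 0) || any(r_squared > 1)) {
    abort("`r_squared` must lie in [0, 1).")
  }
  if (any(r_squared == 1)) {
    abort("`r_squared` = 1 gives an infinite effect size.")
  }
  r_squared / (1 - r_squared)
}

#' Classify an f-squared effect size
#'
#' Cohen's conventional anchors for f-squared are 0.02 (small), 0.15
#' (medium) and 0.35 (large). Intervals are left-closed: an effect exactly
#' at an anchor takes the anchor's label.
#'
#' @param f2 f-squared value(s), non-negative.
#' @return Factor with levels `below_small`, `small`, `medium`, `large`.
#' @examples
#' classify_effect(c(0, 0.021, 0.2, 0.35))
#' @export
classify_effect <- function(f2) {
  if (any(f2 < 0)) abort("`f2` must be non-negative.")
  cut(f2,
      breaks = c(-Inf, 0.02, 0.15, 0.35, Inf),
      labels = c("below_small", "small", "medium", "large"),
      right = FALSE)
}
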
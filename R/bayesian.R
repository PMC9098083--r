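#' Risk specification for the Bayesian optimal escape model
#'
#' The Bayesian optimal escape model weighs the perceived probability of
#' attack from two cues: how far the approaching threat has already closed
#' since detection, and how its speed compares with the animal's maximum
#' escape speed. The cue likelihoods are combined with the behavioral prior
#' \eqn{\alpha} by Bayes' theorem:
#' \deqn{P(attack \mid d, v) = \frac{\alpha\, x_1 x_2}
#'   {\alpha\, x_1 x_2 + (1 - \alpha)(1 - x_1)(1 - x_2)}}
#' with the default cues \eqn{x_1 = 1 - d / AD} (proportional distance
#' closed after detection) and \eqn{x_2 = \min(v / v_{esc}, 1)} (approach
#' speed relative to the maximum escape speed). Both cue functions are
#' pluggable; alternative risk formulations can be supplied without
#' touching the rest of the model.
#'
#' @param distance_cue Function of `(distance, alert_distance)` returning a
#'   value in `[0, 1]` that grows as the threat closes in.
#' @param speed_cue Function of `(approach_speed, species)` returning a
#'   value in `[0, 1]` that grows with the relative approach speed.
#' @return A `bayes_risk` object.
#' @examples
#' risk <- bayes_risk()
#' @export
bayes_risk <- function(distance_cue = function(distance, alert_distance) {
                         1 - distance / alert_distance
                       },
                       speed_cue = function(approach_speed, species) {
                         pmin(approach_speed / species$escape_speed, 1)
                       }) {
  stopifnot(is.function(distance_cue), is.function(speed_cue))
  structure(list(distance_cue = distance_cue, speed_cue = speed_cue),
            class = "bayes_risk")
}

#' Perceived probability of attack
#'
#' Evaluates the Bayes-weighted attack probability of a [bayes_risk()]
#' specification at given distances.
#'
#' @param distance Distance(s) between animal and vehicle, m.
#' @param alert_distance Alert (detection) distance, m.
#' @param approach_speed Vehicle approach speed, m/s.
#' @param species A [species_profile()].
#' @param risk A [bayes_risk()] specification.
#' @return Attack probabilities in `[0, 1]`.
#' @export
attack_probability <- function(distance, alert_distance, approach_speed,
                               species, risk = bayes_risk()) {
  x1 <- risk$distance_cue(distance, alert_distance)
  x2 <- risk$speed_cue(approach_speed, species)
  if (any(x1 < -1e-9 | x1 > 1 + 1e-9) || any(x2 < -1e-9 | x2 > 1 + 1e-9)) {
    abort("Risk cues must return probabilities in [0, 1].")
  }
  x1 <- pmin(pmax(x1, 0), 1)
  x2 <- pmin(pmax(x2, 0), 1)
  alpha <- species$behavioral_bias
  num <- alpha * x1 * x2
  den <- num + (1 - alpha) * (1 - x1) * (1 - x2)
  p <- ifelse(den > 0, num / den, as.numeric(num > 0))
  # both cues fire fully while the prior term vanishes: risk is certain
  p[den == 0 & num == 0 & x1 > 0 & x2 > 0] <- 1
  p
}

#' Predicted FID under the Bayesian optimal escape model
#'
#' The animal flees at the first (largest) distance after detection at
#' which the one-off energetic cost of fleeing no longer exceeds the
#' perceived energetic cost of remaining -- its daily energy budget
#' weighted by the perceived probability of attack. The decision is scanned
#' on a descending distance grid from the alert distance: the predicted FID
#' is the largest grid distance at which
#' `cost_flee <= cost_remain * P(attack | d, v)` holds, the alert distance
#' itself if the condition already holds there, and 0 if it never holds.
#'
#' @param alert_distance Alert (detection) distance, m.
#' @param approach_speed Vehicle approach speed, m/s.
#' @param species A [species_profile()].
#' @param risk A [bayes_risk()] specification.
#' @param cost_flee Energetic cost of one escape flight, kJ. Defaults to
#'   [escape_cost()] of the species.
#' @param cost_remain Energetic cost of remaining if attacked, kJ. Defaults
#'   to the species' [daily_energy_expenditure()].
#' @param step Scan resolution, m.
#' @return Predicted FID in m, in `[0, alert_distance]`.
#' @examples
#' cowbird <- species_profile(body_mass = 0.0439)
#' bayesian_fid(50, 30, cowbird)
#' @export
bayesian_fid <- function(alert_distance, approach_speed, species,
                         risk = bayes_risk(),
                         cost_flee = escape_cost(species),
                         cost_remain = daily_energy_expenditure(
                           species$body_mass * 1000),
                         step = 0.01) {
  if (alert_distance <= 0) abort("`alert_distance` must be positive (m).")
  if (approach_speed <= 0) abort("`approach_speed` must be positive (m/s).")
  if (cost_flee < 0 || cost_remain < 0) {
    abort("Costs must be non-negative (kJ).")
  }
  d <- seq(alert_distance, 0, by = -step)
  if (d[length(d)] > 0) d <- c(d, 0)
  p <- attack_probability(d, alert_distance, approach_speed, species, risk)
  hit <- which(cost_flee <= cost_remain * p)
  if (length(hit) == 0L) 0 else d[hit[1L]]
}
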
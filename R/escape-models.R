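#' Predicted FID under the perceptual limits hypothesis
#'
#' The perceptual limits hypothesis holds that an animal escapes the moment
#' it can visually resolve the approaching object, so the predicted flight
#' initiation distance equals the detection distance. An object of width
#' `w` is resolvable out to the distance at which it subtends the minimum
#' resolvable visual angle -- one full grating cycle, i.e. `1 / acuity`
#' degrees. By exact trigonometry that distance is
#' \eqn{d = (w / 2) / \tan(\theta_{min} / 2)}.
#'
#' @param acuity Visual acuity, cycles per degree. Vectorized.
#' @param object_width Frontal width of the approaching object, m. Vectorized.
#'
#' @return Maximum resolution distance in m (equals the predicted detection
#'   distance and FID under this hypothesis).
#' @examples
#' # brown-headed cowbird (4.82 cycles/degree) watching a 1.73 m wide car
#' perceptual_limit_fid(4.82, 1.73)
#' @export
perceptual_limit_fid <- function(acuity, object_width) {
  if (any(acuity <= 0) || any(object_width <= 0)) {
    abort("`acuity` and `object_width` must be positive.")
  }
  theta_min <- (1 / acuity) * pi / 180 # radians subtended by one cycle
  (object_width / 2) / tan(theta_min / 2)
}

#' Latency-corrected FID under the looming stimulus hypothesis
#'
#' Looming-sensitive neurons fire when the optical variable tau (visual
#' angle over its expansion rate) drops to a threshold; the escape follows
#' after a neuronal latency \eqn{\delta}. During that latency the vehicle
#' keeps closing, so the realized FID is the base (threshold) distance minus
#' `latency * speed`, floored at zero because an escape cannot start behind
#' the point of contact.
#'
#' @param base_fid Distance at which the tau threshold is reached, m. Either
#'   derived from a tau threshold via [looming_base_from_tau()] or an
#'   observed mean FID standing in for it. Vectorized.
#' @param latency Neuronal latency \eqn{\delta}, s.
#' @param approach_speed Approach speed, m/s.
#'
#' @return Predicted FID in m, `max(0, base_fid - latency * approach_speed)`.
#' @examples
#' looming_fid(30, 0.1, 50) # 25 m
#' @export
looming_fid <- function(base_fid, latency, approach_speed) {
  if (any(base_fid < 0)) abort("`base_fid` must be non-negative.")
  if (any(latency < 0)) abort("`latency` must be non-negative.")
  if (any(approach_speed <= 0)) abort("`approach_speed` must be positive.")
  pmax(0, base_fid - latency * approach_speed)
}

#' Distance at which the optical variable tau reaches a threshold
#'
#' For a direct, constant-speed approach of a circular frontal profile of
#' radius `r`, the visual angle is \eqn{\theta(d) = 2 \arctan(r / d)} and
#' tau is \eqn{\tau(d) = \theta / \theta' = \arctan(r/d) (d^2 + r^2) / (r v)}.
#' Tau shrinks as the object closes in; this function returns the distance
#' at which it first falls to `tau_threshold`. In the small-angle regime
#' (distance much larger than the radius) the solution reduces to
#' `tau_threshold * approach_speed`, i.e. tau is simply time to collision.
#'
#' @param tau_threshold Tau threshold, s.
#' @param radius Frontal profile radius, m.
#' @param approach_speed Approach speed, m/s.
#'
#' @return Distance in m at which tau first equals the threshold during the
#'   approach; 0 if the threshold is never reached before contact (for a
#'   finite-radius object tau cannot fall below roughly \eqn{\pi r / (2v)},
#'   because the visual angle saturates as the object fills the visual
#'   field).
#' @examples
#' looming_base_from_tau(1, 0.865, 30) # close to 30 m
#' @export
looming_base_from_tau <- function(tau_threshold, radius, approach_speed) {
  if (any(tau_threshold <= 0) || any(radius <= 0) || any(approach_speed <= 0)) {
    abort("`tau_threshold`, `radius` and `approach_speed` must be positive.")
  }
  n <- max(length(tau_threshold), length(radius), length(approach_speed))
  tau_threshold <- rep_len(tau_threshold, n)
  radius <- rep_len(radius, n)
  approach_speed <- rep_len(approach_speed, n)
  tau_of_d <- function(d, r, v) atan(r / d) * (d^2 + r^2) / (r * v)
  vapply(seq_len(n), function(i) {
    r <- radius[i]; v <- approach_speed[i]; tau <- tau_threshold[i]
    upper <- max(10 * tau * v, 10 * r)
    while (tau_of_d(upper, r, v) < tau) upper <- upper * 2
    # tau falls as the object closes in but turns back up within about one
    # radius of contact; escape is triggered on the approaching branch
    opt <- stats::optimize(tau_of_d, c(1e-9, upper), r = r, v = v)
    if (opt$objective >= tau) return(0) # threshold unreachable before contact
    stats::uniroot(function(d) tau_of_d(d, r, v) - tau,
                   lower = opt$minimum, upper = upper, tol = 1e-9)$root
  }, numeric(1))
}

#' Estimate neuronal latency from escape timing data
#'
#' Regresses the mean time to collision at escape on the ratio of object
#' size to approach speed (a proxy for tau) and returns the intercept,
#' which estimates the neuronal latency \eqn{\delta}: the escape delay that
#' remains when the looming cue itself extrapolates to zero.
#'
#' @param size_speed_ratio Object size / approach speed, s. Length >= 3.
#' @param mean_ttc_flight Mean time to collision at escape, s.
#'
#' @return Estimated latency in s (the OLS intercept).
#' @examples
#' estimate_neuronal_latency(c(0.01, 0.02, 0.05), 2 * c(0.01, 0.02, 0.05) + 0.08)
#' @export
estimate_neuronal_latency <- function(size_speed_ratio, mean_ttc_flight) {
  if (length(size_speed_ratio) != length(mean_ttc_flight)) {
    abort("Inputs must have equal length.")
  }
  if (length(size_speed_ratio) < 3L) {
    abort("At least 3 paired points are required.")
  }
  if (any(size_speed_ratio < 0)) abort("Size/speed ratios must be non-negative.")
  if (sd(size_speed_ratio) == 0) {
    abort("Size/speed ratios have zero variance; the slope is undefined.")
  }
  unname(coef(lm(mean_ttc_flight ~ size_speed_ratio))[1L])
}

#' Parameters of the visual cue model
#'
#' The visual cue model compares the profile-size-to-distance ratio
#' \eqn{A(d) = \kappa w / d} of the approaching object at two distances and
#' triggers escape when the change \eqn{\Delta A} exceeds a threshold.
#' Habitat complexity attenuates the perceived change (vegetation 1 blocks
#' it entirely) and an individual-difference term shifts it around the
#' population mean.
#'
#' @param delta_alpha_threshold Escape threshold on the change in the
#'   profile-size/distance ratio. Must be positive.
#' @param first_distance First (farther) viewing distance, m; typically the
#'   maximum detection distance.
#' @param second_distance Second (closer) assessment distance, m.
#' @param shape_coefficient Shape-specific coefficient \eqn{\kappa};
#'   1 for a circular profile.
#' @param vegetation Habitat complexity in \[0, 1\]; 0 = open habitat.
#' @param individual_difference Deviation of the individual's perceived
#'   change from the population mean (same units as \eqn{\Delta A}).
#'
#' @return A `visual_cue_params` object.
#' @export
visual_cue_params <- function(delta_alpha_threshold,
                              first_distance,
                              second_distance = first_distance / 2,
                              shape_coefficient = 1,
                              vegetation = 0,
                              individual_difference = 0) {
  if (delta_alpha_threshold <= 0) abort("`delta_alpha_threshold` must be positive.")
  if (!(first_distance > second_distance && second_distance > 0)) {
    abort("Distances must satisfy first_distance > second_distance > 0.")
  }
  if (shape_coefficient <= 0) abort("`shape_coefficient` must be positive.")
  if (vegetation < 0 || vegetation > 1) abort("`vegetation` must lie in [0, 1].")
  structure(
    list(
      delta_alpha_threshold = delta_alpha_threshold,
      first_distance = first_distance,
      second_distance = second_distance,
      shape_coefficient = shape_coefficient,
      vegetation = vegetation,
      individual_difference = individual_difference
    ),
    class = "visual_cue_params"
  )
}

#' Predicted FID under the visual cue model
#'
#' Solves for the distance at which the change in the profile-size/distance
#' ratio, relative to the first viewing distance, reaches the escape
#' threshold. The model function
#' \deqn{g(d) = \Delta A_{thr} - \left[(1 - veg)\,(\kappa w / d - \kappa w / d_1)
#'   + ind\right]}
#' is monotone in `d` on `(0, d_1]`; the root is located by bisection to an
#' absolute tolerance of 1e-6 m.
#'
#' @param params A [visual_cue_params()] object.
#' @param object_width Frontal width of the approaching object, m.
#' @param tol Absolute bisection tolerance, m.
#'
#' @return Predicted FID in m, in `(0, first_distance]`.
#' @examples
#' p <- visual_cue_params(delta_alpha_threshold = 0.05, first_distance = 475)
#' visual_cue_fid(p, 1.73)
#' @export
visual_cue_fid <- function(params, object_width, tol = 1e-6) {
  if (!inherits(params, "visual_cue_params")) {
    abort("`params` must be a `visual_cue_params` object.")
  }
  if (object_width <= 0) abort("`object_width` must be positive.")
  kw <- params$shape_coefficient * object_width
  d1 <- params$first_distance
  g <- function(d) {
    params$delta_alpha_threshold -
      ((1 - params$vegetation) * (kw / d - kw / d1) +
         params$individual_difference)
  }
  lower <- tol / 2
  if (g(d1) <= 0) return(d1) # threshold already met at the first distance
  if (g(lower) > 0) {
    abort("No solution: the escape threshold is unreachable on (0, first_distance].")
  }
  # g is increasing in d here: g(lower) <= 0 < g(d1)
  hi <- d1; lo <- lower
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (hi + lo) / 2
}
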
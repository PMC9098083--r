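#' Species profile for escape-model parameterization
#'
#' Bundles the species-level parameters consumed by the escape-behavior
#' models: body mass, visual acuity, escape locomotion, and the behavioral
#' bias of the Bayesian optimal escape model. The default escape kinematics
#' follow the brown-headed cowbird (*Molothrus ater*), the species with the
#' widest published range of experimental vehicle-approach speeds: an escape
#' speed of 3.75 m/s and an escape distance of 3 m (roughly one road lane),
#' giving an escape time of 0.80 s.
#'
#' @param body_mass Body mass in kg. Must be positive.
#' @param visual_acuity Visual acuity in cycles per degree (optional; only
#'   the perceptual limits hypothesis uses it).
#' @param escape_speed Speed at which the animal clears the vehicle path, m/s.
#' @param escape_distance Distance needed to clear the vehicle path, m.
#' @param escape_time Time needed to clear the vehicle path, s. Defaults to
#'   `escape_distance / escape_speed` and must agree with it when supplied.
#' @param behavioral_bias Bias coefficient \eqn{\alpha \in [0, 1]} of the
#'   Bayesian optimal escape model; 0.5 means no prior bias.
#'
#' @return A `species_profile` object (a named list).
#' @examples
#' cowbird <- species_profile(body_mass = 0.0439, visual_acuity = 4.82)
#' cowbird$escape_time
#' @export
species_profile <- function(body_mass,
                            visual_acuity = NULL,
                            escape_speed = 3.75,
                            escape_distance = 3,
                            escape_time = escape_distance / escape_speed,
                            behavioral_bias = 0.5) {
  stopifnot(is.numeric(body_mass), length(body_mass) == 1L)
  if (body_mass <= 0) abort("`body_mass` must be positive (kg).")
  if (!is.null(visual_acuity) && visual_acuity <= 0) {
    abort("`visual_acuity` must be positive (cycles per degree).")
  }
  if (escape_speed <= 0 || escape_distance <= 0 || escape_time <= 0) {
    abort("Escape speed, distance and time must all be positive.")
  }
  if (abs(escape_time - escape_distance / escape_speed) > 1e-6 * escape_time) {
    abort("`escape_time` must equal `escape_distance / escape_speed`.")
  }
  if (behavioral_bias < 0 || behavioral_bias > 1) {
    abort("`behavioral_bias` must lie in [0, 1].")
  }
  structure(
    list(
      body_mass = body_mass,
      visual_acuity = visual_acuity,
      escape_speed = escape_speed,
      escape_distance = escape_distance,
      escape_time = escape_time,
      behavioral_bias = behavioral_bias
    ),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile>\n")
  cat(sprintf("  body mass:       %.4g kg\n", x$body_mass))
  if (!is.null(x$visual_acuity)) {
    cat(sprintf("  visual acuity:   %.3g cycles/degree\n", x$visual_acuity))
  }
  cat(sprintf("  escape:          %.3g m at %.3g m/s (%.3g s)\n",
              x$escape_distance, x$escape_speed, x$escape_time))
  cat(sprintf("  behavioral bias: %.2f\n", x$behavioral_bias))
  invisible(x)
}

#' Vehicle profile for an encounter
#'
#' Describes the approaching vehicle. The frontal profile is treated as a
#' circle of the given width (diameter); 1.73 m is the assumed width of a
#' car. All in-scope computations assume a direct approach (angle 0) at
#' constant speed.
#'
#' @param width Frontal profile width (diameter), m.
#' @param approach_speed Approach speed, m/s.
#' @param approach_angle Approach angle in degrees; must be 0.
#'
#' @return A `vehicle_profile` object with fields `width`, `radius`
#'   (`width / 2`), `approach_speed` and `approach_angle`.
#' @examples
#' car <- vehicle_profile(approach_speed = 30)
#' car$radius
#' @export
vehicle_profile <- function(width = 1.73, approach_speed, approach_angle = 0) {
  if (width <= 0) abort("`width` must be positive (m).")
  if (approach_speed <= 0) abort("`approach_speed` must be positive (m/s).")
  if (approach_angle != 0) {
    abort("Only direct approaches (`approach_angle = 0`) are supported.")
  }
  structure(
    list(
      width = width,
      radius = width / 2,
      approach_speed = approach_speed,
      approach_angle = approach_angle
    ),
    class = "vehicle_profile"
  )
}

#' Distance ladder of one animal-vehicle encounter
#'
#' Validates and assembles the ordered distances of a single encounter --
#' starting distance (SD), detection distance (DD), alert distance (AD) and
#' flight initiation distance (FID) -- together with the time to collision
#' at escape. The ladder must satisfy `0 <= FID <= AD <= SD`; the detection
#' distance, when supplied, must also fall within `[FID, SD]`.
#'
#' @param fid Flight initiation distance, m.
#' @param ad Alert distance, m.
#' @param sd_dist Starting distance, m (defaults to `ad`).
#' @param dd Detection distance, m (defaults to `ad`, the common modeling
#'   assumption that animals become alert at detection).
#' @param approach_speed Constant approach speed, m/s; used to derive the
#'   time to collision `fid / approach_speed`.
#'
#' @return A one-row tibble with columns `sd`, `dd`, `ad`, `fid`, `ttc`.
#' @examples
#' encounter_distances(fid = 28, ad = 48.5, approach_speed = 30)
#' @export
encounter_distances <- function(fid, ad, sd_dist = ad, dd = ad,
                                approach_speed = NULL) {
  vals <- c(fid = fid, ad = ad, sd = sd_dist, dd = dd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("All encounter distances must be finite and non-negative.")
  }
  if (fid > ad || ad > sd_dist || dd > sd_dist || dd < fid) {
    abort("Encounter distances must satisfy 0 <= FID <= AD <= SD and FID <= DD <= SD.")
  }
  ttc <- if (is.null(approach_speed)) {
    NA_real_
  } else {
    if (approach_speed <= 0) abort("`approach_speed` must be positive (m/s).")
    fid / approach_speed
  }
  tibble(sd = sd_dist, dd = dd, ad = ad, fid = fid, ttc = ttc)
}
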
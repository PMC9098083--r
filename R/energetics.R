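#' Metabolic power of short escape flight
#'
#' Allometric power requirement of short flights in passerine-sized birds:
#' \eqn{W = 61.72\, M_b^{0.79}} watts, with body mass \eqn{M_b} in kg.
#'
#' @param body_mass Body mass, kg. Vectorized.
#' @return Flight power in W.
#' @examples
#' flight_power(0.0439) # brown-headed cowbird, ~5.2 W
#' @export
flight_power <- function(body_mass) {
  if (any(body_mass <= 0)) abort("`body_mass` must be positive (kg).")
  61.72 * body_mass^0.79
}

#' Daily energy expenditure from body mass
#'
#' Linear allometry of avian daily energy expenditure,
#' \eqn{DEE = -0.80 + 0.66\, M} kJ/day with body mass \eqn{M} in grams.
#' Note the gram scale: the escape-cost allometry ([flight_power()]) takes
#' kilograms, this one grams, as each was originally fitted.
#'
#' @param body_mass_g Body mass, g. Vectorized.
#' @return Daily energy expenditure in kJ/day.
#' @examples
#' daily_energy_expenditure(43.9) # ~28.2 kJ/day
#' @export
daily_energy_expenditure <- function(body_mass_g) {
  if (any(body_mass_g <= 0)) abort("`body_mass_g` must be positive (g).")
  dee <- -0.80 + 0.66 * body_mass_g
  if (any(dee <= 0)) {
    abort("Body mass too small: the DEE allometry predicts a non-positive budget.")
  }
  dee
}

#' Energetic cost of one escape flight
#'
#' Escape cost is flight power times the escape time needed to clear the
#' vehicle path, converted from J to kJ:
#' `flight_power(body_mass) * escape_time / 1000`.
#'
#' @param species A [species_profile()].
#' @return Escape cost in kJ.
#' @examples
#' escape_cost(species_profile(body_mass = 0.0439)) # ~4.2e-3 kJ
#' @export
escape_cost <- function(species) {
  stopifnot(inherits(species, "species_profile"))
  if (species$escape_distance == 0) return(0)
  flight_power(species$body_mass) * species$escape_time / 1000
}

#' Allometric maximum escape speed
#'
#' Scales the maximum escape speed with body mass as \eqn{M^{1/6}}, the
#' classic allometry of avian flight speed, anchored at the observed
#' brown-headed cowbird escape speed (3.75 m/s at 43.9 g). Used to build
#' species profiles for the Bayesian optimal escape model when only body
#' mass is known.
#'
#' @param body_mass Body mass, kg. Vectorized.
#' @param reference_speed,reference_mass Anchor point of the allometry
#'   (m/s, kg).
#' @param exponent Allometric exponent.
#' @return Maximum escape speed in m/s.
#' @examples
#' escape_speed_allometry(c(0.0115, 0.2674, 6.22))
#' @export
escape_speed_allometry <- function(body_mass,
                                   reference_speed = 3.75,
                                   reference_mass = 0.0439,
                                   exponent = 1 / 6) {
  if (any(body_mass <= 0)) abort("`body_mass` must be positive (kg).")
  reference_speed * (body_mass / reference_mass)^exponent
}
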
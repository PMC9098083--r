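# Small simulation configurations shared across tests.

tiny_grid <- function(slopes = c(-5, 0, 5), n_iterations = 2, seed = 101) {
  simulate_sensitivity_grid(
    sensitivity_config(slopes = slopes, n_iterations = n_iterations,
                       seed = seed))
}

cowbird_profile <- function() {
  species_profile(body_mass = 0.0439, visual_acuity = 4.82)
}
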
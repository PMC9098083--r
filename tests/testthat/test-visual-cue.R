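test_that("visual-cue bisection matches the algebraic closed form", {
  # with no vegetation or individual term the root has a closed form:
  # d* = kw / (threshold + kw / d1)
  cases <- expand.grid(thr = c(0.01, 0.05, 0.2), d1 = c(100, 475),
                       kappa = c(1, 1.4))
  for (i in seq_len(nrow(cases))) {
    thr <- cases$thr[i]; d1 <- cases$d1[i]; kappa <- cases$kappa[i]
    p <- visual_cue_params(delta_alpha_threshold = thr, first_distance = d1,
                           shape_coefficient = kappa)
    kw <- kappa * 1.73
    expect_equal(visual_cue_fid(p, 1.73), kw / (thr + kw / d1),
                 tolerance = 1e-5)
  }
})

test_that("visual-cue root is converged to tolerance and bounded by the bracket", {
  p <- visual_cue_params(delta_alpha_threshold = 0.05, first_distance = 475)
  root <- visual_cue_fid(p, 1.73)
  g <- function(d) 0.05 - (1.73 / d - 1.73 / 475)
  expect_lte(abs(g(root)), max(abs(g(root - 1e-6)), abs(g(root + 1e-6))))
  expect_true(root > 0 && root <= 475)
  # vegetation attenuates the cue, pushing the root closer
  p_veg <- visual_cue_params(delta_alpha_threshold = 0.05,
                             first_distance = 475, vegetation = 0.5)
  expect_lt(visual_cue_fid(p_veg, 1.73), root)
})

test_that("an unreachable visual-cue threshold raises a no-solution error", {
  # the cue change is bounded only by the tiny-distance cutoff; an enormous
  # threshold stays unreachable
  p <- visual_cue_params(delta_alpha_threshold = 1e8, first_distance = 100)
  expect_error(visual_cue_fid(p, 1.73), "No solution")
  # threshold already met at the first distance returns the bracket edge
  p2 <- visual_cue_params(delta_alpha_threshold = 0.05, first_distance = 100,
                          individual_difference = 0.1)
  expect_equal(visual_cue_fid(p2, 1.73), 100)
  expect_error(visual_cue_params(delta_alpha_threshold = -1,
                                 first_distance = 100), "positive")
  expect_error(visual_cue_params(0.05, first_distance = 10,
                                 second_distance = 20), "first_distance")
})
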
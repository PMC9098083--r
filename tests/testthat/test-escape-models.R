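test_that("perceptual-limit distance follows visual-angle trigonometry", {
  # cowbird acuity vs. a car-width object: ~475 m resolution distance
  expect_equal(perceptual_limit_fid(4.82, 1.73), 477.766, tolerance = 1e-4)
  # doubling acuity doubles the distance in the small-angle regime
  expect_equal(perceptual_limit_fid(9.64, 1.73),
               2 * perceptual_limit_fid(4.82, 1.73), tolerance = 1e-3)
  # vanishing object width drives the distance to zero
  expect_lt(perceptual_limit_fid(4.82, 1e-9), 1e-6)
  # strictly increasing in acuity and width
  a <- seq(1, 10, by = 0.5)
  expect_true(all(diff(perceptual_limit_fid(a, 1.73)) > 0))
  w <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(perceptual_limit_fid(4.82, w)) > 0))
  # small-angle approximation agrees within 0.1%
  for (acuity in c(1, 4.82, 10)) {
    for (width in c(0.5, 1.73, 2)) {
      approx <- width * acuity * 180 / pi
      expect_equal(perceptual_limit_fid(acuity, width), approx,
                   tolerance = 1e-3)
    }
  }
  expect_error(perceptual_limit_fid(-1, 1.73), "positive")
  expect_error(perceptual_limit_fid(4.82, 0), "positive")
})

test_that("latency correction of looming FID subtracts distance covered and floors at 0", {
  expect_equal(looming_fid(30, 0.1, 50), 25)
  expect_equal(looming_fid(30, 0, c(1, 50, 100)), rep(30, 3))
  expect_equal(looming_fid(5, 0.1, 100), 0)
  # non-increasing in latency and in speed, never negative
  lat <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(looming_fid(30, lat, 60)) <= 0))
  v <- seq(1, 100, by = 1)
  expect_true(all(diff(looming_fid(30, 0.1, v)) <= 0))
  expect_true(all(looming_fid(30, 0.1, v) >= 0))
  expect_error(looming_fid(30, -0.1, 50), "non-negative")
  expect_error(looming_fid(30, 0.1, 0), "positive")
})

test_that("tau-threshold distance matches a numeric root of theta/theta'", {
  # independent oracle: tau on a fine distance grid from the same geometry
  tau_grid <- function(r, v, d) atan(r / d) * (d^2 + r^2) / (r * v)
  cases <- list(c(1.0, 0.865, 30), c(0.5, 0.865, 30), c(1.0, 0.865, 60),
                c(0.5, 2.5, 15))
  for (cs in cases) {
    tau <- cs[1]; r <- cs[2]; v <- cs[3]
    # restrict the oracle to the approaching branch, where tau still falls
    d <- seq(2 * r, 10 * tau * v + 10 * r, by = 1e-4)
    oracle <- d[which.min(abs(tau_grid(r, v, d) - tau))]
    expect_equal(looming_base_from_tau(tau, r, v), oracle, tolerance = 1e-3)
  }
  # tau never falls below ~pi r / (2 v): such thresholds resolve to contact
  expect_equal(looming_base_from_tau(0.2, 2.5, 15), 0)
  # small-angle limit: distance ~ tau * speed, doubling speed doubles it
  expect_equal(looming_base_from_tau(1, 0.865, 30), 30, tolerance = 0.05)
  expect_equal(looming_base_from_tau(1, 0.865, 60) /
                 looming_base_from_tau(1, 0.865, 30), 2, tolerance = 0.01)
  # threshold -> 0 means escape at contact
  expect_lt(looming_base_from_tau(1e-6, 0.865, 30), 1e-3)
})

test_that("neuronal latency is recovered as the TTC-vs-size/speed intercept", {
  ratios <- c(0.01, 0.02, 0.05)
  expect_equal(estimate_neuronal_latency(ratios, 2 * ratios + 0.08), 0.08)
  # noisy recovery, checked against the closed-form OLS intercept
  set.seed(42)
  r <- runif(50, 0.005, 0.06)
  ttc <- 2 * r + 0.08 + rnorm(50, 0, 0.005)
  b <- sum((r - mean(r)) * (ttc - mean(ttc))) / sum((r - mean(r))^2)
  a <- mean(ttc) - b * mean(r)
  est <- estimate_neuronal_latency(r, ttc)
  expect_equal(est, a, tolerance = 1e-10)
  expect_lt(abs(est - 0.08), 0.01)
  expect_error(estimate_neuronal_latency(rep(0.02, 5), rnorm(5)), "variance")
  expect_error(estimate_neuronal_latency(c(0.01, 0.02), c(1, 2)), "3")
})
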
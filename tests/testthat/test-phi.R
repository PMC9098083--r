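test_that("phi index is the standardized proximity to the 1:1 origin line", {
  expect_equal(phi_index(c(10, 20), c(5, 10)), 0.5)
  ad <- runif(20, 10, 60)
  expect_equal(phi_index(ad, ad), 1)
  expect_equal(phi_index(ad, rep(0, 20)), 0)
  # bounded in [0, 1] across random valid inputs
  set.seed(7)
  for (i in 1:20) {
    ad <- runif(30, 1, 100)
    fid <- runif(30, 0, ad)
    phi <- phi_index(ad, fid)
    expect_gte(phi, 0)
    expect_lte(phi, 1)
  }
  expect_error(phi_index(c(10, 20), c(11, 5)), "FID <= AD")
  expect_error(phi_index(c(0, 20), c(0, 5)), "positive")
  expect_error(phi_index(c(10, 20), 5), "equal length")
})

test_that("phi significance is calibrated against the uniform null", {
  # an observed phi of 1 is virtually unreachable under the null
  expect_lt(phi_significance(runif(25, 10, 80), 1, n_sim = 500, seed = 1),
            0.01)
  expect_equal(phi_significance(runif(25, 10, 80), 0, n_sim = 200, seed = 2),
               1)
  # E[phi] = 0.5 under the uniform null: observing 0.5 gives p ~ 0.5
  p <- phi_significance(rep(100, 30), 0.5, n_sim = 4000, seed = 3)
  expect_lt(abs(p - 0.5), 0.05)
})

test_that("FEAR predicted FID combines the origin-line slope with the 5th AD percentile", {
  ad <- c(30, 40, 50, 60, 70)
  q5 <- unname(quantile(ad, 0.05))
  expect_equal(fear_predicted_fid(ad, ad), q5)
  expect_equal(fear_predicted_fid(ad, 0.5 * ad), 0.5 * q5)
  # noisy through-origin slope recovery vs the closed-form estimator
  set.seed(11)
  ad <- rnorm(100, 50, 10)
  fid <- pmin(pmax(0.6 * ad + rnorm(100, 0, 2), 0), ad)
  b_oracle <- sum(ad * fid) / sum(ad^2)
  expect_lt(abs(b_oracle - 0.6), 0.02)
  expect_equal(fear_predicted_fid(ad, fid),
               b_oracle * unname(quantile(ad, 0.05)), tolerance = 1e-10)
  expect_error(fear_predicted_fid(c(10, 20), c(5, 5)), "3")
})
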
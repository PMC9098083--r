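test_that("Bayesian escape covers its limiting cases", {
  cb <- cowbird_profile()
  # fleeing is free: flee at detection
  expect_equal(bayesian_fid(50, 30, cb, cost_flee = 0), 50)
  # no perceived risk: never flee
  no_risk <- bayes_risk(speed_cue = function(approach_speed, species) 0)
  expect_equal(bayesian_fid(50, 30, cb, risk = no_risk), 0)
  # result always within [0, AD]
  set.seed(5)
  for (i in 1:10) {
    ad <- runif(1, 5, 80)
    v <- runif(1, 1, 100)
    fid <- bayesian_fid(ad, v, cb)
    expect_gte(fid, 0)
    expect_lte(fid, ad)
  }
  expect_error(bayesian_fid(-1, 30, cb), "positive")
  expect_error(bayesian_fid(50, 0, cb), "positive")
  bad_risk <- bayes_risk(speed_cue = function(approach_speed, species) 2)
  expect_error(bayesian_fid(50, 30, cb, risk = bad_risk), "\\[0, 1\\]")
})

test_that("the 0.01 m scan agrees with a 10x finer brute-force scan", {
  cb <- cowbird_profile()
  # force the flee threshold into the interior so the scan is non-trivial
  dee <- daily_energy_expenditure(43.9)
  for (frac in c(0.1, 0.45, 0.8)) {
    for (v in c(2, 30, 90)) {
      coarse <- bayesian_fid(50, v, cb, cost_flee = frac * dee, step = 0.01)
      fine <- bayesian_fid(50, v, cb, cost_flee = frac * dee, step = 0.001)
      expect_lte(abs(coarse - fine), 0.01)
    }
  }
})

test_that("attack probability is a Bayes-weighted product of the two cues", {
  cb <- cowbird_profile()
  # at the alert distance no ground has been closed: probability 0
  expect_equal(attack_probability(50, 50, 30, cb), 0)
  # at contact with both cues firing the probability saturates at 1
  expect_equal(attack_probability(0, 50, 30, cb), 1)
  # monotone in closing distance
  d <- seq(49, 1, by = -1)
  p <- attack_probability(d, 50, 2, cb)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  # with no prior bias and a saturated speed cue the posterior is 1 below AD
  expect_equal(attack_probability(49.99, 50, 30, cb), 1)
})
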
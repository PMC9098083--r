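test_that("allometric energetics follow the published equations and units", {
  expect_equal(flight_power(1), 61.72)
  expect_equal(flight_power(0.0439), 61.72 * 0.0439^0.79)
  expect_lt(abs(flight_power(0.0439) - 5.22), 0.05)
  m <- seq(0.01, 6, length.out = 30)
  expect_true(all(diff(flight_power(m)) > 0))
  expect_error(flight_power(0), "positive")

  expect_equal(daily_energy_expenditure(43.9), 28.174)
  expect_equal(daily_energy_expenditure(10), 5.8)
  expect_error(daily_energy_expenditure(1.21), "non-positive")

  # escape cost = power x escape time, J -> kJ
  sp1 <- species_profile(body_mass = 1, escape_speed = 3,
                         escape_distance = 3) # 1 s escape
  expect_equal(escape_cost(sp1), 0.06172)
  expect_equal(escape_cost(cowbird_profile()),
               61.72 * 0.0439^0.79 * 0.8 / 1000)
  expect_lt(abs(escape_cost(cowbird_profile()) - 4.18e-3), 1e-5)
})

test_that("f-squared transform and Cohen classification behave as specified", {
  expect_equal(f_squared(0), 0)
  expect_equal(f_squared(0.5), 1)
  expect_equal(f_squared(0.02 / 1.02), 0.02) # small-effect boundary inverse
  r2 <- seq(0, 0.95, by = 0.05)
  f2 <- f_squared(r2)
  expect_true(all(diff(f2) > 0))
  expect_true(all(f2 >= r2))
  expect_error(f_squared(1), "infinite")
  expect_error(f_squared(-0.1), "\\[0, 1\\)")

  expect_equal(as.character(classify_effect(c(0, 0.019, 0.021, 0.02,
                                              0.15, 0.2, 0.35, 5))),
               c("below_small", "below_small", "small", "small",
                 "medium", "medium", "large", "large"))
  expect_error(classify_effect(-0.01), "non-negative")
})

test_that("CVAS converts the FID threshold and escape time into km/h", {
  expect_equal(round(cvas(28, 0.80)), 126)
  expect_equal(round(cvas(70, 2.1)), 120)
  expect_equal(round(cvas(150, 2.1)), 257)
  expect_equal(cvas(0, 2), 0)
  # linear in the FID threshold
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(cvas(k * 28, 0.8), k * cvas(28, 0.8))
  }
  expect_error(cvas(28, 0), "positive")
  rep <- cvas_report(28, 0.8, quiet = TRUE)
  expect_equal(rep$cvas_kmh, 126)
  expect_equal(rep$cvas_ms, 35)
})
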
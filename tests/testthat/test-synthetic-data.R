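test_that("sensitivity grid has the designed shape and censoring", {
  cfg <- sensitivity_config(n_iterations = 1, seed = 1)
  s1 <- simulate_sensitivity_grid(cfg)
  expect_equal(nrow(s1), 7000) # 100 speeds x 70 slopes
  expect_equal(length(unique(s1$slope)), 70)
  expect_equal(length(unique(s1$speed)), 100)
  s2 <- tiny_grid(n_iterations = 3)
  expect_equal(nrow(s2), 3 * 3 * 100)
  expect_true(all(s2$fid >= 0 & s2$fid <= s2$ad))
  expect_true(all(s2$ad > 0))
})

test_that("noise-free draws censor deterministically at both bounds", {
  cfg <- sensitivity_config(slopes = c(-37, 32), speeds = 100,
                            n_iterations = 5, fid_noise_sd = 0, seed = 2)
  s <- simulate_sensitivity_grid(cfg)
  # linear predictor -37*100 + 42.98 << 0 -> censored to 0
  expect_true(all(s$fid[s$slope == -37] == 0))
  # linear predictor 32*100 + 42.98 >> AD -> censored to AD
  expect_equal(s$fid[s$slope == 32], s$ad[s$slope == 32])
})

test_that("the same seed reproduces the collection exactly; different seeds differ", {
  a <- tiny_grid(seed = 31)
  b <- tiny_grid(seed = 31)
  c <- tiny_grid(seed = 32)
  expect_identical(a, b)
  expect_false(identical(a$fid, c$fid))
  w1 <- simulate_slope_window_data(slope_window_config(slopes = 0,
                                                      n_iterations = 3,
                                                      seed = 8))
  w2 <- simulate_slope_window_data(slope_window_config(slopes = 0,
                                                      n_iterations = 3,
                                                      seed = 8))
  expect_identical(w1, w2)
})

test_that("simulated AD moments converge to the configured distribution", {
  cfg <- sensitivity_config(slopes = 0, n_iterations = 100, seed = 3)
  s <- simulate_sensitivity_grid(cfg) # 10,000 AD draws
  n <- nrow(s)
  se_mean <- 10.51 / sqrt(n)
  expect_lt(abs(mean(s$ad) - 48.55), 3 * se_mean)
  se_sd <- 10.51 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(s$ad) - 10.51), 3 * se_sd)
})

test_that("censoring responds monotonically to speed at fixed slope", {
  # slope +/- 0.5 keeps the linear predictor inside the censoring band, so
  # the mean censored FID must track the sign of the slope across speeds
  cfg_neg <- sensitivity_config(slopes = -0.5, speeds = c(10, 50, 90),
                                n_iterations = 600, seed = 4)
  m_neg <- simulate_sensitivity_grid(cfg_neg) |>
    dplyr::group_by(speed) |>
    dplyr::summarise(m = mean(fid)) |>
    dplyr::pull(m)
  expect_true(all(diff(m_neg) <= 0))
  cfg_pos <- sensitivity_config(slopes = 0.5, speeds = c(10, 50, 90),
                                n_iterations = 600, seed = 4)
  m_pos <- simulate_sensitivity_grid(cfg_pos) |>
    dplyr::group_by(speed) |>
    dplyr::summarise(m = mean(fid)) |>
    dplyr::pull(m)
  expect_true(all(diff(m_pos) >= 0))
})

test_that("slope-window data matches the 8-treatment design", {
  cfg <- slope_window_config(slopes = 0, n_iterations = 1, seed = 5)
  w <- simulate_slope_window_data(cfg)
  expect_equal(nrow(w), 160) # 8 treatments x 20 points
  expect_equal(sort(unique(w$speed_kmh)),
               c(60, 90, 120, 150, 180, 210, 240, 360))
  expect_equal(w$speed_mps, w$speed_kmh / 3.6)
  expect_true(all(w$fid >= 0 & w$fid <= w$ad))
  # slope 0 with no noise pins every uncensored FID at the 25 m intercept
  flat <- simulate_slope_window_data(
    slope_window_config(slopes = 0, fid_sd = 0, n_iterations = 1, seed = 6))
  expect_true(all(flat$fid == pmin(25, flat$ad)))
  # the 41-slope grid yields 160 records per slope per iteration
  big <- simulate_slope_window_data(
    slope_window_config(n_iterations = 2, seed = 7))
  expect_equal(nrow(big), 41 * 160 * 2)
})

test_that("the packaged species table matches the review's distributional summaries", {
  fx <- load_species_fixture()
  expect_equal(nrow(fx), 50)
  expect_true(all(fx$ad_m > 0 & fx$fid_m > 0 & fx$body_mass_g > 0))
  rel <- function(x, target) abs(x - target) / abs(target)
  expect_lt(rel(mean(fx$slope_s), -2.12), 0.02)
  expect_lt(rel(sd(fx$slope_s), 10.95), 0.02)
  expect_lt(rel(mean(fx$ad_m), 49.55), 0.02)
  expect_lt(rel(sd(fx$ad_m), 10.51), 0.02)
  expect_lt(rel(mean(fx$fid_m), 43.97), 0.02)
  expect_lt(rel(sd(fx$fid_m), 31.08), 0.02)
  expect_lt(rel(mean(fx$intercept_m), 42.98), 0.02)
  expect_equal(min(fx$body_mass_g), 11.5)
  expect_equal(max(fx$body_mass_g), 6220)
  expect_lt(rel(exp(mean(log(fx$body_mass_g))), 267.4), 0.01)
})
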
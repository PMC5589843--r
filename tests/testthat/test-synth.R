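test_that("lake catalog honours the amplification switch and determinism", {
  one <- generate_lake_catalog(1, seed = 1, amplification = FALSE)
  expect_length(one$scenarios, 1L)
  expect_equal(max(one$scenarios[[1]]$rho) - min(one$scenarios[[1]]$rho),
               diff(range(one$scenarios[[1]]$rho)))
  # amplification off: rho field identical across pixels (no cross-lake link)
  off <- generate_lake_catalog(5, seed = 2, amplification = FALSE,
                               rho_seasonal_amp = 0)
  for (sc in off$scenarios) expect_equal(diff(range(sc$rho)), 0)

  on <- generate_lake_catalog(50, seed = 7, amplification = TRUE)
  mean_rho <- vapply(on$scenarios, function(s) mean(s$rho), numeric(1))
  sp <- cor(mean_rho, log10(on$attributes$median_chla), method = "spearman")
  expect_equal(sp, 1)  # monotone link imposed by construction

  a <- generate_lake_catalog(10, seed = 3)
  b <- generate_lake_catalog(10, seed = 3)
  expect_identical(a, b)
  expect_error(generate_lake_catalog(0), class = "lakecor_invalid_argument")
})

test_that("catalog attributes carry deliberate missingness in non-key fields", {
  cat40 <- generate_lake_catalog(40, seed = 11, missing_frac = 0.3)
  n_miss <- sum(is.na(cat40$attributes[, c("elevation", "perimeter",
                                           "mean_depth",
                                           "median_temperature")]))
  expect_gt(n_miss, 0)
  expect_false(anyNA(cat40$attributes$median_chla))
  expect_false(anyNA(cat40$attributes$lake_id))
})

test_that("simulated observations respect the copula ground truth", {
  sc <- lake_scenario(n_pixels_lat = 4, n_pixels_lon = 4, rho_mean = 0.5,
                      obs_prob = 1, seed = 5)
  sim <- simulate_observations(sc)
  # full coverage: every (pixel, bin, year) cell observed
  expect_equal(nrow(sim$observations), 4 * 4 * 73 * 15)
  expect_true(all(sim$observations$chla > 0))
  expect_true(all(is.finite(sim$observations$lst)))
  # truth table consistency
  expect_equal(sim$truth$strata$true_tau,
               (2 / pi) * asin(sim$truth$strata$rho))
  expect_equal(sim$truth$true_r_lake, mean(sim$truth$strata$true_tau))
  # determinism
  expect_identical(sim$observations,
                   simulate_observations(sc)$observations)
})

test_that("independence and vacuous-sampling edge cases", {
  sc0 <- lake_scenario(n_pixels_lat = 3, n_pixels_lon = 3, rho_mean = 0,
                       obs_prob = 1, seed = 6)
  sim0 <- simulate_observations(sc0)
  fld <- correlation_field(subdivide(sim0$observations))
  expect_lt(abs(mean(fld$tau)), 0.03)  # centred on zero over many strata

  sc_none <- lake_scenario(n_pixels_lat = 3, n_pixels_lon = 3,
                           obs_prob = 0, seed = 6)
  sim_none <- simulate_observations(sc_none)
  expect_equal(nrow(sim_none$observations), 0L)
  expect_gt(nrow(sim_none$truth$strata), 0L)
})

test_that("scenario validation rejects inadmissible parameters", {
  expect_error(lake_scenario(years = 5), class = "lakecor_invalid_argument")
  expect_error(lake_scenario(rho_mean = 1.2),
               class = "lakecor_invalid_argument")
  expect_error(lake_scenario(obs_prob = 1.5),
               class = "lakecor_invalid_argument")
})

test_that("in-situ samples reproduce satellite values in the zero-error case", {
  sc <- lake_scenario(n_pixels_lat = 3, n_pixels_lon = 3, seed = 8)
  sim <- simulate_observations(sc)
  s <- simulate_insitu_samples(sc, sim$observations, error_sd_lst = 0,
                               error_bias_chla = 1, n_samples = 25,
                               seed = 9)
  expect_equal(nrow(s), 25L)
  m <- match_nearest(s, sim$observations, max_km = 1, max_days = 0)
  expect_equal(m$insitu_lst, m$satellite_lst)
  expect_equal(m$insitu_chla, m$satellite_chla)
})

test_that("a pure multiplicative chl-a bias shifts the SMA intercept, not the slope", {
  sc <- lake_scenario(n_pixels_lat = 3, n_pixels_lon = 3, seed = 12)
  sim <- simulate_observations(sc)
  s <- simulate_insitu_samples(sc, sim$observations, error_sd_lst = 0,
                               error_bias_chla = 2, n_samples = 60,
                               seed = 13)
  m <- match_nearest(s, sim$observations, max_km = 1, max_days = 0)
  fit <- sma_fit(log10(m$satellite_chla), log10(m$insitu_chla))
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, log10(2), tolerance = 1e-10)
})

test_that("in-situ sampling boundary conditions", {
  sc <- lake_scenario(n_pixels_lat = 2, n_pixels_lon = 2, seed = 14)
  sim <- simulate_observations(sc)
  expect_equal(nrow(simulate_insitu_samples(sc, sim$observations,
                                            n_samples = 3, seed = 1)), 3L)
  expect_error(simulate_insitu_samples(sc, sim$observations, n_samples = 2,
                                       seed = 1),
               class = "lakecor_invalid_argument")
  expect_error(simulate_insitu_samples(sc, sim$observations,
                                       n_samples = nrow(sim$observations) + 1,
                                       seed = 1),
               class = "lakecor_invalid_argument")
})
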
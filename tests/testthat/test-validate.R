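test_that("SMA recovers exact linear relations and the closed-form fixture", {
  x <- c(1, 2, 3, 4, 5, 6)
  fit <- sma_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$slope_ci_low <= 2 && 2 <= fit$slope_ci_high)
  # 10-point fixture frozen from the direct-formula oracle
  xf <- c(7.621, 10.777, 9.311, 8.904, 11.961, 9.527, 11.619, 8.51, 9.48,
          9.634)
  yf <- c(17.544, 25.035, 21.369, 19.294, 27.304, 20.569, 24.703, 20.832,
          21.612, 20.144)
  f <- sma_fit(xf, yf)
  expect_equal(f$slope, 2.1846149203261045)
  expect_equal(f$intercept, 0.57468451957756628)
  expect_equal(f$r_squared, 0.8850701765498501)
})

test_that("SMA identities: symmetry, scale equivariance, sign handling", {
  set.seed(801)
  for (i in 1:10) {
    x <- rnorm(20)
    y <- 0.6 * x + rnorm(20, 0, 0.7)
    f_xy <- sma_fit(x, y)
    f_yx <- sma_fit(y, x)
    expect_equal(f_xy$slope * f_yx$slope, 1, tolerance = 1e-10)
    f_sc <- sma_fit(x, 3.5 * y)
    expect_equal(f_sc$slope, 3.5 * f_xy$slope, tolerance = 1e-12)
    f_neg <- sma_fit(x, -y)
    expect_equal(f_neg$slope, -f_xy$slope, tolerance = 1e-12)
  }
  expect_error(sma_fit(rep(1, 5), rnorm(5)),
               class = "lakecor_degenerate_fit")
  expect_error(sma_fit(1:2, 2:3), class = "lakecor_invalid_argument")
})

test_that("nearest-coincident matching applies bounds and tie-breaks", {
  grid <- data.frame(lake_id = "L",
                     lat = c(45.05, 45.05, 45.15),
                     lon = c(10.05, 10.05, 10.05),
                     date = as.Date(c("2005-06-10", "2005-06-12",
                                      "2005-06-10")),
                     lst = c(10, 11, 12), chla = c(1, 2, 3))
  exact <- data.frame(date = as.Date("2005-06-10"), lat = 45.05, lon = 10.05,
                      insitu_lst = 10.2, insitu_chla = 1.1)
  m <- match_nearest(exact, grid)
  expect_equal(m$satellite_lst, 10)
  expect_equal(m$spatial_offset_km, 0)
  expect_equal(m$temporal_offset_days, 0)
  # equidistant cells: smaller temporal offset wins
  tie <- data.frame(date = as.Date("2005-06-12"), lat = 45.05, lon = 10.05,
                    insitu_lst = 11, insitu_chla = 2)
  expect_equal(match_nearest(tie, grid)$satellite_lst, 11)
  # out-of-bounds sample dropped and counted
  far <- data.frame(date = as.Date("2005-06-10"), lat = 48, lon = 10.05,
                    insitu_lst = 1, insitu_chla = 1)
  out <- match_nearest(far, grid)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("validation report reflects identity, pure bias, and small-n omission", {
  set.seed(802)
  n <- 40
  matched <- data.frame(insitu_lst = rnorm(n, 15, 3),
                        insitu_chla = rlnorm(n))
  matched$satellite_lst <- matched$insitu_lst
  matched$satellite_chla <- matched$insitu_chla
  rep1 <- validation_report(matched)
  expect_equal(rep1$lst$mae, 0)
  expect_equal(rep1$lst$sma$slope, 1)
  expect_equal(rep1$lst$pearson_r, 1)
  expect_true(rep1$lst$ci_covers_1)
  # constant additive offset: MAE equals the offset, slope stays 1
  matched$satellite_lst <- matched$insitu_lst + 0.7
  rep2 <- validation_report(matched)
  expect_equal(rep2$lst$mae, 0.7)
  expect_equal(rep2$lst$sma$slope, 1, tolerance = 1e-12)
  # lake-level section omitted below 3 lakes
  rep3 <- validation_report(matched, lake_pairs = list(
    medians = data.frame(insitu = c(1, 2), satellite = c(1, 2))))
  expect_null(rep3$lake_level$medians)
  expect_match(rep3$lake_level_notice, "fewer than 3")
})
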
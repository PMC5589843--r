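mk_grid <- function(lat, lon, value, date = as.Date("2005-06-10")) {
  data.frame(lat = lat, lon = lon, date = date, value = value)
}

test_that("spatial median filter reduces cells by the median convention", {
  g <- mk_grid(c(45.01, 45.04, 45.08), c(10.02, 10.03, 10.06), c(1, 2, 100))
  out <- spatial_median_subset(g)
  expect_equal(nrow(out), 1L)
  expect_equal(out$value, 2)
  expect_equal(out$lat, 45.05)
  # even-count cell uses the mean of the central order statistics
  g4 <- mk_grid(rep(45.02, 4), rep(10.02, 4), c(1, 2, 3, 4))
  expect_equal(spatial_median_subset(g4)$value, 2.5)
  expect_equal(spatial_median_subset(g4)$value,
               mean(sort(c(1, 2, 3, 4))[2:3]))  # sorting oracle
})

test_that("spatial filter is idempotent at matching resolution and contained", {
  set.seed(301)
  g <- mk_grid(45 + runif(60, 0, 0.5), 10 + runif(60, 0, 0.5), rnorm(60))
  once <- spatial_median_subset(g)
  twice <- spatial_median_subset(once)
  expect_equal(twice[order(twice$lat, twice$lon), ],
               once[order(once$lat, once$lon), ], ignore_attr = TRUE)
  expect_true(all(once$value >= min(g$value) & once$value <= max(g$value)))
  # empty input and invalid cell size
  expect_equal(nrow(spatial_median_subset(g[0, ])), 0L)
  expect_error(spatial_median_subset(g, cell_size = 0),
               class = "lakecor_invalid_argument")
})

test_that("temporal median filter bins by 5 days anchored at Jan 1", {
  d <- data.frame(lat = 45.05, lon = 10.05,
                  date = as.Date("2005-01-01") + 0:9,
                  value = c(10, 11, 12, 13, 14, rep(7, 5)))
  out <- temporal_median_subset(d)
  out <- out[order(out$doy_bin), ]
  expect_equal(out$doy_bin, c(1L, 2L))
  expect_equal(out$value, c(12, 7))
  # singleton bin passes through; constant series unchanged
  s1 <- temporal_median_subset(data.frame(lat = 1, lon = 1,
                                          date = as.Date("2005-03-03"),
                                          value = 42))
  expect_equal(s1$value, 42)
  const <- data.frame(lat = 1, lon = 1, date = as.Date("2005-01-01") + 0:29,
                      value = 5)
  expect_true(all(temporal_median_subset(const)$value == 5))
})

test_that("day-of-year bins align across years and absorb the leap day", {
  expect_equal(doy_bin_of(as.Date("2005-01-01")), 1L)
  expect_equal(doy_bin_of(as.Date("2005-01-05")), 1L)
  expect_equal(doy_bin_of(as.Date("2005-01-06")), 2L)
  expect_equal(doy_bin_of(as.Date("2005-12-31")), 73L)
  expect_equal(doy_bin_of(as.Date("2004-12-31")), 73L)  # leap day 366
  expect_equal(doy_bin_of(as.Date("2004-06-01")),
               doy_bin_of(as.Date("2005-06-01")) + 0L)
})

test_that("coincident matching keeps only doubly observed cells", {
  lst <- data.frame(lat = c(45.05, 45.15), lon = 10.05, year = 2005L,
                    doy_bin = c(1L, 2L), value = c(4, 5))
  chla <- data.frame(lat = 45.05, lon = 10.05, year = 2005L, doy_bin = 1L,
                     value = 2)
  m <- match_coincident(lst, chla)
  expect_equal(nrow(m), 1L)
  expect_equal(m$lst, 4)
  expect_equal(m$chla, 2)
  # identical coverage: size preserved; disjoint coverage: empty
  expect_equal(nrow(match_coincident(lst, setNames(lst, sub("value", "value",
                                                            names(lst))))),
               2L)
  chla2 <- chla
  chla2$doy_bin <- 50L
  expect_equal(nrow(match_coincident(lst, chla2)), 0L)
  # symmetric in input order (up to column naming)
  m_ab <- match_coincident(lst, chla)
  m_ba <- match_coincident(chla, lst)
  expect_equal(m_ab$lst, m_ba$chla)
  expect_equal(nrow(m_ab), nrow(m_ba))
  # different cell anchoring is a configuration error
  shifted <- chla
  shifted$lat <- shifted$lat - 0.03
  expect_error(match_coincident(lst, shifted),
               class = "lakecor_config_error")
})

test_that("lake assignment labels, drops, and rejects overlapping masks", {
  masks <- data.frame(lake_id = c("A", "A", "B"),
                      lat = c(45.05, 45.15, 46.05),
                      lon = c(10.05, 10.05, 11.05))
  pts <- data.frame(lat = c(45.06, 46.04, 50.0), lon = c(10.09, 11.01, 10.0))
  out <- assign_lakes(pts, masks)
  expect_equal(out$lake_id, c("A", "B"))
  expect_equal(attr(out, "n_dropped"), 1L)
  overlap <- rbind(masks, data.frame(lake_id = "C", lat = 45.05, lon = 10.05))
  expect_error(assign_lakes(pts, overlap), class = "lakecor_config_error")
  expect_error(assign_lakes(pts, overlap), "A.*C")
})
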
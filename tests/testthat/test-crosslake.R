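# direct synthetic cross-lake table: r_lake driven by median chl-a alone
mk_crosslake_table <- function(n = 60, seed = 701) {
  set.seed(seed)
  chla <- 10^runif(n, -1, 2)
  data.frame(lake_id = sprintf("L%02d", 1:n),
             r_lake = 0.5 * (log10(chla) - 0.5) / 1.5 + rnorm(n, 0, 0.03),
             weight = runif(n, 0.8, 1),
             elevation = exp(runif(n, 0, 8)),
             latitude = runif(n, -55, 65),
             surface_area = exp(runif(n, 6, 11)),
             perimeter = exp(runif(n, 4, 8)),
             mean_depth = exp(runif(n, 1, 5)),
             salinity_class = sample(c("fresh", "saline"), n, TRUE),
             median_temperature = runif(n, 5, 25),
             median_chla = chla)
}

test_that("assemble_table computes significance weights and keeps missing cells", {
  catalog <- data.frame(lake_id = c("a", "b", "c"),
                        elevation = c(100, NA, 300),
                        latitude = c(50, 40, 30),
                        surface_area = c(600, 700, 800),
                        perimeter = c(90, 100, 110),
                        mean_depth = c(NA, 20, 30),
                        salinity_class = "fresh",
                        median_temperature = c(10, 12, 14),
                        median_chla = c(0.5, 5, 50))
  summaries <- data.frame(lake_id = c("a", "b", "c"),
                          r_lake = c(-0.2, 0.1, 0.3),
                          wilcoxon_p = c(0.01, 1, 0.2),
                          n = 100L, exclusion_reason = NA_character_)
  tab <- assemble_table(catalog, summaries)
  expect_equal(tab$weight, c(0.99, 0, 0.8))
  expect_true(is.na(tab$elevation[2]))
  expect_true(is.na(tab$mean_depth[1]))
  # a summary lake missing from the catalog is a hard error naming it
  bad <- summaries
  bad$lake_id[2] <- "zz"
  expect_error(assemble_table(catalog, bad), "zz")
  # excluded lakes are dropped
  summaries$exclusion_reason[2] <- "insufficient_data"
  expect_equal(nrow(assemble_table(catalog, summaries)), 2L)
})

test_that("cross-lake model recovers a trophic-state-driven response", {
  tab <- mk_crosslake_table()
  m <- fit_crosslake(tab, seed = 702)
  ri <- relative_influence(m)
  expect_equal(sum(ri), 100, tolerance = 1e-6)
  expect_equal(names(which.max(ri)), "median_chla")
  expect_gte(m$best_iter, 1000L)
  expect_lte(m$best_iter, 10000L)
  # permuting lake rows leaves the influence report unchanged on the
  # deterministic path (no bagging, fixed tree count: row order only enters
  # through the stochastic components)
  det <- brt_spec(interaction_depth = 8, learning_rate = 0.05,
                  cv_folds = 0L, n_trees = 300L, bag_fraction = 1, seed = 1)
  preds <- setdiff(names(tab), c("lake_id", "r_lake", "weight"))
  m_det <- fit_brt(tab, "r_lake", preds, weights = tab$weight, spec = det)
  set.seed(703)
  perm <- sample(nrow(tab))
  m_perm <- fit_brt(tab[perm, ], "r_lake", preds,
                    weights = tab$weight[perm], spec = det)
  expect_equal(relative_influence(m_perm), relative_influence(m_det),
               tolerance = 1e-9)

  eff <- medianchl_effect(m, tab)
  expect_true(min(eff$effect) < 0 && max(eff$effect) > 0)
  expect_equal(eff$asinh_effect, asinh(eff$effect))
  # single-point grid equals the partial dependence there
  one <- medianchl_effect(m, tab, grid = tab$median_chla[5])
  pd <- partial_dependence(m, "median_chla", tab$median_chla[5])
  expect_equal(one$effect, pd$yhat)
  expect_warning(medianchl_effect(m, tab, grid = c(1e-6, 1)), "clipped")
})

test_that("zero-weight lakes cannot influence the cross-lake fit", {
  tab <- mk_crosslake_table(n = 80, seed = 704)
  tab$weight[3] <- 0
  sp <- brt_spec(interaction_depth = 8, learning_rate = 0.05,
                 cv_folds = 0L, n_trees = 100L, bag_fraction = 1, seed = 9)
  m1 <- fit_brt(tab, "r_lake", setdiff(names(tab),
                                       c("lake_id", "r_lake", "weight")),
                weights = tab$weight, spec = sp)
  tab2 <- tab
  tab2$r_lake[3] <- 5
  m2 <- fit_brt(tab2, "r_lake", setdiff(names(tab2),
                                        c("lake_id", "r_lake", "weight")),
                weights = tab2$weight, spec = sp)
  expect_equal(predict(m1, tab), predict(m2, tab))
  # equal weights give a different fit from the significance weights
  m3 <- fit_brt(tab, "r_lake", setdiff(names(tab),
                                       c("lake_id", "r_lake", "weight")),
                weights = rep(1, nrow(tab)), spec = sp)
  expect_false(isTRUE(all.equal(predict(m1, tab), predict(m3, tab))))
})
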
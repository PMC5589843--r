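fast_spec <- function(n_trees = 200L, ...) {
  brt_spec(cv_folds = 0L, n_trees = n_trees, learning_rate = 0.05,
           bag_fraction = 1, seed = 7, ...)
}

test_that("a dominant predictor takes almost all relative influence", {
  set.seed(501)
  n <- 300
  d <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  d$y <- d$a
  m <- fit_brt(d, "y", c("a", "b", "c"),
               spec = fast_spec(interaction_depth = 3))
  ri <- relative_influence(m)
  expect_gt(ri[["a"]], 90)
  expect_equal(sum(ri), 100, tolerance = 1e-6)
  # influence is invariant to predictor order
  m2 <- fit_brt(d, "y", c("c", "b", "a"),
                spec = fast_spec(interaction_depth = 3))
  expect_equal(relative_influence(m2)[["a"]], ri[["a"]])
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(502)
  d <- data.frame(a = runif(120), b = runif(120))
  d$y <- sin(6 * d$a) + rnorm(120, 0, 0.1)
  sp <- brt_spec(interaction_depth = 2, learning_rate = 0.05,
                 cv_folds = 5L, max_trees = 400L, min_trees = 10L,
                 patience = 100L, seed = 99)
  m1 <- fit_brt(d, "y", c("a", "b"), spec = sp)
  m2 <- fit_brt(d, "y", c("a", "b"), spec = sp)
  expect_identical(m1$best_iter, m2$best_iter)
  expect_identical(m1$fit$node_split, m2$fit$node_split)
  expect_identical(predict(m1, d), predict(m2, d))
})

test_that("observation weights behave like replication", {
  set.seed(503)
  d <- data.frame(a = runif(40), b = runif(40))
  d$y <- d$a + rnorm(40, 0, 0.2)
  sp <- fast_spec(interaction_depth = 2, n_trees = 50L)
  w <- rep(1, 40); w[7] <- 2
  m_w <- fit_brt(d, "y", c("a", "b"), weights = w, spec = sp)
  m_dup <- fit_brt(rbind(d, d[7, ]), "y", c("a", "b"), spec = sp)
  expect_equal(predict(m_w, d), predict(m_dup, d))
  # a zero-weight observation cannot affect the fit
  w0 <- rep(1, 40); w0[7] <- 0
  d_alt <- d; d_alt$y[7] <- 99
  m_a <- fit_brt(d, "y", c("a", "b"), weights = w0, spec = sp)
  m_b <- fit_brt(d_alt, "y", c("a", "b"), weights = w0, spec = sp)
  expect_equal(predict(m_a, d), predict(m_b, d))
  expect_error(fit_brt(d, "y", c("a", "b"), weights = rep(-1, 40),
                       spec = sp),
               class = "lakecor_invalid_argument")
})

test_that("missing predictor values are routed, not dropped", {
  set.seed(504)
  n <- 300
  d <- data.frame(a = runif(n), b = runif(n))
  d$y <- d$a + rnorm(n, 0, 0.05)
  d$a[sample(n, 60)] <- NA
  m <- fit_brt(d, "y", c("a", "b"), spec = fast_spec(interaction_depth = 2))
  expect_true(all(is.finite(predict(m, d))))
  allna <- data.frame(a = NA_real_, b = NA_real_)
  expect_true(is.finite(predict(m, allna)))
  # duplicate rows predict identically
  expect_equal(predict(m, d[c(1, 1), ]),
               rep(predict(m, d[1, , drop = FALSE]), 2))
})

test_that("categorical predictors work and unseen levels route as missing", {
  set.seed(505)
  n <- 200
  d <- data.frame(g = sample(c("fresh", "saline"), n, replace = TRUE),
                  x = runif(n))
  d$y <- ifelse(d$g == "fresh", 1, -1) + rnorm(n, 0, 0.1)
  m <- fit_brt(d, "y", c("g", "x"), spec = fast_spec(interaction_depth = 2))
  pr <- predict(m, data.frame(g = c("fresh", "saline"), x = 0.5))
  expect_gt(pr[1] - pr[2], 1)
  expect_warning(predict(m, data.frame(g = "brackish", x = 0.5)),
                 "unknown level")
})

test_that("partial dependence recovers a monotone signal and flat noise", {
  set.seed(506)
  n <- 400
  d <- data.frame(a = runif(n), b = runif(n))
  d$y <- d$a
  m <- fit_brt(d, "y", c("a", "b"), spec = fast_spec(interaction_depth = 2))
  grid <- seq(0.1, 0.9, length.out = 17)
  pd <- partial_dependence(m, "a", grid)
  expect_true(all(diff(pd$yhat) >= -1e-9))
  expect_lt(max(abs(pd$yhat - grid)), 0.1)  # near-identity in the interior
  pd_b <- partial_dependence(m, "b", grid)
  expect_lt(diff(range(pd_b$yhat)), 0.02)   # never-selected: flat curve
  expect_error(partial_dependence(m, "a", numeric(0)),
               class = "lakecor_invalid_argument")
  expect_error(partial_dependence(m, "zz", 1),
               class = "lakecor_invalid_argument")
})

test_that("degenerate fits are refused and tiny tables raise insufficiency", {
  d <- data.frame(a = runif(30), y = 1)
  expect_error(fit_brt(d, "y", "a", spec = fast_spec()),
               class = "lakecor_degenerate_fit")
  tiny <- data.frame(a = runif(10), y = rnorm(10))
  expect_error(tune_learning_rate(tiny, "y", "a",
                                  spec = brt_spec(interaction_depth = 1)),
               class = "lakecor_insufficient_data")
})

test_that("serialised models round-trip predictions exactly", {
  set.seed(507)
  d <- data.frame(a = runif(80), g = sample(c("u", "v"), 80, replace = TRUE))
  d$y <- d$a + (d$g == "u") + rnorm(80, 0, 0.1)
  m <- fit_brt(d, "y", c("a", "g"), spec = fast_spec(interaction_depth = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_brt(m, path)
  m2 <- read_brt(path)
  expect_equal(predict(m2, d), predict(m, d))
  expect_equal(m2$relative_influence, m$relative_influence,
               tolerance = 1e-12)
})
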
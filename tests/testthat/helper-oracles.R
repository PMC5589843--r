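# Independent oracles used by the tests. These deliberately avoid the
# package's own algorithms: pair counting by double loop, null
# distributions by explicit enumeration, SMA by direct formula.

# Kendall tau-b and the concordance statistic S by brute-force O(n^2)
# pair counting.
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0; txy <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) txy <- txy + 1
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (sign(dx) == sign(dy)) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx - txy) * (n0 - ty - txy))
  list(tau = if (den == 0) NA_real_ else (C - D) / den, S = C - D)
}

# Exact null distribution of S for untied samples of size n by explicit
# enumeration of all n! permutations (feasible for n <= 7); the enumerated
# S values are cached per n so repeated queries are cheap.
.oracle_kendall_cache <- new.env(parent = emptyenv())
oracle_kendall_null_svals <- function(n) {
  key <- as.character(n)
  hit <- .oracle_kendall_cache[[key]]
  if (!is.null(hit)) return(hit)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  svals <- vapply(perms(seq_len(n)), function(p) {
    oracle_kendall(seq_len(n), p)$S
  }, numeric(1))
  .oracle_kendall_cache[[key]] <- svals
  svals
}

oracle_kendall_null_p <- function(s_obs, n) {
  svals <- oracle_kendall_null_svals(n)
  mean(abs(svals) >= abs(s_obs))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments (zeros must already be removed from x).
oracle_wilcoxon_p <- function(x) {
  n <- length(x)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# SMA slope/intercept/R^2 recomputed from the defining formulas.
oracle_sma <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope <- (if (r < 0) -1 else 1) *
    sqrt(sum((y - mean(y))^2) / sum((x - mean(x))^2))
  list(slope = slope, intercept = mean(y) - slope * mean(x), r2 = r^2)
}

# The seasonal-sign world: coupling positive in the summer half of the
# strata and negative in the winter half, with missingness oversampling
# the positive strata about 4:1 in retained subdivisions.
seasonal_sign_scenario <- function(seed, n_px = 3L) {
  rho_bin <- ifelse((1:73) >= 19 & (1:73) <= 54, 0.5, -0.5)
  p_bin <- ifelse(rho_bin > 0, 0.9, 0.45)
  lake_scenario(lake_id = "seasonal", n_pixels_lat = n_px,
                n_pixels_lon = n_px, rho_by_bin = rho_bin,
                obs_prob_by_bin = p_bin, seed = seed)
}
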
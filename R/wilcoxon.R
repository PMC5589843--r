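#' Wilcoxon signed-rank test against zero
#'
#' One-sample two-sided signed-rank test used to decide whether a lake's
#' balanced ensemble of correlation values differs from zero. Zeros are
#' dropped, tied absolute values receive average ranks, and the p-value is
#' exact (computed by convolution over the doubled midranks, valid under
#' ties) for `n <= exact_max` after zero removal, otherwise a tie-corrected
#' normal approximation with continuity correction is used. The two-sided
#' exact p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x numeric vector of differences from the hypothesised centre.
#' @param exact_max largest post-zero-removal sample size for which the
#'   exact distribution is enumerated (default 25).
#' @return list with `statistic` (W, sum of positive ranks), `p_value`,
#'   `n_used` (after dropping zeros), and `method`.
#' @examples
#' wilcoxon_signed_rank(c(0.2, -0.1, 0.3, 0.25, -0.05, 0.15, 0.1, 0.2))
#' @export
wilcoxon_signed_rank <- function(x, exact_max = 25L) {
  if (anyNA(x)) stop_invalid("missing values are not allowed")
  d <- x[x != 0]
  n <- length(d)
  if (n < 1L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                method = "none"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))     # doubled midranks are integers
    f <- signed_rank_null(r2)          # counts over W2 = 0..sum(r2)
    w2 <- as.integer(round(2 * w))
    total <- 2^n
    p_le <- sum(f[seq_len(w2 + 1L)]) / total
    p_ge <- sum(f[(w2 + 1L):length(f)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- if (w > mu) 0.5 else if (w < mu) -0.5 else 0
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n_used = n, method = method)
}

# Null counts of the doubled signed-rank statistic: each of the 2^n sign
# assignments contributes its subset-sum of doubled ranks; classic
# subset-sum convolution.
signed_rank_null <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (v in r2) {
    idx <- (total + 1L):(v + 1L)
    f[idx] <- f[idx] + f[idx - v]
  }
  f
}
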
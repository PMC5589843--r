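#' Kendall rank correlation (tau-b) with small-sample exact p-values
#'
#' Computes the tie-corrected Kendall rank correlation between two equal
#' length vectors, the statistic used for every (pixel, day-of-year)
#' subdivision of the interannual analysis. The two-sided p-value comes from
#' the exact null distribution of the concordance statistic when `n <= 10`
#' and there are no ties, and from the tie-corrected normal approximation
#' otherwise.
#'
#' With all values of `x` or all values of `y` tied the correlation is
#' undefined; `tau` and `p_value` are then `NA` and callers are expected to
#' drop the subdivision rather than score it zero.
#'
#' @param x,y numeric vectors of equal length (no missing values).
#' @return a list with elements `tau`, `p_value`, `n`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' kendall_tau(1:8, c(3, 1, 4, 1, 5, 9, 2, 6))
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) {
    stop_invalid("`x` and `y` must have equal length (got ",
                 length(x), " and ", length(y), ")")
  }
  n <- length(x)
  if (n < 2L) stop_invalid("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values are not allowed")

  cnt <- kendall_counts_cpp(as.numeric(x), as.numeric(y))
  n0 <- n * (n - 1) / 2
  ties_x <- cnt$tx + cnt$txy
  ties_y <- cnt$ty + cnt$txy
  den <- sqrt((n0 - ties_x) * (n0 - ties_y))
  if (den == 0) {
    return(list(tau = NA_real_, p_value = NA_real_, n = n, method = "undefined"))
  }
  s <- cnt$C - cnt$D
  tau <- s / den

  has_ties <- (cnt$tx + cnt$ty + cnt$txy) > 0
  if (n <= 10L && !has_ties) {
    p <- kendall_exact_p(s, n)
    method <- "exact"
  } else {
    tx <- tabulate(match(x, unique(x)))
    ty <- tabulate(match(y, unique(y)))
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- s / sqrt(var_s)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(tau = tau, p_value = p, n = n, method = method)
}

# Exact null distribution of S = C - D for an untied sample of size n:
# equivalent to the Mahonian distribution of inversion counts, built by the
# standard convolution recursion and cached per n. Counts are exact in
# doubles up to n = 10 (10! = 3,628,800).
kendall_null_counts <- function(n) {
  key <- as.character(n)
  if (is.null(the$kendall_null)) the$kendall_null <- list()
  hit <- the$kendall_null[[key]]
  if (!is.null(hit)) return(hit)
  counts <- 1  # n = 1: zero inversions
  if (n > 1) {
    for (m in 2:n) {
      # convolve with a run of m ones: counts_k = sum_{j=0}^{m-1} prev_{k-j}
      padded <- c(counts, numeric(m - 1))
      cs <- cumsum(padded)
      counts <- cs - c(numeric(m), head(cs, -m))[seq_along(cs)]
    }
  }
  the$kendall_null[[key]] <- counts
  counts
}

kendall_exact_p <- function(s, n) {
  counts <- kendall_null_counts(n)
  n0 <- n * (n - 1) / 2
  inv <- 0:(length(counts) - 1)
  s_vals <- n0 - 2 * inv
  p <- sum(counts[abs(s_vals) >= abs(s)]) / sum(counts)
  min(1, p)
}
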
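#' Match in-situ samples to the nearest coincident satellite cell
#'
#' For each in-situ point the satellite cell minimising great-circle
#' distance is chosen among cells within `max_km` and dates within
#' `max_days`; ties are broken by smaller temporal offset, then by
#' lexicographic (lat, lon). Samples with no admissible candidate are
#' dropped and counted.
#'
#' @param insitu data frame with `date`, `lat`, `lon` and `insitu_lst`
#'   and/or `insitu_chla` columns.
#' @param grid paired-observation data frame (`lat`, `lon`, `date`, `lst`,
#'   `chla`).
#' @param max_km spatial matching radius (default 4 km, the cell scale).
#' @param max_days temporal matching window (default 5 days, the bin width).
#' @return data frame of matched pairs with satellite values, offsets, and
#'   the in-situ values; `attr(, "n_dropped")` counts unmatched samples.
#' @export
match_nearest <- function(insitu, grid, max_km = 4, max_days = 5) {
  if (nrow(insitu) == 0L || nrow(grid) == 0L) {
    stop_invalid("both insitu and grid tables must be non-empty")
  }
  gdate <- as.numeric(as.Date(grid$date))
  idate <- as.numeric(as.Date(insitu$date))
  rows <- vector("list", nrow(insitu))
  dropped <- 0L
  for (i in seq_len(nrow(insitu))) {
    dt <- abs(gdate - idate[i])
    cand <- which(dt <= max_days)
    if (length(cand) == 0L) { dropped <- dropped + 1L; next }
    dk <- haversine_km(insitu$lat[i], insitu$lon[i],
                       grid$lat[cand], grid$lon[cand])
    ok <- dk <= max_km
    if (!any(ok)) { dropped <- dropped + 1L; next }
    cand <- cand[ok]; dk <- dk[ok]
    o <- order(dk, dt[cand], grid$lat[cand], grid$lon[cand])
    j <- cand[o[1L]]
    rows[[i]] <- data.frame(
      lake_id = if ("lake_id" %in% names(grid)) grid$lake_id[j] else NA,
      date = insitu$date[i],
      insitu_lst = insitu$insitu_lst[i], satellite_lst = grid$lst[j],
      insitu_chla = insitu$insitu_chla[i], satellite_chla = grid$chla[j],
      spatial_offset_km = dk[o[1L]], temporal_offset_days = dt[j],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}

#' Standardized major axis (SMA) regression
#'
#' Symmetric line fit appropriate when both variables carry measurement
#' error: slope is `sign(r) * sd(y) / sd(x)`, the intercept passes through
#' the means, and the 95% confidence interval for the slope uses the
#' standard F-based interval with `n - 2` denominator degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, both with nonzero variance).
#' @param alpha 1 - confidence level (default 0.05).
#' @return an object of class `sma_fit`: list with `slope`, `intercept`,
#'   `slope_ci_low`, `slope_ci_high`, `r_squared`, `n`.
#' @export
sma_fit <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop(errorCondition("zero variance in x or y: degenerate SMA fit",
                        class = c("lakecor_degenerate_fit", "error")))
  }
  r <- cor(x, y)
  s <- if (r < 0) -1 else 1
  slope <- s * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  B <- qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B)))
  structure(list(slope = slope, intercept = intercept,
                 slope_ci_low = ci[1], slope_ci_high = ci[2],
                 r_squared = r^2, n = n),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit (n = %d): slope %.4f [%.4f, %.4f], intercept %.4f, R^2 %.4f\n",
              x$n, x$slope, x$slope_ci_low, x$slope_ci_high, x$intercept,
              x$r_squared))
  invisible(x)
}

var_stats <- function(insitu, satellite) {
  sma <- sma_fit(insitu, satellite)
  ct <- stats::cor.test(insitu, satellite)
  list(sma = sma, pearson_r = unname(ct$estimate),
       pearson_p = ct$p.value,
       mae = median(abs(insitu - satellite)),
       ci_covers_1 = sma$slope_ci_low <= 1 && sma$slope_ci_high >= 1)
}

#' Satellite vs in-situ validation report
#'
#' Observation-level comparison for LST and chl-a (SMA fit, Pearson
#' correlation, median absolute error, and whether the slope CI covers 1),
#' plus optional lake-level comparisons of per-lake summary pairs (e.g.
#' median chl-a, or lake-wide correlations) when at least 3 lakes are
#' available.
#'
#' @param matched a [match_nearest()] table.
#' @param lake_pairs optional named list of data frames, each with columns
#'   `insitu` and `satellite` (one row per lake) for lake-level comparison.
#' @param log_chla compare chl-a on the log10 scale? (default FALSE, raw
#'   values).
#' @return an object of class `validation_report`: nested list with `lst`,
#'   `chla`, and `lake_level` sections (the latter `NULL` with a notice
#'   when fewer than 3 lakes are supplied).
#' @export
validation_report <- function(matched, lake_pairs = NULL, log_chla = FALSE) {
  if (nrow(matched) < 3L) stop_invalid("need at least 3 matched pairs")
  ic <- matched$insitu_chla
  sc <- matched$satellite_chla
  if (log_chla) { ic <- log10(ic); sc <- log10(sc) }
  out <- list(lst = var_stats(matched$insitu_lst, matched$satellite_lst),
              chla = var_stats(ic, sc),
              lake_level = NULL, lake_level_notice = NULL)
  if (!is.null(lake_pairs)) {
    out$lake_level <- list()
    for (nm in names(lake_pairs)) {
      lp <- lake_pairs[[nm]]
      if (nrow(lp) < 3L) {
        out$lake_level_notice <- c(out$lake_level_notice, paste0(
          nm, ": fewer than 3 lakes, section omitted"))
        next
      }
      out$lake_level[[nm]] <- var_stats(lp$insitu, lp$satellite)
    }
  }
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  show <- function(nm, v) {
    cat(sprintf("%s: n=%d slope=%.3f [%.3f, %.3f] R^2=%.3f r=%.3f MAE=%.4g CI covers 1: %s\n",
                nm, v$sma$n, v$sma$slope, v$sma$slope_ci_low,
                v$sma$slope_ci_high, v$sma$r_squared, v$pearson_r, v$mae,
                v$ci_covers_1))
  }
  cat("Satellite vs in-situ validation\n")
  show("  LST ", x$lst)
  show("  chl-a", x$chla)
  for (nm in names(x$lake_level)) show(paste0("  lake-level ", nm),
                                       x$lake_level[[nm]])
  for (msg in x$lake_level_notice) cat(" ", msg, "\n")
  invisible(x)
}
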
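#' Fit a lake's correlation surface over space and season
#'
#' Models one lake's observed subdivision correlations as a boosted
#' regression tree of latitude, longitude and day-of-year stratum
#' (interaction depth 3, one per predictor). Lakes with more than
#' `subsample_cap` correlation records are fit on a seeded uniform random
#' subset of exactly `subsample_cap` records. The learning rate is tuned so
#' the cross-validation selected tree count lies in the protocol window; if
#' no admissible rate of at least 1e-4 succeeds the lake is declared
#' insufficient (condition class `lakecor_insufficient_data`).
#'
#' @param records a [correlation_field()] table for a single lake.
#' @param seed RNG seed for subsampling, fold assignment and bagging.
#' @param subsample_cap maximum number of records used for fitting
#'   (default 10,000).
#' @param spec template [brt_spec()]; interaction depth is forced to 3.
#' @param grid learning-rate grid passed to [tune_learning_rate()].
#' @return an object of class `lake_surface`: list with `lake_id`, `model`
#'   (the tuned `lakecor_brt`), `records` (the training records), and
#'   `residuals` (observed minus fitted on the training records).
#' @export
fit_lake_surface <- function(records, seed = 1L, subsample_cap = 10000L,
                             spec = brt_spec(), grid = c(0.1, 0.05, 0.01,
                                                         0.005, 0.001, 5e-4,
                                                         1e-4)) {
  lake_id <- unique(records$lake_id)
  if (length(lake_id) != 1L) {
    stop_invalid("records must belong to a single lake (got ",
                 length(lake_id), ")")
  }
  if (nrow(records) > subsample_cap) {
    pick <- with_seed(child_seed(seed, 1), sample.int(nrow(records),
                                                      subsample_cap))
    records <- records[sort(pick), , drop = FALSE]
  }
  spec$interaction_depth <- 3L
  spec$seed <- child_seed(seed, 2)
  model <- tune_learning_rate(records, response = "tau",
                              predictors = c("lat", "lon", "doy_bin"),
                              spec = spec, grid = grid, lake_id = lake_id)
  structure(list(lake_id = lake_id, model = model, records = records,
                 residuals = model$residuals),
            class = "lake_surface")
}

#' Balanced ensemble of modelled correlations plus resampled residuals
#'
#' Draws `n` (= training-set size) ensemble members: for each member an
#' observed pixel (latitude-longitude pair) and an observed day-of-year
#' stratum are drawn independently and uniformly with replacement from the
#' lake's unique observed lists, the surface model predicts a modelled
#' correlation there, and a residual is added, drawn *without* replacement
#' from the fit's residual pool (the pool is a permutation consumed exactly
#' once). Uniform resampling over the unique lists is what removes the
#' spatial/seasonal sampling bias carried by the raw correlation records.
#'
#' @param surface a [fit_lake_surface()] result.
#' @param seed RNG seed.
#' @return an object of class `lakecor_ensemble`: list with `lake_id`, `n`,
#'   `modeled`, `residuals`, `members` (modeled + residuals).
#' @export
balanced_ensemble <- function(surface, seed = 1L) {
  stopifnot(inherits(surface, "lake_surface"))
  rec <- surface$records
  n <- nrow(rec)
  pix <- unique(rec[, c("lat", "lon")])
  strata <- unique(rec$doy_bin)
  with_seed(seed, {
    pi_idx <- sample.int(nrow(pix), n, replace = TRUE)
    st_idx <- sample.int(length(strata), n, replace = TRUE)
    newdata <- data.frame(lat = pix$lat[pi_idx], lon = pix$lon[pi_idx],
                          doy_bin = strata[st_idx])
    modeled <- predict(surface$model, newdata)
    resid <- surface$residuals[sample.int(n, n)]  # permutation: no reuse
    structure(list(lake_id = surface$lake_id, n = n, modeled = modeled,
                   residuals = resid, members = modeled + resid),
              class = "lakecor_ensemble")
  })
}

#' Summarise a lake's balanced ensemble
#'
#' The lake-wide correlation is the mean of the ensemble members; a
#' two-sided Wilcoxon signed-rank test asks whether the members differ from
#' zero. With fewer than 6 non-zero members a two-sided p below 0.05 is
#' unattainable, so the test is skipped and `wilcoxon_p` is `NA`.
#'
#' @param ensemble a [balanced_ensemble()] result.
#' @return one-row data frame with `lake_id`, `r_lake`, `wilcoxon_p`, `n`.
#' @export
summarize_lake <- function(ensemble) {
  stopifnot(inherits(ensemble, "lakecor_ensemble"))
  r_lake <- mean(ensemble$members)
  p <- if (sum(ensemble$members != 0) >= 6L) {
    wilcoxon_signed_rank(ensemble$members)$p_value
  } else {
    NA_real_
  }
  data.frame(lake_id = ensemble$lake_id, r_lake = r_lake, wilcoxon_p = p,
             n = ensemble$n, stringsAsFactors = FALSE)
}

#' Flag significance after multiple-comparison correction
#'
#' Benjamini-Hochberg adjustment across all lakes' Wilcoxon p-values;
#' `adjusted_significant` is true where the adjusted p falls below `alpha`.
#'
#' @param summaries data frame of [summarize_lake()] rows.
#' @param alpha significance level (default 0.05).
#' @return `summaries` with columns `p_adjusted` and `adjusted_significant`.
#' @export
adjust_multiplicity <- function(summaries, alpha = 0.05) {
  if (nrow(summaries) < 1L) stop_invalid("no summaries to adjust")
  summaries$p_adjusted <- p.adjust(summaries$wilcoxon_p, method = "BH")
  summaries$adjusted_significant <- !is.na(summaries$p_adjusted) &
    summaries$p_adjusted < alpha
  summaries
}

#' Debias all lakes in a correlation field
#'
#' Runs [fit_lake_surface()], [balanced_ensemble()] and [summarize_lake()]
#' per lake and applies [adjust_multiplicity()]. Lakes whose learning-rate
#' tuning fails are retained in the output with an `exclusion_reason` and
#' `NA` estimates.
#'
#' @param field a [correlation_field()] table (possibly many lakes).
#' @param seed base RNG seed; each lake derives its own stream from it.
#' @param alpha significance level for the adjusted flags.
#' @inheritParams fit_lake_surface
#' @return data frame with one row per lake: `lake_id`, `r_lake`,
#'   `wilcoxon_p`, `n`, `p_adjusted`, `adjusted_significant`,
#'   `exclusion_reason`.
#' @export
debias_lakes <- function(field, seed = 1L, subsample_cap = 10000L,
                         spec = brt_spec(), alpha = 0.05) {
  lakes <- unique(field$lake_id)
  rows <- vector("list", length(lakes))
  for (i in seq_along(lakes)) {
    lk <- lakes[i]
    rec <- field[field$lake_id == lk, , drop = FALSE]
    lake_seed <- child_seed(seed, i)
    rows[[i]] <- tryCatch({
      surface <- fit_lake_surface(rec, seed = lake_seed,
                                  subsample_cap = subsample_cap, spec = spec)
      ens <- balanced_ensemble(surface, seed = child_seed(lake_seed, 3))
      s <- summarize_lake(ens)
      s$exclusion_reason <- NA_character_
      s
    }, lakecor_insufficient_data = function(e) {
      data.frame(lake_id = lk, r_lake = NA_real_, wilcoxon_p = NA_real_,
                 n = nrow(rec), exclusion_reason = "insufficient_data",
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- is.na(out$exclusion_reason)
  out$p_adjusted <- NA_real_
  out$adjusted_significant <- NA
  if (any(ok)) {
    adj <- adjust_multiplicity(out[ok, , drop = FALSE], alpha = alpha)
    out$p_adjusted[ok] <- adj$p_adjusted
    out$adjusted_significant[ok] <- adj$adjusted_significant
  }
  out
}
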
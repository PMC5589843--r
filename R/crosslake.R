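#' Assemble the cross-lake modelling table
#'
#' Joins each lake's debiased lake-wide correlation to its catalog
#' attributes and attaches the significance weights `1 - p` (clipped to
#' [0, 1]), so that less significant lake-wide correlations carry less
#' influence on the cross-lake model. Missing predictor entries are kept as
#' missing: the tree engine routes them rather than dropping lakes.
#'
#' @param catalog data frame of lake attributes (the `attributes` element of
#'   a [generate_lake_catalog()], or any table with `lake_id` and the eight
#'   predictors).
#' @param summaries a [debias_lakes()] table; excluded lakes are dropped.
#' @return data frame with `lake_id`, `r_lake`, `weight` and the predictor
#'   columns.
#' @export
assemble_table <- function(catalog, summaries) {
  keep <- is.na(summaries$exclusion_reason) | is.null(summaries$exclusion_reason)
  if ("exclusion_reason" %in% names(summaries)) {
    summaries <- summaries[keep, , drop = FALSE]
  }
  missing_lakes <- setdiff(summaries$lake_id, catalog$lake_id)
  if (length(missing_lakes) > 0L) {
    stop_invalid("summary lakes absent from catalog: ",
                 paste(missing_lakes, collapse = ", "))
  }
  idx <- match(summaries$lake_id, catalog$lake_id)
  preds <- c("elevation", "latitude", "surface_area", "perimeter",
             "mean_depth", "salinity_class", "median_temperature",
             "median_chla")
  have <- intersect(preds, names(catalog))
  out <- cbind(summaries[, c("lake_id", "r_lake", "wilcoxon_p")],
               catalog[idx, have, drop = FALSE])
  out$weight <- pmin(pmax(1 - out$wilcoxon_p, 0), 1)
  out$wilcoxon_p <- NULL
  rownames(out) <- NULL
  out
}

crosslake_predictors <- c("elevation", "latitude", "surface_area",
                          "perimeter", "mean_depth", "salinity_class",
                          "median_temperature", "median_chla")

#' Fit the cross-lake boosted regression tree
#'
#' Significance-weighted boosted regression tree of the lake-wide
#' correlations on the eight lake attributes (elevation, latitude, surface
#' area, perimeter, mean depth, salinity class, median temperature, median
#' chl-a); interaction depth 8 per the one-split-per-predictor complexity
#' rule, learning rate tuned to the protocol tree window.
#'
#' @param table an [assemble_table()] result.
#' @param seed RNG seed.
#' @param spec template [brt_spec()]; interaction depth is forced to the
#'   number of predictors present.
#' @param grid learning-rate grid.
#' @return a `lakecor_brt` model; `relative_influence(model)` gives the
#'   per-attribute percentages.
#' @export
fit_crosslake <- function(table, seed = 1L, spec = brt_spec(),
                          grid = c(0.1, 0.05, 0.01, 0.005, 0.001, 5e-4,
                                   1e-4)) {
  preds <- intersect(crosslake_predictors, names(table))
  if (length(preds) < 2L) {
    stop_invalid("cross-lake table lacks attribute predictors")
  }
  spec$interaction_depth <- length(preds)
  spec$seed <- child_seed(seed, 4)
  tune_learning_rate(table, response = "r_lake", predictors = preds,
                     weights = table$weight, spec = spec, grid = grid,
                     lake_id = "crosslake")
}

#' Isolated effect of median chl-a on the lake-wide correlation
#'
#' Partial-dependence curve of the cross-lake model over a log-spaced grid
#' of median chl-a spanning the observed range, holding variability from
#' the other seven attributes at its empirical distribution. The returned
#' table carries log10-x and hyperbolic-sine-y display transforms matching
#' the conventional presentation of the trophic-state amplification effect.
#'
#' @param model a [fit_crosslake()] result.
#' @param table the modelling table the model was fit to (defaults to the
#'   model's training data).
#' @param grid optional numeric grid of median chl-a values; values outside
#'   the observed range are clipped with a warning.
#' @param n_grid grid length when `grid` is not given (default 50).
#' @return data frame with `median_chla`, `log10_median_chla`, `effect`,
#'   `asinh_effect`.
#' @export
medianchl_effect <- function(model, table = model$data, grid = NULL,
                             n_grid = 50L) {
  stopifnot(inherits(model, "lakecor_brt"))
  rng <- range(table$median_chla, na.rm = TRUE)
  if (is.null(grid)) {
    grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n_grid)
  } else if (any(grid < rng[1] | grid > rng[2])) {
    warning("grid values outside the observed median chl-a range clipped",
            call. = FALSE)
    grid <- pmin(pmax(grid, rng[1]), rng[2])
  }
  pd <- partial_dependence(model, "median_chla", grid)
  data.frame(median_chla = pd$value,
             log10_median_chla = log10(pd$value),
             effect = pd$yhat, asinh_effect = asinh(pd$yhat))
}
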
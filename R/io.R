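#' Write / read paired observation tables
#'
#' Flat headered CSV with columns lake_id, lat, lon, date (ISO-8601),
#' doy_bin, year, lst_c, chla_mg_m3. On reading, rows with non-positive
#' chl-a, non-finite LST, or a day-of-year bin inconsistent with the date
#' are rejected with a warning; the rejected line numbers are kept in
#' `attr(, "rejected_rows")`.
#'
#' @param obs paired observation data frame (as from
#'   [simulate_observations()]).
#' @param path CSV file path.
#' @return `write_observations`: `path`, invisibly. `read_observations`:
#'   validated data frame with columns `lake_id`, `lat`, `lon`, `date`,
#'   `year`, `doy_bin`, `lst`, `chla`.
#' @export
write_observations <- function(obs, path) {
  out <- data.frame(lake_id = obs$lake_id, lat = obs$lat, lon = obs$lon,
                    date = format(obs$date, "%Y-%m-%d"),
                    doy_bin = obs$doy_bin, year = obs$year,
                    lst_c = obs$lst, chla_mg_m3 = obs$chla)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  need <- c("lake_id", "lat", "lon", "date", "doy_bin", "year", "lst_c",
            "chla_mg_m3")
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop(errorCondition(paste0("missing column(s): ",
                               paste(missing_cols, collapse = ", ")),
                        class = c("lakecor_format_error", "error")))
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- is.na(date) | !is.finite(raw$lst_c) |
    is.na(raw$chla_mg_m3) | raw$chla_mg_m3 <= 0
  chk <- !bad
  bad[chk] <- bad[chk] | doy_bin_of(date[chk]) != raw$doy_bin[chk]
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) rejected (lines ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")", call. = FALSE)
  }
  out <- data.frame(lake_id = raw$lake_id, lat = raw$lat, lon = raw$lon,
                    date = date, year = raw$year, doy_bin = raw$doy_bin,
                    lst = raw$lst_c, chla = raw$chla_mg_m3,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_rows") <- which(bad)
  out
}

#' Pipeline configuration
#'
#' Bundles the thresholds and seeds of the whole pipeline: 0.1-degree
#' cells, 5-day bins, the >= 8 observation rule, the 10,000-record
#' subsample cap, the [1,000, 10,000] tree window with learning-rate floor
#' 1e-4, alpha 0.05, plus the synthetic-scenario block.
#'
#' @param n_lakes number of synthetic lakes.
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param amplification couple coupling strength to trophic state?
#' @param years,n_pixels_lat,n_pixels_lon,obs_prob scenario geometry and
#'   missingness passed to [generate_lake_catalog()].
#' @param min_obs minimum coincident pairs per subdivision.
#' @param subsample_cap per-lake cap on correlation records used for the
#'   surface fit.
#' @param min_trees,max_trees accepted cross-validation tree-count window.
#' @param alpha significance level.
#' @param with_insitu also simulate and validate in-situ samples?
#' @param insitu_n in-situ samples per lake when `with_insitu`.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(n_lakes = 8L, seed = 1L, amplification = TRUE,
                            years = 15L, n_pixels_lat = 5L,
                            n_pixels_lon = 5L, obs_prob = 0.8,
                            min_obs = 8L, subsample_cap = 10000L,
                            min_trees = 1000L, max_trees = 10000L,
                            alpha = 0.05, with_insitu = FALSE,
                            insitu_n = 50L) {
  cfg <- list(n_lakes = as.integer(n_lakes), seed = as.numeric(seed),
              amplification = isTRUE(amplification),
              years = as.integer(years),
              n_pixels_lat = as.integer(n_pixels_lat),
              n_pixels_lon = as.integer(n_pixels_lon),
              obs_prob = obs_prob, min_obs = as.integer(min_obs),
              subsample_cap = as.integer(subsample_cap),
              min_trees = as.integer(min_trees),
              max_trees = as.integer(max_trees), alpha = alpha,
              with_insitu = isTRUE(with_insitu),
              insitu_n = as.integer(insitu_n))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop_invalid("config must declare a seed")
  }
  for (f in c("n_lakes", "years", "min_obs", "subsample_cap", "min_trees",
              "max_trees", "alpha")) {
    if (is.null(cfg[[f]]) || cfg[[f]] <= 0) {
      stop_invalid("config field `", f, "` must be positive")
    }
  }
  if (cfg$min_trees >= cfg$max_trees) {
    stop_invalid("min_trees must be < max_trees")
  }
  invisible(cfg)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> correlate -> debias -> cross-lake (-> validate) and
#' writes every intermediate table as CSV to `out_dir`, together with a run
#' manifest (configuration, seeds, package version, file checksums).
#' Re-running with an identical configuration reproduces byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`catalog`,
#'   `field`, `summaries`, `crosslake_model`, `influence`, `effect`,
#'   `validation`, `truth`).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- generate_lake_catalog(
    n_lakes = config$n_lakes, seed = child_seed(config$seed, 11),
    amplification = config$amplification, years = config$years,
    n_pixels_lat = config$n_pixels_lat,
    n_pixels_lon = config$n_pixels_lon, obs_prob = config$obs_prob)
  write.csv(catalog$attributes, file.path(out_dir, "catalog.csv"),
            row.names = FALSE)

  fields <- list()
  truths <- list()
  insitu_reports <- NULL
  all_obs <- list()
  for (i in seq_along(catalog$scenarios)) {
    sim <- simulate_observations(catalog$scenarios[[i]])
    all_obs[[i]] <- sim$observations
    truths[[i]] <- data.frame(lake_id = sim$truth$strata$lake_id[1],
                              true_r_lake = sim$truth$true_r_lake)
    fields[[i]] <- correlation_field(subdivide(sim$observations),
                                     min_obs = config$min_obs)
  }
  obs <- do.call(rbind, all_obs)
  write_observations(obs, file.path(out_dir, "observations.csv"))
  field <- do.call(rbind, fields)
  attr(field, "n_below_min") <- sum(vapply(fields, attr, 0L, "n_below_min"))
  attr(field, "n_undefined") <- sum(vapply(fields, attr, 0L, "n_undefined"))
  write.csv(field, file.path(out_dir, "correlation_field.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, truths), file.path(out_dir, "truth.csv"),
            row.names = FALSE)

  summaries <- debias_lakes(field, seed = child_seed(config$seed, 12),
                            subsample_cap = config$subsample_cap,
                            spec = brt_spec(min_trees = config$min_trees,
                                            max_trees = config$max_trees),
                            alpha = config$alpha)
  write.csv(summaries, file.path(out_dir, "lake_summaries.csv"),
            row.names = FALSE)

  crosslake_model <- NULL
  influence <- NULL
  effect <- NULL
  fitted_lakes <- sum(is.na(summaries$exclusion_reason))
  if (fitted_lakes >= 10L) {
    tab <- assemble_table(catalog$attributes, summaries)
    crosslake_model <- tryCatch(
      fit_crosslake(tab, seed = child_seed(config$seed, 13),
                    spec = brt_spec(min_trees = config$min_trees,
                                    max_trees = config$max_trees)),
      lakecor_insufficient_data = function(e) NULL)
    if (!is.null(crosslake_model)) {
      influence <- data.frame(
        predictor = names(relative_influence(crosslake_model)),
        relative_influence = as.numeric(relative_influence(crosslake_model)))
      write.csv(influence, file.path(out_dir, "relative_influence.csv"),
                row.names = FALSE)
      effect <- medianchl_effect(crosslake_model, tab)
      write.csv(effect, file.path(out_dir, "medianchl_effect.csv"),
                row.names = FALSE)
    }
  }

  validation <- NULL
  if (config$with_insitu) {
    sc <- catalog$scenarios[[1]]
    sim1 <- simulate_observations(sc)
    samples <- simulate_insitu_samples(
      sc, sim1$observations, n_samples = min(config$insitu_n,
                                             nrow(sim1$observations)),
      seed = child_seed(config$seed, 14))
    matched <- match_nearest(samples, sim1$observations)
    validation <- validation_report(matched)
    vr <- data.frame(variable = c("lst", "chla"),
                     n = c(validation$lst$sma$n, validation$chla$sma$n),
                     slope = c(validation$lst$sma$slope,
                               validation$chla$sma$slope),
                     r_squared = c(validation$lst$sma$r_squared,
                                   validation$chla$sma$r_squared),
                     mae = c(validation$lst$mae, validation$chla$mae))
    write.csv(vr, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }

  md5 <- tools::md5sum(sort(list.files(out_dir, pattern = "\\.csv$",
                                       full.names = TRUE)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lakecor")),
    config = unclass(config),
    files = setNames(as.list(unname(md5)), basename(names(md5))))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(catalog = catalog, field = field, summaries = summaries,
                 crosslake_model = crosslake_model, influence = influence,
                 effect = effect, validation = validation,
                 truth = do.call(rbind, truths)))
}
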
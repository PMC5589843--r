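#' Define a synthetic lake scenario
#'
#' A scenario describes one lake's simulated observation process: a
#' 0.1-degree pixel grid, a multi-year record in 5-day day-of-year bins, a
#' Gaussian-copula coupling between interannual LST and chl-a anomalies
#' within each (pixel, bin) stratum, and a cloud/ice-style missingness
#' surface that may oversample particular seasons or pixels. Because the
#' coupling is a Gaussian copula, the population Kendall tau of each stratum
#' has the closed form `(2/pi) * asin(rho)`, which downstream recovery tests
#' use as ground truth.
#'
#' The coupling and missingness surfaces can be given at three levels of
#' detail; the most specific wins:
#' * a full `n_pixels x 73` matrix (`rho_field`, `obs_prob_field`);
#' * a length-73 per-bin vector (`rho_by_bin`, `obs_prob_by_bin`), optionally
#'   modulated across space by `rho_spatial_amp`;
#' * scalars (`rho_mean` with `rho_seasonal_amp`, `obs_prob`).
#'
#' @param lake_id identifier.
#' @param center_lat,center_lon lake centre, decimal degrees WGS84.
#' @param n_pixels_lat,n_pixels_lon grid extent in 0.1-degree cells.
#' @param years number of simulated years (>= 8 so the minimum-sample rule
#'   can be met); the default 15 matches a 2002--2016 style record.
#' @param start_year first calendar year.
#' @param median_chla lake median chl-a, mg m^-3.
#' @param rho_mean,rho_seasonal_amp,rho_spatial_amp scalar copula
#'   correlation, its seasonal modulation amplitude, and a linear
#'   north--south spatial modulation amplitude.
#' @param rho_by_bin optional length-73 vector of per-bin copula correlations.
#' @param rho_field optional `n_pixels x 73` matrix of copula correlations.
#' @param seasonal_amplitude_lst seasonal LST cycle amplitude, degrees C.
#' @param seasonal_amplitude_chla seasonal chl-a cycle amplitude on the log
#'   scale (dimensionless).
#' @param mean_lst annual mean LST, degrees C.
#' @param sd_lst,sd_chla interannual anomaly scales (degrees C; log units).
#' @param lst_peak_doy,chla_peak_doy days of year of the seasonal maxima.
#' @param obs_prob scalar observation probability per (pixel, bin, year) cell.
#' @param obs_prob_by_bin,obs_prob_field finer-grained observation
#'   probabilities (length 73; `n_pixels x 73`).
#' @param attributes optional named list of the eight cross-lake catalog
#'   predictors.
#' @param seed RNG seed used by [simulate_observations()].
#' @return an object of class `lake_scenario`.
#' @export
lake_scenario <- function(lake_id = "lake_1", center_lat = 45,
                          center_lon = 10, n_pixels_lat = 10L,
                          n_pixels_lon = 10L, years = 15L,
                          start_year = 2002L, median_chla = 3,
                          rho_mean = 0, rho_seasonal_amp = 0,
                          rho_spatial_amp = 0, rho_by_bin = NULL,
                          rho_field = NULL, seasonal_amplitude_lst = 8,
                          seasonal_amplitude_chla = 0.5, mean_lst = 12,
                          sd_lst = 1.5, sd_chla = 0.6, lst_peak_doy = 200,
                          chla_peak_doy = 140, obs_prob = 0.8,
                          obs_prob_by_bin = NULL, obs_prob_field = NULL,
                          attributes = NULL, seed = 1L) {
  n_bins <- 73L
  n_pix <- as.integer(n_pixels_lat) * as.integer(n_pixels_lon)
  if (years < 8L) stop_invalid("years must be >= 8 (minimum-sample rule)")
  if (median_chla <= 0) stop_invalid("median_chla must be positive")

  bin_mid_doy <- (seq_len(n_bins) - 1) * 5 + 3

  rho <- if (!is.null(rho_field)) {
    if (!is.matrix(rho_field) || nrow(rho_field) != n_pix ||
        ncol(rho_field) != n_bins) {
      stop_invalid("rho_field must be an n_pixels x 73 matrix")
    }
    rho_field
  } else {
    by_bin <- if (!is.null(rho_by_bin)) {
      if (length(rho_by_bin) != n_bins) stop_invalid("rho_by_bin must have length 73")
      rho_by_bin
    } else {
      rho_mean + rho_seasonal_amp * cos(2 * pi * (bin_mid_doy - lst_peak_doy) / 365)
    }
    sp <- if (n_pixels_lat > 1) {
      rho_spatial_amp * (seq_len(n_pixels_lat) - (n_pixels_lat + 1) / 2) /
        ((n_pixels_lat - 1) / 2)
    } else {
      rep(0, n_pixels_lat)
    }
    outer(rep(sp, times = n_pixels_lon), rep(1, n_bins)) +
      outer(rep(1, n_pix), by_bin)
  }
  if (any(abs(rho) >= 1)) {
    stop_invalid("copula correlations must lie strictly within (-1, 1)")
  }

  pobs <- if (!is.null(obs_prob_field)) {
    if (!is.matrix(obs_prob_field) || nrow(obs_prob_field) != n_pix ||
        ncol(obs_prob_field) != n_bins) {
      stop_invalid("obs_prob_field must be an n_pixels x 73 matrix")
    }
    obs_prob_field
  } else if (!is.null(obs_prob_by_bin)) {
    if (length(obs_prob_by_bin) != n_bins) {
      stop_invalid("obs_prob_by_bin must have length 73")
    }
    outer(rep(1, n_pix), obs_prob_by_bin)
  } else {
    matrix(obs_prob, n_pix, n_bins)
  }
  if (any(pobs < 0 | pobs > 1)) {
    stop_invalid("observation probabilities must lie in [0, 1]")
  }

  structure(list(lake_id = lake_id, center_lat = center_lat,
                 center_lon = center_lon,
                 n_pixels_lat = as.integer(n_pixels_lat),
                 n_pixels_lon = as.integer(n_pixels_lon),
                 years = as.integer(years), start_year = as.integer(start_year),
                 median_chla = median_chla, rho = rho, obs_prob = pobs,
                 seasonal_amplitude_lst = seasonal_amplitude_lst,
                 seasonal_amplitude_chla = seasonal_amplitude_chla,
                 mean_lst = mean_lst, sd_lst = sd_lst, sd_chla = sd_chla,
                 lst_peak_doy = lst_peak_doy, chla_peak_doy = chla_peak_doy,
                 bin_mid_doy = bin_mid_doy, attributes = attributes,
                 seed = as.numeric(seed)),
            class = "lake_scenario")
}

scenario_pixel_coords <- function(scenario) {
  base_lat <- round(scenario$center_lat, 1) -
    scenario$n_pixels_lat / 2 * 0.1 + 0.05
  base_lon <- round(scenario$center_lon, 1) -
    scenario$n_pixels_lon / 2 * 0.1 + 0.05
  lat <- base_lat + (seq_len(scenario$n_pixels_lat) - 1) * 0.1
  lon <- base_lon + (seq_len(scenario$n_pixels_lon) - 1) * 0.1
  # pixel index runs lat-fastest, matching the rho/obs_prob row order
  data.frame(lat = rep(lat, times = scenario$n_pixels_lon),
             lon = rep(lon, each = scenario$n_pixels_lat))
}

#' Generate a catalog of synthetic lake scenarios
#'
#' Draws `n_lakes` scenarios along a log-uniform trophic-state gradient
#' (median chl-a spanning roughly 0.1--100 mg m^-3). With `amplification`
#' on, each lake's mean copula correlation is a strictly increasing linear
#' function of log10 median chl-a crossing zero mid-gradient, so that
#' phytoplankton-rich lakes warm-covary positively and phytoplankton-poor
#' lakes negatively -- the cross-lake truth the inference should recover.
#' With `amplification` off all lakes share a constant coupling.
#'
#' The attribute table carries the eight cross-lake predictors; a fraction
#' `missing_frac` of the non-key entries (elevation, perimeter, mean depth,
#' median temperature) is deliberately blanked to exercise missing-data
#' tolerance.
#'
#' @param n_lakes number of lakes (>= 1).
#' @param seed RNG seed.
#' @param amplification logical; couple mean rho to trophic state?
#' @param rho_span half-range of the mean copula correlation under
#'   amplification (lakes span roughly `-rho_span..+rho_span`).
#' @param rho_constant mean copula correlation used when amplification is
#'   off.
#' @param rho_seasonal_amp within-lake seasonal modulation of the coupling
#'   (default 0.25): real coupling strength varies over the year, and this
#'   structure is what the per-lake debiasing surface has to learn.
#' @param missing_frac fraction of blanked entries per non-key attribute.
#' @param ... further arguments passed to [lake_scenario()] (e.g. grid size,
#'   years, missingness).
#' @return an object of class `lake_catalog`: list with `scenarios` (list of
#'   [lake_scenario()]) and `attributes` (data frame, one row per lake).
#' @export
generate_lake_catalog <- function(n_lakes, seed = 1L, amplification = TRUE,
                                  rho_span = 0.6, rho_constant = 0,
                                  rho_seasonal_amp = 0.25,
                                  missing_frac = 0.1, ...) {
  if (!is.numeric(n_lakes) || length(n_lakes) != 1L || n_lakes < 1) {
    stop_invalid("n_lakes must be a positive count")
  }
  n_lakes <- as.integer(n_lakes)
  with_seed(seed, {
    log_chla <- runif(n_lakes, -1, 2)          # 0.1 .. 100 mg m^-3
    lat <- runif(n_lakes, -55, 65)
    elevation <- round(exp(runif(n_lakes, 0, 8)))   # 1 m .. ~3 km
    surface_area <- exp(runif(n_lakes, log(500), log(80000)))  # km^2
    perimeter <- 4 * sqrt(surface_area) * exp(rnorm(n_lakes, 0.3, 0.3))
    mean_depth <- exp(runif(n_lakes, log(2), log(300)))
    salinity <- ifelse(runif(n_lakes) < 0.12, "saline", "fresh")
    med_temp <- pmax(1, 26 - 0.28 * abs(lat) + rnorm(n_lakes, 0, 1.5))
    rho_mean <- if (amplification) {
      rho_span * (log_chla - 0.5) / 1.5
    } else {
      rep(rho_constant, n_lakes)
    }
    lake_ids <- sprintf("lake_%03d", seq_len(n_lakes))
    attrs <- data.frame(lake_id = lake_ids, elevation = elevation,
                        latitude = lat, surface_area = surface_area,
                        perimeter = perimeter, mean_depth = mean_depth,
                        salinity_class = salinity,
                        median_temperature = med_temp,
                        median_chla = 10^log_chla,
                        true_rho_mean = rho_mean,
                        stringsAsFactors = FALSE)
    for (col in c("elevation", "perimeter", "mean_depth",
                  "median_temperature")) {
      blank <- runif(n_lakes) < missing_frac
      attrs[[col]][blank] <- NA
    }
    scen_seeds <- floor(runif(n_lakes, 1, 2^31 - 1))
    scenarios <- lapply(seq_len(n_lakes), function(i) {
      lake_scenario(lake_id = lake_ids[i], center_lat = lat[i],
                    center_lon = runif(1, -170, 170),
                    median_chla = 10^log_chla[i], rho_mean = rho_mean[i],
                    rho_seasonal_amp = rho_seasonal_amp,
                    mean_lst = med_temp[i],
                    attributes = as.list(attrs[i, , drop = FALSE]),
                    seed = scen_seeds[i], ...)
    })
    structure(list(scenarios = scenarios, attributes = attrs),
              class = "lake_catalog")
  })
}

#' Simulate a lake's coincident satellite observation record
#'
#' For every (pixel, 5-day bin, year) cell a latent bivariate standard
#' normal anomaly pair with the scenario's copula correlation is drawn; LST
#' is the seasonal mean plus a scaled anomaly and chl-a is the lake median
#' times a lognormal seasonal/anomaly factor, so chl-a is strictly positive
#' and the within-stratum population Kendall tau is `(2/pi) * asin(rho)`.
#' Cells are then retained independently with the scenario's observation
#' probability, emulating cloud/ice gaps that can oversample seasons or
#' pixels.
#'
#' @param scenario a [lake_scenario()].
#' @param seed optional override of the scenario seed.
#' @return an object of class `lake_simulation`: list with `observations`
#'   (data frame: lake_id, lat, lon, date, year, doy_bin, lst, chla) and
#'   `truth` (class `lake_truth`: per-stratum `rho` and `true_tau`, and the
#'   balanced lake-wide mean `true_r_lake`).
#' @export
simulate_observations <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "lake_scenario"))
  n_bins <- 73L
  n_pix <- scenario$n_pixels_lat * scenario$n_pixels_lon
  years <- scenario$years
  coords <- scenario_pixel_coords(scenario)

  # cell order: pixel fastest, then bin, then year
  pix_i <- rep(seq_len(n_pix), times = n_bins * years)
  bin_i <- rep(rep(seq_len(n_bins), each = n_pix), times = years)
  year_i <- rep(seq_len(years), each = n_pix * n_bins)
  rho_cell <- scenario$rho[cbind(pix_i, bin_i)]

  doy <- scenario$bin_mid_doy[bin_i]
  seas_lst <- scenario$mean_lst + scenario$seasonal_amplitude_lst *
    cos(2 * pi * (doy - scenario$lst_peak_doy) / 365)
  seas_chla <- scenario$seasonal_amplitude_chla *
    cos(2 * pi * (doy - scenario$chla_peak_doy) / 365)

  with_seed(seed, {
    z1 <- rnorm(length(pix_i))
    z2 <- rho_cell * z1 + sqrt(1 - rho_cell^2) * rnorm(length(pix_i))
    keep <- runif(length(pix_i)) < scenario$obs_prob[cbind(pix_i, bin_i)]

    lst <- seas_lst + scenario$sd_lst * z1
    chla <- scenario$median_chla * exp(seas_chla + scenario$sd_chla * z2)
    year <- scenario$start_year + year_i - 1L
    date <- as.Date(paste0(year, "-01-01")) + (doy - 1)

    obs <- data.frame(lake_id = scenario$lake_id,
                      lat = coords$lat[pix_i], lon = coords$lon[pix_i],
                      date = date, year = year, doy_bin = bin_i,
                      lst = lst, chla = chla,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(obs) <- NULL

    strata <- data.frame(lake_id = scenario$lake_id,
                         lat = coords$lat[rep(seq_len(n_pix), n_bins)],
                         lon = coords$lon[rep(seq_len(n_pix), n_bins)],
                         doy_bin = rep(seq_len(n_bins), each = n_pix),
                         rho = as.vector(scenario$rho),
                         stringsAsFactors = FALSE)
    strata$true_tau <- (2 / pi) * asin(strata$rho)
    truth <- structure(list(strata = strata,
                            true_r_lake = mean(strata$true_tau)),
                       class = "lake_truth")
    structure(list(observations = obs, truth = truth,
                   scenario = scenario),
              class = "lake_simulation")
  })
}

#' Simulate in-situ point samples matched to a satellite record
#'
#' Draws `n_samples` observed grid cells and perturbs the satellite values
#' with configurable measurement error: additive Gaussian noise for LST and
#' a multiplicative bias (plus optional lognormal noise) for chl-a, so that
#' standardized-major-axis validation slopes different from 1 can be
#' produced on purpose. Every sample has, by construction, an exactly
#' coincident satellite pair in the grid.
#'
#' @param scenario the generating [lake_scenario()].
#' @param grid the `observations` data frame of a [simulate_observations()]
#'   result (non-empty).
#' @param error_sd_lst additive LST error standard deviation, degrees C.
#' @param error_bias_chla multiplicative chl-a bias (1 = unbiased).
#' @param error_cv_chla lognormal chl-a noise scale on the log scale
#'   (default 0).
#' @param n_samples number of samples (>= 3, <= available cells).
#' @param seed RNG seed.
#' @return data frame with columns lake_id, date, lat, lon, insitu_lst,
#'   insitu_chla.
#' @export
simulate_insitu_samples <- function(scenario, grid, error_sd_lst = 0.4,
                                    error_bias_chla = 1,
                                    error_cv_chla = 0, n_samples = 50L,
                                    seed = 1L) {
  if (nrow(grid) < 1L) stop_invalid("satellite grid is empty")
  if (n_samples < 3L) stop_invalid("n_samples must be >= 3")
  if (n_samples > nrow(grid)) {
    stop_invalid("n_samples (", n_samples, ") exceeds available cells (",
                 nrow(grid), ")")
  }
  with_seed(seed, {
    idx <- sample.int(nrow(grid), n_samples)
    g <- grid[idx, , drop = FALSE]
    data.frame(lake_id = g$lake_id, date = g$date, lat = g$lat, lon = g$lon,
               insitu_lst = g$lst + rnorm(n_samples, 0, error_sd_lst),
               insitu_chla = g$chla * error_bias_chla *
                 exp(rnorm(n_samples, 0, error_cv_chla)),
               stringsAsFactors = FALSE)
  })
}
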
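#' Day-of-year bin index for dates
#'
#' 5-day seasonal strata anchored at Jan 1 of each calendar year: bin
#' `floor((doy - 1) / width) + 1`, with the final bin absorbing the leap
#' day so every year has the same number of strata (73 for the default
#' 5-day width).
#'
#' @param dates a `Date` vector.
#' @param width bin width in days (default 5).
#' @return integer bin indices.
#' @export
doy_bin_of <- function(dates, width = 5L) {
  doy <- as.integer(strftime(dates, "%j"))
  n_bins <- (365L %/% as.integer(width)) + as.integer(365L %% width > 0)
  pmin(((doy - 1L) %/% as.integer(width)) + 1L, n_bins)
}

snap_cell <- function(x, cell_size) {
  floor(x / cell_size + 1e-9)
}

#' Spatial median filter and subset to a coarser grid
#'
#' Reduces a native-resolution grid to `cell_size`-degree cells: per
#' timestamp and per half-open cell `[k*cell, (k+1)*cell)` the output value
#' is the median of all non-missing native pixels falling in the cell, and
#' the reported coordinate is the cell centre. Cells with no contributing
#' pixel are absent from the output. Even-sized cells use the conventional
#' mean of the two central order statistics.
#'
#' @param grid data frame with columns `lat`, `lon`, `date`, `value`.
#' @param cell_size output cell size in degrees (default 0.1).
#' @return data frame with columns `lat`, `lon`, `date`, `value` at the
#'   reduced resolution.
#' @export
spatial_median_subset <- function(grid, cell_size = 0.1) {
  if (cell_size <= 0) stop_invalid("cell_size must be positive")
  need <- c("lat", "lon", "date", "value")
  if (!all(need %in% names(grid))) {
    stop_invalid("grid must have columns ", paste(need, collapse = ", "))
  }
  grid <- grid[!is.na(grid$value), , drop = FALSE]
  if (nrow(grid) == 0L) {
    return(data.frame(lat = numeric(0), lon = numeric(0),
                      date = grid$date[0], value = numeric(0)))
  }
  ci <- snap_cell(grid$lat, cell_size)
  cj <- snap_cell(grid$lon, cell_size)
  out <- aggregate(list(value = grid$value),
                   by = list(date = grid$date, cell_lat = ci, cell_lon = cj),
                   FUN = median)
  data.frame(lat = (out$cell_lat + 0.5) * cell_size,
             lon = (out$cell_lon + 0.5) * cell_size,
             date = out$date, value = out$value)
}

#' Temporal median filter and subset to fixed-width day-of-year bins
#'
#' Per pixel, calendar year and bin, the output is the median of the
#' non-missing daily values in the bin, stamped with the bin's midpoint
#' date.
#'
#' @param series data frame with columns `lat`, `lon`, `date`, `value`.
#' @param window_days bin width in days (default 5).
#' @return data frame with columns `lat`, `lon`, `year`, `doy_bin`, `date`
#'   (bin midpoint), `value`.
#' @export
temporal_median_subset <- function(series, window_days = 5L) {
  if (window_days <= 0) stop_invalid("window_days must be positive")
  need <- c("lat", "lon", "date", "value")
  if (!all(need %in% names(series))) {
    stop_invalid("series must have columns ", paste(need, collapse = ", "))
  }
  series <- series[!is.na(series$value), , drop = FALSE]
  if (nrow(series) == 0L) {
    return(data.frame(lat = numeric(0), lon = numeric(0), year = integer(0),
                      doy_bin = integer(0), date = series$date[0],
                      value = numeric(0)))
  }
  year <- as.integer(strftime(series$date, "%Y"))
  bin <- doy_bin_of(series$date, width = window_days)
  out <- aggregate(list(value = series$value),
                   by = list(lat = series$lat, lon = series$lon,
                             year = year, doy_bin = bin),
                   FUN = median)
  mid_doy <- (out$doy_bin - 1L) * as.integer(window_days) +
    (as.integer(window_days) + 1L) %/% 2L
  out$date <- as.Date(paste0(out$year, "-01-01")) + (mid_doy - 1L)
  out[, c("lat", "lon", "year", "doy_bin", "date", "value")]
}

#' Match coincident LST and chl-a cells
#'
#' Inner join of two reduced grids on (pixel, year, day-of-year bin); only
#' cells observed in both variables survive, mirroring the construction of
#' a merged coincident satellite record. Both inputs must use the same cell
#' and bin conventions.
#'
#' @param lst_grid,chla_grid data frames with columns `lat`, `lon`, `year`,
#'   `doy_bin`, `value` (plus optional `lake_id`, `date`).
#' @return data frame of paired observations with columns `lat`, `lon`,
#'   `year`, `doy_bin`, `lst`, `chla` (plus `lake_id`/`date` when present in
#'   the LST input).
#' @export
match_coincident <- function(lst_grid, chla_grid) {
  keys <- c("lat", "lon", "year", "doy_bin")
  for (nm in keys) {
    if (!nm %in% names(lst_grid) || !nm %in% names(chla_grid)) {
      stop_invalid("both grids need key column `", nm, "`")
    }
  }
  if (nrow(lst_grid) > 0 && nrow(chla_grid) > 0) {
    # different cell anchoring produces centre offsets that are not
    # multiples of the implied cell size; detect gross mismatch
    frac <- function(x) {
      f <- (round(x * 1e6) %% 1e5) / 1e5  # fractional part of x / 0.1
      sort(unique(round(f, 3)))
    }
    if (!any(frac(lst_grid$lat) %in% frac(chla_grid$lat))) {
      stop(errorCondition("grid cell anchors differ between inputs",
                          class = c("lakecor_config_error", "error")))
    }
  }
  if ("lake_id" %in% names(lst_grid)) keys <- c("lake_id", keys)
  a <- lst_grid
  b <- chla_grid
  names(a)[names(a) == "value"] <- "lst"
  names(b)[names(b) == "value"] <- "chla"
  b <- b[, c(intersect(keys, names(b)), "chla")]
  merged <- merge(a, b, by = intersect(keys, names(b)), sort = TRUE)
  rownames(merged) <- NULL
  merged
}

#' Assign points to lakes via cell masks
#'
#' Labels each point by the lake whose mask contains its 0.1-degree cell.
#' Masks must be disjoint; points outside every mask are dropped and
#' counted in the `n_dropped` attribute of the result.
#'
#' @param points data frame with `lat`, `lon` columns.
#' @param lake_masks data frame with `lake_id`, `lat`, `lon` cell centres.
#' @param cell_size grid cell size (default 0.1 degrees).
#' @return `points` with a `lake_id` column; dropped-point count in
#'   `attr(, "n_dropped")`.
#' @export
assign_lakes <- function(points, lake_masks, cell_size = 0.1) {
  key <- function(lat, lon) {
    paste(snap_cell(lat, cell_size), snap_cell(lon, cell_size), sep = ":")
  }
  mk <- key(lake_masks$lat, lake_masks$lon)
  dup <- duplicated(mk) | duplicated(mk, fromLast = TRUE)
  if (any(dup)) {
    bad <- sort(unique(lake_masks$lake_id[dup]))
    stop(errorCondition(
      paste0("lake masks overlap (lakes: ", paste(bad, collapse = ", "), ")"),
      class = c("lakecor_config_error", "error")))
  }
  pk <- key(points$lat, points$lon)
  hit <- match(pk, mk)
  out <- points[!is.na(hit), , drop = FALSE]
  out$lake_id <- lake_masks$lake_id[hit[!is.na(hit)]]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(is.na(hit))
  out
}
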
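#' Subdivide paired observations by pixel and day-of-year stratum
#'
#' Groups a paired LST/chl-a table by (lake, pixel, day-of-year bin); each
#' subdivision holds at most one pair per year. Multiple same-year entries
#' (which should not occur after median subsetting) are collapsed to their
#' medians with a warning.
#'
#' @param pairs data frame with columns `lake_id`, `lat`, `lon`, `doy_bin`,
#'   `year`, `lst`, `chla`.
#' @return a list of class `lake_subdivisions`: data frames with columns
#'   `year`, `lst`, `chla`, named by `lake_id|lat|lon|doy_bin` key, each
#'   carrying `lake_id`, `lat`, `lon`, `doy_bin` attributes.
#' @export
subdivide <- function(pairs) {
  need <- c("lake_id", "lat", "lon", "doy_bin", "year", "lst", "chla")
  if (!all(need %in% names(pairs))) {
    stop_invalid("pairs must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(pairs) == 0L) {
    return(structure(list(), class = "lake_subdivisions"))
  }
  key <- paste(pairs$lake_id, pairs$lat, pairs$lon, pairs$doy_bin, sep = "|")
  idx <- split(seq_len(nrow(pairs)), key)
  n_collapsed <- 0L
  out <- lapply(idx, function(i) {
    d <- pairs[i, c("year", "lst", "chla")]
    if (anyDuplicated(d$year)) {
      n_collapsed <<- n_collapsed + 1L
      d <- aggregate(d[c("lst", "chla")], by = list(year = d$year),
                     FUN = median)
    }
    d <- d[order(d$year), , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "lake_id") <- pairs$lake_id[i[1L]]
    attr(d, "lat") <- pairs$lat[i[1L]]
    attr(d, "lon") <- pairs$lon[i[1L]]
    attr(d, "doy_bin") <- pairs$doy_bin[i[1L]]
    d
  })
  if (n_collapsed > 0L) {
    warning(n_collapsed, " subdivision(s) had multiple same-year entries; ",
            "collapsed to medians", call. = FALSE)
  }
  structure(out, class = "lake_subdivisions")
}

#' Field of interannual Kendall correlations across subdivisions
#'
#' Computes Kendall's tau-b between LST and chl-a across years within every
#' (pixel, day-of-year) subdivision that has at least `min_obs` coincident
#' pairs (default 8, the minimum-sample rule). Subdivisions below the
#' threshold, or whose correlation is undefined because one variable is
#' completely tied, are counted in attributes and not emitted.
#'
#' @param subdivisions a [subdivide()] result, or a paired-observation data
#'   frame (which is subdivided first).
#' @param min_obs minimum number of coincident year pairs (default 8).
#' @return data frame of class `correlation_field` with columns `lake_id`,
#'   `lat`, `lon`, `doy_bin`, `n_obs`, `tau`, `p_value`; attributes
#'   `n_below_min` and `n_undefined` count the skipped subdivisions.
#' @export
correlation_field <- function(subdivisions, min_obs = 8L) {
  if (is.data.frame(subdivisions)) subdivisions <- subdivide(subdivisions)
  stopifnot(inherits(subdivisions, "lake_subdivisions"))
  n_sub <- length(subdivisions)
  lake_id <- character(n_sub); lat <- numeric(n_sub); lon <- numeric(n_sub)
  doy_bin <- integer(n_sub); n_obs <- integer(n_sub)
  tau <- numeric(n_sub); p_value <- numeric(n_sub)
  keep <- logical(n_sub)
  n_below <- 0L; n_undef <- 0L
  for (k in seq_len(n_sub)) {
    d <- subdivisions[[k]]
    if (nrow(d) < min_obs) { n_below <- n_below + 1L; next }
    kt <- kendall_tau(d$lst, d$chla)
    if (is.na(kt$tau)) { n_undef <- n_undef + 1L; next }
    keep[k] <- TRUE
    lake_id[k] <- attr(d, "lake_id"); lat[k] <- attr(d, "lat")
    lon[k] <- attr(d, "lon"); doy_bin[k] <- attr(d, "doy_bin")
    n_obs[k] <- nrow(d); tau[k] <- kt$tau; p_value[k] <- kt$p_value
  }
  out <- data.frame(lake_id = lake_id[keep], lat = lat[keep],
                    lon = lon[keep], doy_bin = doy_bin[keep],
                    n_obs = n_obs[keep], tau = tau[keep],
                    p_value = p_value[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_below_min") <- n_below
  attr(out, "n_undefined") <- n_undef
  class(out) <- c("correlation_field", "data.frame")
  out
}
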
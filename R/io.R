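CLIMATE_COLS <- c("site_id", "date", "tmax", "tmin", "tavg")
QY_COLS <- c("site_id", "date", "line", "replicate", "qy")

#' Read and write daily-climate CSV files
#'
#' The daily-climate schema is `site_id, date, tmax, tmin, tavg` with
#' ISO-8601 dates and empty fields for missing temperatures. The reader
#' returns one `daily_temps` series per site, inserting explicit missing
#' rows for absent days so every series is gap-free; it rejects unknown
#' headers, malformed dates or temperatures (naming the line) and duplicate
#' (site, date) rows. Write-then-read round-trips a series exactly.
#'
#' @param path file path.
#' @param series a `daily_temps`, or a list of them.
#' @return `read_climate_csv()`: a named list of `daily_temps`, one per
#'   site. `write_climate_csv()`: the path, invisibly.
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), CLIMATE_COLS))
    stop_("unknown climate schema: expected columns %s",
          paste(CLIMATE_COLS, collapse = ", "))
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop_("malformed date at line %d: '%s'", which(is.na(dates))[1L] + 1L,
          raw$date[which(is.na(dates))[1L]])
  nums <- lapply(raw[c("tmax", "tmin", "tavg")], function(v) {
    v[v == ""] <- NA
    x <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(x)
    if (any(bad))
      stop_("non-numeric temperature at line %d: '%s'",
            which(bad)[1L] + 1L, v[which(bad)[1L]])
    x
  })
  key <- paste(raw$site_id, raw$date)
  if (anyDuplicated(key))
    stop_("duplicate (site, date) row at line %d: %s",
          which(duplicated(key))[1L] + 1L, key[which(duplicated(key))[1L]])
  out <- list()
  for (sid in unique(raw$site_id)) {
    sel <- raw$site_id == sid
    d <- dates[sel]
    o <- order(d)
    full <- seq(min(d), max(d), by = 1L)
    idx <- match(full, d[o])
    out[[sid]] <- daily_temps(sid, full,
                              nums$tmax[sel][o][idx],
                              nums$tmin[sel][o][idx],
                              nums$tavg[sel][o][idx])
  }
  out
}

#' @rdname read_climate_csv
#' @export
write_climate_csv <- function(series, path) {
  if (inherits(series, "daily_temps")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write QY observation CSV files
#'
#' Schema: `site_id, date, line, replicate, qy` with ISO-8601 dates and QY
#' in \eqn{[0, 1]}.
#'
#' @param path file path.
#' @param observations a `qy_obs` data frame.
#' @return `read_qy_csv()`: a `qy_obs` data frame. `write_qy_csv()`: the
#'   path, invisibly.
#' @export
read_qy_csv <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  raw <- read.csv(path, check.names = FALSE)
  if (!identical(names(raw), QY_COLS))
    stop_("unknown QY schema: expected columns %s",
          paste(QY_COLS, collapse = ", "))
  dates <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
  if (anyNA(dates))
    stop_("malformed date at line %d", which(is.na(dates))[1L] + 1L)
  qy_obs(raw$site_id, dates, raw$line, raw$replicate, raw$qy)
}

#' @rdname read_qy_csv
#' @export
write_qy_csv <- function(observations, path) {
  df <- as.data.frame(observations)
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Generate a synthetic network of observation sites
#'
#' Places `n_sites` sites on a jittered lattice over the given coordinate
#' ranges and assigns each a mean climate that cools linearly with absolute
#' latitude: `annual_mean = base_mean + lat_slope * |lat|`. The defaults
#' emulate a mid-latitude national station network (Japan-like, 30-40 N,
#' 128-144 E, ~14.5 degC at 35 N with a -0.6 degC per degree latitude
#' lapse).
#'
#' @param n_sites number of sites, >= 1.
#' @param lat_range,lon_range coordinate ranges, degrees.
#' @param base_mean annual-mean temperature at latitude 0, degC.
#' @param lat_slope change in annual mean per degree of absolute latitude.
#' @param climate template [climate_params()] supplying the non-mean
#'   parameters (amplitude, noise, diurnal range, warming, missing
#'   fraction).
#' @param seed integer seed.
#' @return A data frame of class `site_network` with columns `site_id`,
#'   `lat`, `lon`, `annual_mean`; the template is kept in
#'   `attr(, "climate")`.
#' @export
gen_site_network <- function(n_sites, lat_range = c(30, 40),
                             lon_range = c(128, 144), base_mean = 35.5,
                             lat_slope = -0.6,
                             climate = climate_params(), seed = 1L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop_("`n_sites` must be >= 1")
  if (diff(range(lat_range)) < 0 || length(lat_range) != 2L ||
      length(lon_range) != 2L)
    stop_("coordinate ranges must be c(low, high)")
  if (lat_range[2L] < lat_range[1L] || lon_range[2L] < lon_range[1L])
    stop_("empty coordinate range")
  n_sites <- as.integer(n_sites)
  ncol_ <- ceiling(sqrt(n_sites)); nrow_ <- ceiling(n_sites / ncol_)
  cells <- expand.grid(i = seq_len(ncol_), j = seq_len(nrow_))[seq_len(n_sites), ]
  local_seed(seed, {
    lat <- lat_range[1L] + (cells$j - runif(n_sites)) *
      diff(lat_range) / nrow_
    lon <- lon_range[1L] + (cells$i - runif(n_sites)) *
      diff(lon_range) / ncol_
    structure(data.frame(site_id = sprintf("site%03d", seq_len(n_sites)),
                         lat = lat, lon = lon,
                         annual_mean = base_mean + lat_slope * abs(lat)),
              climate = climate, class = c("site_network", "data.frame"))
  })
}

#' Realize daily temperature series for a site network
#'
#' Generates one `daily_temps` series per network site from the network's
#' climate template, substituting each site's latitude-driven annual mean.
#' Per-site seeds are derived deterministically from `seed`.
#'
#' @param network a [gen_site_network()] result.
#' @param start_date first day.
#' @param n_days days per series.
#' @param seed integer base seed.
#' @return A list of site records (`site_id`, `lat`, `lon`, `series`)
#'   suitable for [site_period_max_cu()].
#' @export
gen_network_series <- function(network, start_date, n_days, seed = 1L) {
  stopifnot(inherits(network, "site_network"))
  tmpl <- attr(network, "climate")
  lapply(seq_len(nrow(network)), function(i) {
    p <- tmpl
    p$annual_mean <- network$annual_mean[i]
    list(site_id = network$site_id[i], lat = network$lat[i],
         lon = network$lon[i],
         series = gen_temperature_series(p, start_date, n_days,
                                         site_id = network$site_id[i],
                                         seed = seed + i))
  })
}
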
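#' Period-maximum chilling unit per site
#'
#' For each site: apply the missing-rate filter on the statistic the CU
#' uses, impute the admitted series, compute the CU series and take its
#' maximum over the period. Sites failing the filter (or too short for the
#' window) are excluded and listed with the reason; processing order does
#' not affect per-site results.
#'
#' @param sites a list of site records, each a list with `site_id`, `lat`,
#'   `lon` and `series` (a `daily_temps`).
#' @param config a [cu_config()].
#' @param start,end period bounds passed to [period_max_cu()].
#' @param max_rate missing-rate admission bound (default 0.1).
#' @return A list with `values` (data frame `site_id`, `lat`, `lon`,
#'   `cu_max`) and `excluded` (data frame `site_id`, `reason`).
#' @export
site_period_max_cu <- function(sites, config, start = NULL, end = NULL,
                               max_rate = 0.1) {
  stopifnot(inherits(config, "cu_config"))
  vals <- list(); excl <- list()
  for (site in sites) {
    res <- tryCatch({
      flt <- filter_by_missing_rate(site$series, config$temp_stat, max_rate)
      if (!flt$accepted)
        stop_("missing rate %.3f exceeds %.3f", flt$rate, max_rate)
      s <- impute_missing(site$series)
      cu <- compute_cu(s, config, quiet = TRUE)
      period_max_cu(cu, start = start, end = end)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(site_id = site$site_id,
                                              reason = conditionMessage(res))
    } else {
      vals[[length(vals) + 1L]] <- data.frame(site_id = site$site_id,
                                              lat = site$lat, lon = site$lon,
                                              cu_max = res)
    }
  }
  list(values = if (length(vals)) do.call(rbind, vals) else
         data.frame(site_id = character(), lat = numeric(), lon = numeric(),
                    cu_max = numeric()),
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(site_id = character(), reason = character()))
}

#' Interpolate site values to a latitude/longitude grid with an SVM
#'
#' Trains a radial-basis support vector machine on (latitude, longitude) ->
#' value (regression mode) or -> class (classification mode) at the
#' observation sites and predicts every cell of a regular lat/lon lattice
#' (cell centres, origin at the bounding box's south-west corner).
#' Coordinates are raw degrees; set `scale_lon_by_cos_lat = TRUE` to scale
#' longitude by cos(latitude) for high-latitude work. Deterministic under
#' the given seed (the RBF bandwidth estimate is randomized).
#'
#' @param sites data frame with columns `lat`, `lon` and `value` (numeric
#'   for regression; logical or factor for classification). At least 10
#'   sites; classification needs both classes present.
#' @param grid_resolution lattice spacing, degrees.
#' @param mode `"regression"` or `"classification"`.
#' @param bbox `c(lat_min, lat_max, lon_min, lon_max)`; default the range of
#'   the sites.
#' @param C SVM cost parameter (kernlab default 1).
#' @param kpar RBF kernel parameters; `"automatic"` estimates the bandwidth.
#' @param scale_lon_by_cos_lat scale longitude by cos(latitude).
#' @param seed integer seed (caller RNG state preserved).
#' @return A `suitability_grid` data frame with columns `lat`, `lon`,
#'   `value` (numeric prediction, or logical class in classification mode),
#'   with attributes `grid_resolution`, `mode`, `training_pred` (predictions
#'   at the training sites) and `model` (the fitted `ksvm`).
#' @export
svm_interpolate <- function(sites, grid_resolution = 2,
                            mode = c("regression", "classification"),
                            bbox = NULL, C = 1, kpar = "automatic",
                            scale_lon_by_cos_lat = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(sites), all(c("lat", "lon", "value") %in% names(sites)))
  if (nrow(sites) < 10L)
    stop_("need at least 10 sites to interpolate, got %d", nrow(sites))
  y <- sites$value
  if (mode == "regression") {
    if (any(!is.finite(y))) stop_("site values must be finite")
  } else {
    y <- factor(as.logical(y), levels = c(FALSE, TRUE))
    if (length(unique(y[!is.na(y)])) < 2L)
      stop_("classification requires both classes among the sites")
  }
  coord <- function(lat, lon)
    cbind(lat = lat,
          lon = if (scale_lon_by_cos_lat) lon * cos(lat * pi / 180) else lon)
  if (is.null(bbox)) bbox <- c(range(sites$lat), range(sites$lon))
  lat_g <- seq(bbox[1L], bbox[2L], by = grid_resolution)
  lon_g <- seq(bbox[3L], bbox[4L], by = grid_resolution)
  cells <- expand.grid(lon = lon_g, lat = lat_g)[, c("lat", "lon")]

  if (mode == "regression" && diff(range(y)) == 0) {
    # a constant field has no margin to fit; predict the constant everywhere
    return(structure(
      data.frame(lat = cells$lat, lon = cells$lon, value = y[1L]),
      grid_resolution = grid_resolution, mode = mode,
      training_pred = rep(y[1L], nrow(sites)), model = NULL,
      class = c("suitability_grid", "data.frame")))
  }

  fit <- local_seed(seed,
    kernlab::ksvm(coord(sites$lat, sites$lon), y,
                  type = if (mode == "regression") "eps-svr" else "C-svc",
                  kernel = "rbfdot", kpar = kpar, C = C))
  pred_cells <- kernlab::predict(fit, coord(cells$lat, cells$lon))
  pred_train <- kernlab::predict(fit, coord(sites$lat, sites$lon))
  if (mode == "classification") {
    pred_cells <- as.logical(pred_cells)
    pred_train <- as.logical(pred_train)
  } else {
    pred_cells <- as.numeric(pred_cells)
    pred_train <- as.numeric(pred_train)
  }
  structure(data.frame(lat = cells$lat, lon = cells$lon, value = pred_cells),
            grid_resolution = grid_resolution, mode = mode,
            training_pred = pred_train, model = fit,
            class = c("suitability_grid", "data.frame"))
}

#' Classify grid cells as suitable for plantation
#'
#' Applies the suitability rule to interpolated values: with
#' `value_kind = "cu_max"` a cell is suitable when its period-maximum CU is
#' at or below the threshold (the canonical cutoff is CU = 35, the exposure
#' at which predicted QY falls to about 0.15); with `value_kind = "qy_min"`
#' when its annual-minimum QY is at or above the threshold. Boundaries are
#' inclusive.
#'
#' @param grid a data frame with a `value` column (e.g. a
#'   `suitability_grid`).
#' @param threshold suitability cutoff (CU or QY, per `value_kind`).
#' @param value_kind `"cu_max"` or `"qy_min"`.
#' @return The grid with a logical `suitable` column; the number of
#'   suitable cells is in `attr(, "n_suitable")`.
#' @examples
#' g <- data.frame(lat = 0, lon = 0:2, value = c(10, 35, 40))
#' classify_suitability(g, 35, "cu_max")$suitable  # TRUE TRUE FALSE
#' @export
classify_suitability <- function(grid, threshold,
                                 value_kind = c("cu_max", "qy_min")) {
  value_kind <- match.arg(value_kind)
  check_number(threshold, "threshold")
  grid$suitable <- if (value_kind == "cu_max") grid$value <= threshold
                   else grid$value >= threshold
  attr(grid, "n_suitable") <- sum(grid$suitable)
  attr(grid, "threshold") <- threshold
  attr(grid, "value_kind") <- value_kind
  grid
}
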
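#' Configuration for a full pipeline run
#'
#' One configuration object drives [run_pipeline()]: synthetic-data
#' generation, missing-rate filtering and imputation, the AIC grid search,
#' held-out-season validation, geographic suitability mapping and the
#' warming-trend extrapolation. Values are validated at construction.
#' `read_pipeline_config()` loads the same structure from a YAML file,
#' filling unspecified fields with these defaults.
#'
#' @param seed master seed; every stage derives its seeds from it.
#' @param n_training_seasons seasons used to fit the grid search.
#' @param start_year first training-season start year.
#' @param climate [climate_params()] for the focal site.
#' @param truth [true_model()] generating the synthetic QY observations.
#' @param n_lines,n_replicates QY sampling design per date.
#' @param sampling_interval days between QY sampling dates.
#' @param spec [grid_spec()] for the search.
#' @param aggregation,eps see [assemble_design()].
#' @param max_missing_rate site admission bound.
#' @param interval_kind validation band, `"confidence"` or `"prediction"`.
#' @param cu_threshold period-max-CU suitability cutoff (default 35).
#' @param qy_threshold annual-min-QY suitability cutoff (default 0.20; 0.4
#'   is the named alternative).
#' @param geo_resolution,geo_bbox geographic grid spacing (degrees) and
#'   bounding box `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param n_sites network size for the simulations.
#' @param warming_rate degC per year imposed in the warming scenario.
#' @param n_warming_seasons seasons of record in the warming scenario.
#' @param target_years years at which suitability is compared.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_training_seasons = 3L,
                            start_year = 2013L,
                            climate = climate_params(),
                            truth = true_model(),
                            n_lines = 2L, n_replicates = 3L,
                            sampling_interval = 14L,
                            spec = grid_spec(),
                            aggregation = "per_line_date_mean",
                            eps = 1e-3,
                            max_missing_rate = 0.1,
                            interval_kind = "confidence",
                            cu_threshold = 35,
                            qy_threshold = 0.20,
                            geo_resolution = 2,
                            geo_bbox = c(24, 46, 122, 146),
                            n_sites = 97L,
                            warming_rate = 0.02,
                            n_warming_seasons = 25L,
                            target_years = c(1995L, 2085L)) {
  cfg <- list(seed = as.integer(seed),
              n_training_seasons = as.integer(n_training_seasons),
              start_year = as.integer(start_year),
              climate = climate, truth = truth,
              n_lines = as.integer(n_lines),
              n_replicates = as.integer(n_replicates),
              sampling_interval = as.integer(sampling_interval),
              spec = spec, aggregation = aggregation, eps = eps,
              max_missing_rate = max_missing_rate,
              interval_kind = interval_kind,
              cu_threshold = cu_threshold, qy_threshold = qy_threshold,
              geo_resolution = geo_resolution, geo_bbox = geo_bbox,
              n_sites = n_sites, warming_rate = warming_rate,
              n_warming_seasons = as.integer(n_warming_seasons),
              target_years = as.integer(target_years))
  stopifnot(inherits(cfg$climate, "climate_params"),
            inherits(cfg$truth, "true_model"),
            inherits(cfg$spec, "grid_spec"))
  check_number(cfg$max_missing_rate, "max_missing_rate", 0, 1)
  check_number(cfg$qy_threshold, "qy_threshold", 0, 1)
  if (cfg$n_training_seasons < 1L) stop_("need at least one training season")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file; top-level keys match the argument names, with
#'   `climate`, `truth` (fields `a`, `b`, `obs_sd`, `cu_type`, `temp_stat`,
#'   `threshold`, `window`) and `spec` given as nested maps.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  y <- yaml::read_yaml(path)
  args <- list()
  plain <- intersect(names(y), setdiff(names(formals(pipeline_config)),
                                       c("climate", "truth", "spec")))
  args[plain] <- y[plain]
  if (!is.null(y$climate)) args$climate <- do.call(climate_params, y$climate)
  if (!is.null(y$truth)) {
    tr <- y$truth
    cfg <- cu_config(tr$cu_type %||% "day_count", tr$temp_stat %||% "max",
                     tr$threshold %||% 9.5, tr$window %||% 46L)
    args$truth <- true_model(cfg, a = tr$a %||% -0.082, b = tr$b %||% 0.85,
                             obs_sd = tr$obs_sd %||% 0.1)
  }
  if (!is.null(y$spec)) args$spec <- do.call(grid_spec, y$spec)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

season_dates <- function(year) {
  list(first = as.Date(sprintf("%d-11-01", year)),
       last = as.Date(sprintf("%d-03-31", year + 1L)))
}

#' Run the full desk-scale analysis pipeline
#'
#' Executes, in order: (1) synthetic climate and biweekly QY observation
#' generation for the training seasons plus one held-out season; (2)
#' missing-rate filtering and imputation; (3) the exhaustive AIC grid
#' search on the training seasons; (4) out-of-sample validation of the
#' selected model on the held-out season with 95% intervals; (5) a
#' geographic suitability map from the period-maximum CU of a synthetic
#' site network, SVM-interpolated and thresholded; (6) a warming-trend
#' simulation: per-site annual-minimum-QY trends under imposed warming,
#' extrapolated to the target years, binarized and mapped. Each stage logs
#' row counts and seeds to `stderr`; with `out_dir` set, stage outputs are
#' written as CSV (plus a YAML run manifest) atomically — files appear
#' only on success.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for the CSV artifacts.
#' @param stages subset of `c("fit", "evaluate", "geo", "warming")` to run
#'   after data generation.
#' @return A list with elements `series`, `observations`, `search`
#'   (`cu_grid_search`), `validation` (`qy_validation`), `geo` (site
#'   values, classified grid, counts), `warming` (per-site trends, counts
#'   and boundary grids per target year), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         stages = c("fit", "evaluate", "geo", "warming")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  log_ <- function(...) message("[chillqy] ", sprintf(...))
  res <- list(manifest = list(seed = config$seed, stages = stages))

  # --- data -----------------------------------------------------------
  n_seasons <- config$n_training_seasons
  start <- as.Date(sprintf("%d-08-01", config$start_year))
  n_days <- as.integer(as.Date(sprintf("%d-04-15",
                                       config$start_year + n_seasons + 1L)) -
                       start) + 1L
  log_("simulate: %d days from %s (seed %d)", n_days, format(start),
       config$seed)
  series <- gen_temperature_series(config$climate, start, n_days,
                                   site_id = "focal", seed = config$seed)
  obs_train <- list(); obs_hold <- NULL
  for (k in seq_len(n_seasons + 1L)) {
    sd_ <- season_dates(config$start_year + k - 1L)
    o <- gen_qy_observations(series, config$truth, sd_$first, sd_$last,
                             interval = config$sampling_interval,
                             n_lines = config$n_lines,
                             n_replicates = config$n_replicates,
                             seed = config$seed * 100L + k)
    if (k <= n_seasons) obs_train[[k]] <- o else obs_hold <- o
  }
  observations <- do.call(rbind, obs_train)
  class(observations) <- class(obs_train[[1L]])
  log_("simulate: %d training observations, %d held-out",
       nrow(observations), nrow(obs_hold))
  res$series <- series; res$observations <- observations
  res$held_out <- obs_hold

  # --- filter / impute ------------------------------------------------
  flt <- filter_by_missing_rate(series, config$truth$cu_config$temp_stat,
                                config$max_missing_rate)
  log_("filter: missing rate %.3f (max %.3f) -> %s", flt$rate,
       config$max_missing_rate, if (flt$accepted) "accepted" else "rejected")
  if (!flt$accepted)
    stop_("pipeline aborted at stage 'filter': focal series missing rate %.3f exceeds %.3f",
          flt$rate, config$max_missing_rate)
  series <- impute_missing(series)

  # --- grid search ----------------------------------------------------
  if ("fit" %in% stages) {
    log_("fit: AIC search over %d configurations", nrow(enumerate_grid(config$spec)))
    res$search <- cu_grid_search(series, observations, config$spec,
                                 aggregation = config$aggregation,
                                 eps = config$eps)
    b <- res$search$best$cu_config
    log_("fit: selected %s/%s Th=%g L=%d (AIC %.2f)", b$cu_type, b$temp_stat,
         b$threshold, b$window, res$search$best$aic)
  }

  # --- held-out validation -------------------------------------------
  if ("evaluate" %in% stages && !is.null(res$search)) {
    res$validation <- validate_season(res$search$best, series, obs_hold,
                                      season = sprintf("%d-%d",
                                                       config$start_year + n_seasons,
                                                       config$start_year + n_seasons + 1L),
                                      interval_kind = config$interval_kind,
                                      aggregation = config$aggregation,
                                      eps = config$eps)
    log_("evaluate: %d/%d within the 95%% %s interval, r = %.3f",
         res$validation$n_within, res$validation$n_points,
         res$validation$interval_kind, res$validation$pearson_r)
  }

  # --- geographic suitability ----------------------------------------
  if ("geo" %in% stages) {
    fit <- if (!is.null(res$search)) res$search$best else NULL
    cfg_cu <- if (!is.null(fit)) fit$cu_config else config$truth$cu_config
    net <- gen_site_network(config$n_sites,
                            lat_range = config$geo_bbox[1:2],
                            lon_range = config$geo_bbox[3:4],
                            climate = config$climate,
                            seed = config$seed + 1000L)
    sites <- gen_network_series(net, start, n_days,
                                seed = config$seed + 2000L)
    pm <- site_period_max_cu(sites, cfg_cu, max_rate = config$max_missing_rate)
    log_("geo: %d sites admitted, %d excluded", nrow(pm$values),
         nrow(pm$excluded))
    grid <- svm_interpolate(data.frame(lat = pm$values$lat,
                                       lon = pm$values$lon,
                                       value = pm$values$cu_max),
                            grid_resolution = config$geo_resolution,
                            mode = "regression",
                            bbox = config$geo_bbox,
                            seed = config$seed + 3000L)
    grid <- classify_suitability(grid, config$cu_threshold, "cu_max")
    log_("geo: %d of %d grid cells suitable (CU <= %g)",
         attr(grid, "n_suitable"), nrow(grid), config$cu_threshold)
    res$geo <- list(site_values = pm$values, excluded = pm$excluded,
                    grid = grid, n_suitable = attr(grid, "n_suitable"))
  }

  # --- warming trend --------------------------------------------------
  if ("warming" %in% stages) {
    fit <- if (!is.null(res$search)) res$search$best
           else fit_cu_model(series, observations, config$truth$cu_config,
                             aggregation = config$aggregation,
                             eps = config$eps)
    warm_climate <- config$climate
    warm_climate$warming_rate <- config$warming_rate
    w_start <- as.Date(sprintf("%d-08-01",
                               config$target_years[1L] - config$n_warming_seasons %/% 2L))
    w_days <- as.integer(config$n_warming_seasons * 365.25 + 300)
    net <- gen_site_network(config$n_sites,
                            lat_range = config$geo_bbox[1:2],
                            lon_range = config$geo_bbox[3:4],
                            climate = warm_climate,
                            seed = config$seed + 1000L)
    sites <- gen_network_series(net, w_start, w_days,
                                seed = config$seed + 4000L)
    trends <- list(); preds <- list()
    for (s in sites) {
      ann <- seasonal_min_qy(impute_missing(s$series), fit)
      if (nrow(ann) < 3L) next
      tr <- fit_trend(ann, site_id = s$site_id)
      trends[[length(trends) + 1L]] <-
        data.frame(site_id = s$site_id, lat = s$lat, lon = s$lon,
                   slope = tr$slope, intercept = tr$intercept,
                   n_seasons = tr$n_seasons)
      preds[[length(preds) + 1L]] <-
        data.frame(site_id = s$site_id, lat = s$lat, lon = s$lon,
                   t(vapply(config$target_years,
                            function(yy) extrapolate(tr, yy), numeric(1))))
    }
    trend_tab <- do.call(rbind, trends)
    pred_tab <- do.call(rbind, preds)
    names(pred_tab)[-(1:3)] <- paste0("qy_", config$target_years)
    counts <- vapply(config$target_years, function(yy)
      count_suitable_sites(pred_tab[[paste0("qy_", yy)]],
                           config$qy_threshold), numeric(1))
    names(counts) <- config$target_years
    log_("warming: median slope %+.5f QY/yr; suitable sites: %s",
         median(trend_tab$slope),
         paste(sprintf("%s in %s", counts, names(counts)), collapse = ", "))
    boundaries <- lapply(config$target_years, function(yy) {
      suit <- pred_tab[[paste0("qy_", yy)]] > config$qy_threshold
      if (length(unique(suit)) < 2L) return(NULL)
      map_decision_boundary(data.frame(lat = pred_tab$lat,
                                       lon = pred_tab$lon, value = suit),
                            grid_resolution = max(config$geo_resolution / 4, 0.1),
                            bbox = config$geo_bbox,
                            seed = config$seed + 5000L)
    })
    names(boundaries) <- config$target_years
    res$warming <- list(trends = trend_tab, predictions = pred_tab,
                        counts = counts, boundaries = boundaries)
  }

  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir, log_)
  res
}

# Atomic CSV export of the pipeline artifacts: everything is written into a
# temporary directory first and renamed into place only when complete.
write_pipeline_outputs <- function(res, config, out_dir, log_) {
  tmp <- paste0(out_dir, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  write_climate_csv(res$series, file.path(tmp, "climate.csv"))
  write_qy_csv(res$observations, file.path(tmp, "qy_train.csv"))
  write_qy_csv(res$held_out, file.path(tmp, "qy_heldout.csv"))
  if (!is.null(res$search))
    write.csv(res$search$fits, file.path(tmp, "aic_table.csv"),
              row.names = FALSE)
  if (!is.null(res$validation))
    write.csv(res$validation$table, file.path(tmp, "validation.csv"),
              row.names = FALSE)
  if (!is.null(res$geo)) {
    write.csv(res$geo$site_values, file.path(tmp, "geo_sites.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(res$geo$grid), file.path(tmp, "geo_grid.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$warming)) {
    write.csv(res$warming$trends, file.path(tmp, "warming_trends.csv"),
              row.names = FALSE)
    write.csv(res$warming$predictions,
              file.path(tmp, "warming_predictions.csv"), row.names = FALSE)
  }
  manifest <- list(seed = config$seed,
                   stages = res$manifest$stages,
                   qy_threshold = config$qy_threshold,
                   cu_threshold = config$cu_threshold,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  yaml::write_yaml(manifest, file.path(tmp, "run_manifest.yaml"))
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  file.rename(tmp, out_dir)
  log_("outputs written to %s", out_dir)
  invisible(out_dir)
}
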
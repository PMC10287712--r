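#' Threshold-by-window search grid specification
#'
#' The exhaustive model search fits one logit-linear QY model per chilling
#' unit on a grid of thresholds and windows. The defaults reproduce the
#' standard search: per temperature statistic a 15 degC threshold range in
#' 0.25 degC increments (61 values) crossed with windows of 1 to 70 days in
#' 1-day increments (70 values), i.e. 61 x 70 = 4,270 configurations per
#' (CU type, statistic) pair and 25,620 over all six pairs. The per-statistic
#' threshold ranges bracket the known optima for each statistic: daily
#' maximum \eqn{[0, 15]}, daily average \eqn{[-2.5, 12.5]}, daily minimum
#' \eqn{[-7, 8]} degC.
#'
#' @param threshold_ranges named list of `c(low, high)` threshold ranges in
#'   degC, one per temperature statistic.
#' @param threshold_step threshold increment in degC.
#' @param window_range `c(min_L, max_L)` window range in days.
#' @param window_step window increment in days.
#' @param cu_types CU types to search.
#' @param temp_stats temperature statistics to search.
#' @return An object of class `grid_spec`.
#' @seealso [enumerate_grid()], [cu_grid_search()]
#' @export
grid_spec <- function(threshold_ranges = list(max = c(0, 15),
                                              min = c(-7, 8),
                                              avg = c(-2.5, 12.5)),
                      threshold_step = 0.25,
                      window_range = c(1, 70), window_step = 1,
                      cu_types = c("day_count", "temperature_sum"),
                      temp_stats = c("max", "min", "avg")) {
  cu_types <- match.arg(cu_types, c("day_count", "temperature_sum"),
                        several.ok = TRUE)
  temp_stats <- match.arg(temp_stats, c("max", "min", "avg"),
                          several.ok = TRUE)
  if (!all(temp_stats %in% names(threshold_ranges)))
    stop_("`threshold_ranges` must name every statistic in `temp_stats`")
  check_number(threshold_step, "threshold_step", lower = 1e-9)
  check_number(window_step, "window_step", lower = 1)
  for (stat in temp_stats) {
    r <- threshold_ranges[[stat]]
    if (length(r) != 2L || r[2L] < r[1L])
      stop_("threshold range for '%s' must be c(low, high)", stat)
    k <- (r[2L] - r[1L]) / threshold_step
    if (abs(k - round(k)) > 1e-8)
      stop_("threshold step %g does not divide the range [%g, %g] for '%s'",
            threshold_step, r[1L], r[2L], stat)
  }
  if (window_range[2L] < window_range[1L] || window_range[1L] < 1)
    stop_("`window_range` must be c(min_L, max_L) with min_L >= 1")
  k <- (window_range[2L] - window_range[1L]) / window_step
  if (abs(k - round(k)) > 1e-8)
    stop_("window step %g does not divide the range [%d, %d]",
          window_step, window_range[1L], window_range[2L])
  structure(list(threshold_ranges = threshold_ranges,
                 threshold_step = threshold_step,
                 window_range = as.integer(window_range),
                 window_step = as.integer(window_step),
                 cu_types = cu_types, temp_stats = temp_stats),
            class = "grid_spec")
}

grid_thresholds <- function(spec, temp_stat) {
  r <- spec$threshold_ranges[[temp_stat]]
  seq(r[1L], r[2L], by = spec$threshold_step)
}

grid_windows <- function(spec) {
  seq(spec$window_range[1L], spec$window_range[2L], by = spec$window_step)
}

#' Enumerate every chilling-unit configuration in a grid
#'
#' Deterministic ordering: CU type, then temperature statistic (in the order
#' given in the spec), then threshold ascending, then window ascending. The
#' default [grid_spec()] yields 25,620 rows.
#'
#' @param spec a [grid_spec()].
#' @return A data frame with columns `cu_type`, `temp_stat`, `threshold`,
#'   `window`, one row per configuration.
#' @examples
#' nrow(enumerate_grid(grid_spec()))  # 25620
#' @export
enumerate_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  Ls <- grid_windows(spec)
  blocks <- list()
  for (cu_type in spec$cu_types)
    for (stat in spec$temp_stats) {
      ths <- grid_thresholds(spec, stat)
      blocks[[length(blocks) + 1L]] <- data.frame(
        cu_type = cu_type, temp_stat = stat,
        threshold = rep(ths, each = length(Ls)),
        window = rep(Ls, times = length(ths)))
    }
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}
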
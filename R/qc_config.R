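#' Parameters of one moving window
#'
#' Each of the five QC passes is described by a window width (a count of
#' records), the centre statistic it computes, and three nonnegative
#' constants controlling the dynamic bounds: at every evaluated point the
#' upper bound is `centre + topadd + std_factor * std` and the lower bound
#' `centre - bottomsub - std_factor * std`, where `centre` and `std` are the
#' masked rolling centre statistic and sample standard deviation of the
#' window. `topadd` and `bottomsub` are in sensor units; `std_factor` is
#' dimensionless.
#'
#' An even `width` is widened by one record so the centred window has the
#' same number of points before and after the evaluated point.
#'
#' @param window_id Integer 1..5; windows are applied in id order.
#' @param width Positive integer count of records (>= 3; made odd).
#' @param statistic One of `"mean"`, `"median"`, `"triangular_mean"`.
#' @param topadd,bottomsub Nonnegative constants (sensor units) widening the
#'   upper/lower bound additively.
#' @param std_factor Nonnegative multiplier on the rolling standard
#'   deviation.
#' @param use_uncertainty Should the sensor-uncertainty margin gate flagging
#'   in this window?
#'
#' @return An object of class `window_params`.
#' @seealso [qc_config()], [default_qc_windows()]
#' @export
window_params <- function(window_id, width,
                          statistic = c("mean", "median", "triangular_mean"),
                          topadd = 0.5, bottomsub = 0.5, std_factor = 3,
                          use_uncertainty = FALSE) {
  statistic <- match.arg(statistic)
  window_id <- as.integer(window_id)
  if (is.na(window_id) || window_id < 1L || window_id > 5L)
    stop("window_id must be an integer in 1..5", call. = FALSE)
  width <- as.integer(width)
  if (is.na(width) || width < 3L)
    stop("width must be an integer >= 3", call. = FALSE)
  if (width %% 2L == 0L) width <- width + 1L  # centre needs equal sides
  for (nm in c("topadd", "bottomsub", "std_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(nm, " must be a single nonnegative number", call. = FALSE)
  }
  structure(
    list(window_id = window_id, width = width, statistic = statistic,
         topadd = as.numeric(topadd), bottomsub = as.numeric(bottomsub),
         std_factor = as.numeric(std_factor),
         use_uncertainty = isTRUE(use_uncertainty)),
    class = "window_params"
  )
}

#' Sensor uncertainty specification
#'
#' Manufacturer accuracy statements of the form "X% of the measured value or
#' +/- Y units" (e.g. 3% or 0.5 mg N/L for an optical nitrate sensor).
#' The margin applied at a value `x` is `max(pct * |x| / 100, constant)`,
#' i.e. whichever part of the statement is larger at that value. Both zero
#' disables the gate.
#'
#' @param pct Nonnegative percentage of the measured value.
#' @param constant Nonnegative constant margin in sensor units.
#' @return An object of class `uncertainty_spec`.
#' @export
#' @examples
#' uncertainty_margin(10, uncertainty_spec(pct = 3, constant = 0.5))   # 0.5
#' uncertainty_margin(100, uncertainty_spec(pct = 3, constant = 0.5))  # 3
uncertainty_spec <- function(pct = 0, constant = 0) {
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct) || pct < 0)
    stop("pct must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(constant) || length(constant) != 1L || is.na(constant) ||
      constant < 0)
    stop("constant must be a single nonnegative number", call. = FALSE)
  structure(list(pct = as.numeric(pct), constant = as.numeric(constant)),
            class = "uncertainty_spec")
}

#' @rdname uncertainty_spec
#' @param value Measured value(s), sensor units.
#' @param spec An [uncertainty_spec()].
#' @return `uncertainty_margin()`: nonnegative margin(s), sensor units.
#' @export
uncertainty_margin <- function(value, spec) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  pmax(spec$pct * abs(value) / 100, spec$constant)
}

#' Default five-window set
#'
#' The published widths and statistics: two wide mean windows of 960 records
#' that stabilise the series against clusters of anomalies, a 48-record
#' median window for robustness, and two 5-record windows (plain mean, then
#' triangular-weighted mean) that pick out single local and global
#' anomalies. The uncertainty gate applies to the first two windows.
#'
#' @param topadd,bottomsub,std_factor Either length-1 (recycled) or length-5
#'   vectors of per-window bound constants.
#' @return List of five [window_params()].
#' @export
default_qc_windows <- function(topadd = 0.5, bottomsub = 0.5, std_factor = 3) {
  widths <- c(960L, 960L, 48L, 5L, 5L)
  stats <- c("mean", "mean", "median", "mean", "triangular_mean")
  topadd <- rep_len(topadd, 5L)
  bottomsub <- rep_len(bottomsub, 5L)
  std_factor <- rep_len(std_factor, 5L)
  lapply(1:5, function(i)
    window_params(i, widths[i], stats[i], topadd[i], bottomsub[i],
                  std_factor[i], use_uncertainty = i <= 2L))
}

#' Full QC parameterization
#'
#' Bundles the ordered five-window set with the warm-up/cool-down lengths,
#' the sensor uncertainty, and numerical guards. Warm-up and cool-down
#' records contribute to the window statistics but are never flagged; their
#' default of 480 records ensures every evaluated point has adequate window
#' support and can be adjusted for short deployments.
#'
#' @param windows List of exactly five [window_params()], ids 1..5.
#' @param warmup_records,cooldown_records Positive integer counts of
#'   protected leading/trailing records (default 480 each).
#' @param uncertainty An [uncertainty_spec()].
#' @param min_valid_in_window Minimum number of valid (unflagged,
#'   non-missing) points a window must contain for its statistics to be
#'   used; positions below this are skipped, not flagged. Default 3.
#' @param include_center Should the evaluated point itself contribute to its
#'   own window's statistics? Default `TRUE` (conventional centred-rolling
#'   semantics).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(windows = default_qc_windows(),
                      warmup_records = 480L, cooldown_records = 480L,
                      uncertainty = uncertainty_spec(),
                      min_valid_in_window = 3L, include_center = TRUE) {
  if (!is.list(windows) || length(windows) != 5L)
    stop("exactly 5 windows are required", call. = FALSE)
  if (!all(vapply(windows, inherits, logical(1), "window_params")))
    stop("windows must be a list of window_params objects", call. = FALSE)
  ids <- vapply(windows, `[[`, integer(1), "window_id")
  if (!identical(sort(ids), 1:5))
    stop("window ids must be exactly 1..5", call. = FALSE)
  windows <- windows[order(ids)]
  stopifnot(inherits(uncertainty, "uncertainty_spec"))
  warmup_records <- as.integer(warmup_records)
  cooldown_records <- as.integer(cooldown_records)
  min_valid_in_window <- as.integer(min_valid_in_window)
  if (is.na(warmup_records) || warmup_records < 1L ||
      is.na(cooldown_records) || cooldown_records < 1L)
    stop("warmup_records and cooldown_records must be positive integers",
         call. = FALSE)
  if (is.na(min_valid_in_window) || min_valid_in_window < 1L)
    stop("min_valid_in_window must be a positive integer", call. = FALSE)
  structure(
    list(windows = windows, warmup_records = warmup_records,
         cooldown_records = cooldown_records, uncertainty = uncertainty,
         min_valid_in_window = min_valid_in_window,
         include_center = isTRUE(include_center)),
    class = "qc_config"
  )
}

#' Validate a configuration against a series length
#'
#' Returns (not raises) warnings about satisfiable-but-questionable
#' configurations, in particular a series too short for the configured
#' warm-up and cool-down periods, in which case a run would flag nothing.
#' Structural violations (wrong window count, negative constants) raise at
#' construction time instead.
#'
#' @param cfg A [qc_config()].
#' @param n Series length (record count).
#' @return Character vector of warning messages (empty when none).
#' @export
validate_config <- function(cfg, n) {
  stopifnot(inherits(cfg, "qc_config"))
  n <- as.integer(n)
  out <- character(0)
  if (n <= cfg$warmup_records + cfg$cooldown_records)
    out <- c(out, sprintf(
      paste0("insufficient data points for the warm-up/cool-down periods ",
             "(n = %d <= %d + %d); no points will be evaluated"),
      n, cfg$warmup_records, cfg$cooldown_records))
  wmax <- max(vapply(cfg$windows, `[[`, integer(1), "width"))
  if (wmax > n)
    out <- c(out, sprintf(
      "widest window (%d records) exceeds the series length (%d)", wmax, n))
  out
}

#' @export
print.qc_config <- function(x, ...) {
  cat("<qc_config>\n")
  for (w in x$windows)
    cat(sprintf(
      "  window %d: width %d, %s, topadd %.4g, bottomsub %.4g, std_factor %.4g%s\n",
      w$window_id, w$width, w$statistic, w$topadd, w$bottomsub, w$std_factor,
      if (w$use_uncertainty) ", uncertainty-gated" else ""))
  cat(sprintf("  warm-up %d, cool-down %d records; min valid/window %d\n",
              x$warmup_records, x$cooldown_records, x$min_valid_in_window))
  cat(sprintf("  uncertainty: %.4g%% or +/-%.4g units\n",
              x$uncertainty$pct, x$uncertainty$constant))
  invisible(x)
}
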
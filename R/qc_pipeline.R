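#' Dynamic window bounds
#'
#' The acceptance band at one evaluated point: upper bound
#' `center_stat + topadd + std_factor * spread`, lower bound
#' `center_stat - bottomsub - std_factor * spread`. For the median window
#' the centre statistic is the rolling median instead of the mean.
#' Vectorized over `center_stat`/`spread`.
#'
#' @param center_stat Rolling centre statistic (mean, median, or
#'   triangular-weighted mean), sensor units.
#' @param spread Rolling standard deviation, nonnegative.
#' @param params A [window_params()].
#' @return A list with numeric components `topwin` and `botwin`.
#' @export
#' @examples
#' p <- window_params(1, 5, "mean", topadd = 0.5, bottomsub = 0.5,
#'                    std_factor = 3)
#' window_bounds(10, 1, p)  # topwin 13.5, botwin 6.5
window_bounds <- function(center_stat, spread, params) {
  stopifnot(inherits(params, "window_params"))
  list(topwin = center_stat + params$topadd + params$std_factor * spread,
       botwin = center_stat - params$bottomsub - params$std_factor * spread)
}

#' Run one flagging pass over a series
#'
#' Scans the series left to right. At every `PENDING` position with defined
#' window statistics (over the currently valid, i.e. unflagged and
#' non-missing, points) the dynamic bounds are computed via
#' [window_bounds()], and the point is flagged iff
#' `value - m > topwin` or `value + m < botwin`, where `m` is the
#' uncertainty margin when `params$use_uncertainty` and zero otherwise
#' (strict inequalities: a value exactly on the boundary survives). A point
#' flagged during the pass is excluded from all later window evaluations,
#' including later positions of the same pass.
#'
#' This is the mid-level engine behind [run_qc()]; most users call that
#' instead.
#'
#' @param values Numeric vector of measurements.
#' @param status Integer status codes (as in a [sensor_series()]).
#' @param flag_window Integer vector recording which window flagged each
#'   point (`NA` when unflagged).
#' @param params A [window_params()] for this pass.
#' @param uncertainty An [uncertainty_spec()].
#' @param min_valid,include_center See [qc_config()].
#' @return List with updated `status`, `flag_window`, and the count
#'   `n_flagged` of points newly flagged in this pass.
#' @export
apply_window_pass <- function(values, status, flag_window, params,
                              uncertainty = uncertainty_spec(),
                              min_valid = 3L, include_center = TRUE) {
  stopifnot(inherits(params, "window_params"),
            inherits(uncertainty, "uncertainty_spec"))
  n <- length(values)
  if (length(status) != n || length(flag_window) != n)
    stop("values, status and flag_window must have the same length",
         call. = FALSE)
  qc_pass_cpp(as.numeric(values), as.integer(status),
              as.integer(flag_window), params$width,
              .stat_code(params$statistic), params$topadd, params$bottomsub,
              params$std_factor, params$use_uncertainty, uncertainty$pct,
              uncertainty$constant, as.integer(min_valid),
              isTRUE(include_center), params$window_id)
}

#' Run the five-pass moving-window QC
#'
#' Marks the first `warmup_records` and last `cooldown_records` records as
#' protected (they contribute to window statistics but are never flagged),
#' marks missing values, then applies the five window passes in id order.
#' Wide windows flag long runs of anomalous readings first so that the
#' narrow windows that follow see stabilised statistics; each pass works
#' only on the points that all earlier evaluations left unflagged. Points
#' still pending afterwards are approved.
#'
#' @param series A [sensor_series()].
#' @param config A [qc_config()]. Configuration warnings from
#'   [validate_config()] (e.g. a series shorter than warm-up plus
#'   cool-down) are emitted as R warnings; the run then proceeds with an
#'   empty flagging region.
#' @return An object of class `qc_result`: the series with final statuses,
#'   per-point `flag_window` provenance, per-window flag counts, status
#'   totals, and `pct_flagged` = 100 * FLAGGED / (FLAGGED + APPROVED).
#' @export
#' @examples
#' ts <- as.POSIXct("2022-01-01", tz = "UTC") + 60 * (0:2000)
#' x <- rep(8, 2001); x[1000] <- 40
#' cfg <- qc_config(warmup_records = 100, cooldown_records = 100)
#' res <- run_qc(sensor_series(ts, x, parameter = "oxygen"), cfg)
#' summary(res)
run_qc <- function(series, config = qc_config()) {
  stopifnot(inherits(series, "sensor_series"), inherits(config, "qc_config"))
  n <- length(series)
  for (msg in validate_config(config, n)) warning(msg, call. = FALSE)

  status <- series$status
  idx <- seq_len(n)
  warm <- idx <= config$warmup_records
  cool <- idx > n - config$cooldown_records
  status[warm & status == .ST$PENDING] <- .ST$WARMUP
  status[!warm & cool & status == .ST$PENDING] <- .ST$COOLDOWN
  flag_window <- rep(NA_integer_, n)

  for (wp in config$windows) {
    pass <- qc_pass_cpp(series$values, status, flag_window, wp$width,
                        .stat_code(wp$statistic), wp$topadd, wp$bottomsub,
                        wp$std_factor, wp$use_uncertainty,
                        config$uncertainty$pct, config$uncertainty$constant,
                        config$min_valid_in_window, config$include_center,
                        wp$window_id)
    status <- pass$status
    flag_window <- pass$flag_window
  }
  status[status == .ST$PENDING] <- .ST$APPROVED

  out <- series
  out$status <- status
  totals <- vapply(.ST, function(code) sum(status == code), integer(1))
  per_window <- vapply(1:5, function(w) sum(flag_window == w, na.rm = TRUE),
                       integer(1))
  names(per_window) <- paste0("window_", 1:5)
  evaluable <- totals[["FLAGGED"]] + totals[["APPROVED"]]
  pct <- if (evaluable > 0) 100 * totals[["FLAGGED"]] / evaluable else 0
  structure(
    list(series = out, flag_window = flag_window,
         per_window_counts = per_window, totals = totals,
         pct_flagged = pct, config = config),
    class = "qc_result"
  )
}

#' Flag indices of a QC result
#'
#' @param result A `qc_result`.
#' @return Integer positions flagged as anomalies.
#' @export
flagged_indices <- function(result) {
  stopifnot(inherits(result, "qc_result"))
  which(result$series$status == .ST$FLAGGED)
}

#' Per-point flag table
#'
#' The tabular output: timestamp, raw value, final status, and, for flagged
#' points, the window that flagged them.
#'
#' @param result A `qc_result`.
#' @return A `data.frame` with columns `timestamp`, `value`, `status`,
#'   `flag_window`.
#' @export
qc_flag_table <- function(result) {
  stopifnot(inherits(result, "qc_result"))
  s <- result$series
  data.frame(timestamp = s$timestamps, value = s$values,
             status = .status_factor(s$status),
             flag_window = result$flag_window)
}

#' Summarize a QC result
#'
#' Per-window flagged counts, status totals, and the flagged percentage
#' 100 * FLAGGED / (FLAGGED + APPROVED), rounded to `digits` decimals
#' (default one, the precision used for reported anomaly rates). The
#' denominator excludes warm-up, cool-down and missing records by default;
#' set `denominator = "all"` to divide by the full record count instead.
#'
#' @param object A `qc_result`.
#' @param digits Decimals for the reported percentage.
#' @param denominator `"evaluable"` (default) or `"all"`.
#' @param ... Unused.
#' @return A list of class `qc_summary` with components `per_window`
#'   (data.frame of window id and flagged count), `totals` (named counts by
#'   status), `n`, and `pct_flagged`.
#' @export
summary.qc_result <- function(object, digits = 1,
                              denominator = c("evaluable", "all"), ...) {
  denominator <- match.arg(denominator)
  n <- length(object$series)
  den <- switch(denominator,
                evaluable = object$totals[["FLAGGED"]] +
                  object$totals[["APPROVED"]],
                all = n)
  pct <- if (den > 0) round(100 * object$totals[["FLAGGED"]] / den,
                            digits) else 0
  structure(
    list(per_window = data.frame(window_id = 1:5,
                                 flagged = unname(object$per_window_counts)),
         totals = object$totals, n = n, pct_flagged = pct,
         site = object$series$site, parameter = object$series$parameter),
    class = "qc_summary"
  )
}

#' @export
print.qc_summary <- function(x, ...) {
  hdr <- paste0(
    if (nzchar(x$parameter)) paste0(x$parameter, " ") else "",
    if (nzchar(x$site)) paste0("@ ", x$site, " ") else "")
  cat(sprintf("QC summary %s(%d records)\n", hdr, x$n))
  for (i in 1:5)
    cat(sprintf("  window %d flagged: %d\n", i, x$per_window$flagged[i]))
  for (nm in names(x$totals))
    cat(sprintf("  %-9s %d\n", nm, x$totals[[nm]]))
  cat(sprintf("  flagged: %s%%\n", format(x$pct_flagged)))
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  cat(format(x$series), "\n")
  print(summary(x))
  invisible(x)
}
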
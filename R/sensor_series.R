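#' Construct a sensor time series
#'
#' A `sensor_series` holds one parameter measured by one sensor: strictly
#' increasing timestamps, the raw measurement values in sensor units, and a
#' per-point status (see [qc_status_levels()]). Missing values (`NA`/`NaN`)
#' are given status `MISSING` at construction and are never approved or
#' flagged; all other points start as `PENDING`.
#'
#' @param timestamps `POSIXct` vector (or something coercible via
#'   [as.POSIXct()]), strictly increasing, no duplicates.
#' @param values Numeric vector of measurements, same length as
#'   `timestamps`; may contain `NA`.
#' @param site Free-text site label.
#' @param parameter Free-text parameter label (e.g. `"nitrate-N"`,
#'   `"turbidity"`, `"dissolved oxygen"`, `"pH"`).
#' @param tz Time zone used when `timestamps` must be coerced; default
#'   `"UTC"` (loggers are treated as timezone-naive).
#'
#' @return An object of class `sensor_series`.
#' @export
#' @examples
#' ts <- as.POSIXct("2021-05-05 00:00", tz = "UTC") + 60 * (0:4)
#' s <- sensor_series(ts, c(4.2, 4.3, NA, 4.1, 4.2), parameter = "nitrate-N")
#' s
sensor_series <- function(timestamps, values, site = "", parameter = "",
                          tz = "UTC") {
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = tz)
  values <- as.numeric(values)
  n <- length(timestamps)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (length(values) != n)
    stop("timestamps and values must have the same length", call. = FALSE)
  if (anyNA(timestamps)) stop("unparseable timestamp", call. = FALSE)
  dt <- diff(as.numeric(timestamps))
  if (any(dt == 0)) stop("duplicate timestamp", call. = FALSE)
  if (any(dt < 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  values[!is.finite(values)] <- NA_real_
  status <- ifelse(is.na(values), .ST$MISSING, .ST$PENDING)
  structure(
    list(site = site, parameter = parameter, timestamps = timestamps,
         values = values, status = as.integer(status)),
    class = "sensor_series"
  )
}

#' @export
length.sensor_series <- function(x) length(x$values)

#' @export
format.sensor_series <- function(x, ...) {
  sprintf("<sensor_series: %s%s, %d points, %d missing, %s .. %s>",
          if (nzchar(x$parameter)) x$parameter else "unnamed parameter",
          if (nzchar(x$site)) paste0(" @ ", x$site) else "",
          length(x), sum(x$status == .ST$MISSING),
          format(x$timestamps[1]), format(x$timestamps[length(x)]))
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.data.frame.sensor_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, value = x$values,
             status = .status_factor(x$status))
}
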
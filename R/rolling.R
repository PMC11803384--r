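.stat_code <- function(statistic) {
  match(statistic, c("mean", "median", "triangular_mean")) - 1L
}

#' Masked centred rolling statistics
#'
#' Computes, for every position `i`, the centre statistic and sample
#' standard deviation (`n - 1` denominator) of the valid points inside the
#' centred window `[i - h, i + h]`, `h = (width - 1) / 2`. Points with
#' `valid = FALSE` or a non-finite value are excluded from every window they
#' fall in; edge windows truncated by the series boundary use the points
#' that remain. Positions with fewer than `min_valid` contributing points
#' are returned as `NA` (undefined).
#'
#' @param values Numeric vector.
#' @param valid Logical vector of the same length; `NULL` means all valid.
#' @param width Odd integer window width >= 3 (an even width is an error
#'   here; widths are made odd at configuration time).
#' @param statistic `"mean"`, `"median"`, or `"triangular_mean"`.
#' @param min_valid Minimum contributing points for a defined position.
#' @param include_center Should position `i` contribute to its own window?
#'
#' @return A `data.frame` of class `rolling_stats` with columns
#'   `center_stat`, `spread`, `n_valid`.
#' @export
#' @examples
#' masked_rolling(c(1, 2, 100, 3, 4), c(TRUE, TRUE, FALSE, TRUE, TRUE),
#'                width = 5, statistic = "mean")
masked_rolling <- function(values, valid = NULL, width,
                           statistic = c("mean", "median", "triangular_mean"),
                           min_valid = 3L, include_center = TRUE) {
  statistic <- match.arg(statistic)
  values <- as.numeric(values)
  n <- length(values)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n)
    stop("values and valid must have the same length", call. = FALSE)
  width <- as.integer(width)
  if (is.na(width) || width < 3L) stop("width must be >= 3", call. = FALSE)
  if (width %% 2L == 0L)
    stop("width must be odd (centred window)", call. = FALSE)
  res <- rolling_stats_cpp(values, as.logical(valid), width,
                           .stat_code(statistic), as.integer(min_valid),
                           isTRUE(include_center))
  out <- data.frame(center_stat = res$center_stat, spread = res$spread,
                    n_valid = res$n_valid)
  class(out) <- c("rolling_stats", "data.frame")
  out
}

#' @rdname masked_rolling
#' @details `triangular_rolling()` is `masked_rolling()` with the
#'   triangular-weighted mean: symmetric weights `w_k = h + 1 - |k|` for
#'   offsets `k` in `[-h, h]` give the middle of the window more weight than
#'   its ends. The weighted spread uses the frequency-weight convention
#'   `sqrt(sum(w * (x - m)^2) / sum(w))`.
#' @export
triangular_rolling <- function(values, valid = NULL, width, min_valid = 3L,
                               include_center = TRUE) {
  masked_rolling(values, valid, width, statistic = "triangular_mean",
                 min_valid = min_valid, include_center = include_center)
}

#' Triangular window weights
#'
#' @param width Odd window width.
#' @return Integer weights `h + 1 - |k|`, e.g. `c(1, 2, 3, 2, 1)` for
#'   width 5.
#' @export
triangular_weights <- function(width) {
  width <- as.integer(width)
  if (is.na(width) || width < 3L || width %% 2L == 0L)
    stop("width must be an odd integer >= 3", call. = FALSE)
  h <- (width - 1L) %/% 2L
  h + 1L - abs(seq.int(-h, h))
}
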
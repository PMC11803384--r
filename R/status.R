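# Per-point status codes. Integer codes are shared with the C++ engine:
# PENDING 0, APPROVED 1, FLAGGED 2, WARMUP 3, COOLDOWN 4, MISSING 5.

.STATUS_LEVELS <- c("PENDING", "APPROVED", "FLAGGED", "WARMUP", "COOLDOWN",
                    "MISSING")

.ST <- list(PENDING = 0L, APPROVED = 1L, FLAGGED = 2L, WARMUP = 3L,
            COOLDOWN = 4L, MISSING = 5L)

#' Status levels used for sensor series points
#'
#' Every point of a [sensor_series()] carries exactly one status:
#' `PENDING` (not yet evaluated), `APPROVED` (evaluated, kept), `FLAGGED`
#' (marked as an anomaly by one of the five windows), `WARMUP` / `COOLDOWN`
#' (leading/trailing records protected from flagging but contributing to the
#' window statistics), and `MISSING` (no usable value).
#'
#' @return Character vector of the six status levels, in code order.
#' @export
#' @examples
#' qc_status_levels()
qc_status_levels <- function() .STATUS_LEVELS

# integer codes -> factor
.status_factor <- function(code) {
  factor(.STATUS_LEVELS[code + 1L], levels = .STATUS_LEVELS)
}

# factor/character -> integer codes
.status_code <- function(status) {
  m <- match(as.character(status), .STATUS_LEVELS)
  if (anyNA(m)) stop("unknown status level", call. = FALSE)
  m - 1L
}
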
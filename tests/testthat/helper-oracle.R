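# Independent brute-force reference implementation: at every position it
# literally re-collects the window's valid members and recomputes the
# statistics with base R. Shares no code with the package engine.

oracle_members <- function(x, ok, i, h, include_center = TRUE) {
  lo <- max(1, i - h)
  hi <- min(length(x), i + h)
  j <- lo:hi
  if (!include_center) j <- j[j != i]
  j[ok[j] & is.finite(x[j])]
}

oracle_center <- function(x, j, i, h, statistic) {
  v <- x[j]
  switch(statistic,
         mean = mean(v),
         median = stats::median(v),
         triangular_mean = {
           w <- (h + 1) - abs(j - i)
           sum(w * v) / sum(w)
         })
}

oracle_spread <- function(x, j, i, h, statistic) {
  v <- x[j]
  if (statistic == "triangular_mean") {
    w <- (h + 1) - abs(j - i)
    m <- sum(w * v) / sum(w)
    sqrt(sum(w * (v - m)^2) / sum(w))
  } else {
    if (length(v) < 2) return(NA_real_)
    stats::sd(v)
  }
}

oracle_rolling <- function(values, valid, width, statistic, min_valid = 3,
                           include_center = TRUE) {
  n <- length(values)
  h <- (width - 1) / 2
  center <- spread <- rep(NA_real_, n)
  nv <- integer(n)
  for (i in seq_len(n)) {
    j <- oracle_members(values, valid, i, h, include_center)
    nv[i] <- length(j)
    if (length(j) >= min_valid) {
      center[i] <- oracle_center(values, j, i, h, statistic)
      spread[i] <- oracle_spread(values, j, i, h, statistic)
    }
  }
  list(center_stat = center, spread = spread, n_valid = nv)
}

# full five-pass naive reference; `windows` is a plain list of lists with
# width, statistic, topadd, bottomsub, std_factor, use_uncertainty,
# applied in order with immediate within-pass exclusion
oracle_qc <- function(values, windows, warmup = 0, cooldown = 0,
                      unc_pct = 0, unc_con = 0, min_valid = 3,
                      include_center = TRUE) {
  n <- length(values)
  miss <- !is.finite(values)
  flagged <- rep(FALSE, n)
  flag_window <- rep(NA_integer_, n)
  protected <- rep(FALSE, n)
  if (warmup > 0) protected[seq_len(min(n, warmup))] <- TRUE
  if (cooldown > 0) protected[max(1, n - cooldown + 1):n] <- TRUE
  for (wid in seq_along(windows)) {
    w <- windows[[wid]]
    h <- (w$width - 1) / 2
    for (i in seq_len(n)) {
      if (miss[i] || flagged[i] || protected[i]) next
      ok <- !miss & !flagged
      j <- oracle_members(values, ok, i, h, include_center)
      if (length(j) < min_valid) next
      ctr <- oracle_center(values, j, i, h, w$statistic)
      spr <- oracle_spread(values, j, i, h, w$statistic)
      if (!is.finite(ctr) || !is.finite(spr)) next
      top <- ctr + w$topadd + w$std_factor * spr
      bot <- ctr - w$bottomsub - w$std_factor * spr
      m <- if (isTRUE(w$use_uncertainty))
        max(unc_pct * abs(values[i]) / 100, unc_con) else 0
      if (values[i] - m > top || values[i] + m < bot) {
        flagged[i] <- TRUE
        flag_window[i] <- wid
      }
    }
  }
  list(flagged = flagged, flag_window = flag_window)
}

oracle_windows_from_cfg <- function(cfg) {
  lapply(cfg$windows, function(w)
    list(width = w$width, statistic = w$statistic, topadd = w$topadd,
         bottomsub = w$bottomsub, std_factor = w$std_factor,
         use_uncertainty = w$use_uncertainty))
}

# run the package pipeline and the oracle on the same inputs
run_both <- function(series, cfg) {
  res <- suppressWarnings(run_qc(series, cfg))
  ora <- oracle_qc(series$values, oracle_windows_from_cfg(cfg),
                   warmup = cfg$warmup_records,
                   cooldown = cfg$cooldown_records,
                   unc_pct = cfg$uncertainty$pct,
                   unc_con = cfg$uncertainty$constant,
                   min_valid = cfg$min_valid_in_window,
                   include_center = cfg$include_center)
  list(pkg = res, oracle = ora)
}
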
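# In-code fixtures for the tests: quick series builders and randomized
# series/configuration cases for the property checks.

make_series <- function(values, start = as.POSIXct("2022-01-01 00:00:00",
                                                   tz = "UTC"),
                        by = 60, ...) {
  sensor_series(start + by * (seq_along(values) - 1), values, ...)
}

# random series with spikes and gaps plus a random five-window config
random_qc_case <- function(seed, n_range = c(80L, 600L)) {
  set.seed(seed)
  n <- sample(n_range[1]:n_range[2], 1)
  x <- 10 + stats::rnorm(n, 0, 0.5)
  nspike <- sample(0:6, 1)
  if (nspike > 0) {
    idx <- sample(n, nspike)
    x[idx] <- x[idx] + sample(c(-1, 1), nspike, TRUE) * stats::runif(nspike, 2, 8)
  }
  ngap <- sample(0:3, 1)
  for (k in seq_len(ngap)) {
    s <- sample(n, 1)
    x[s:min(n, s + sample(1:10, 1))] <- NA
  }
  widths <- sample(c(5L, 9L, 21L, 49L, 101L), 5, replace = TRUE)
  stats_k <- sample(c("mean", "median", "triangular_mean"), 5, replace = TRUE)
  windows <- lapply(1:5, function(i)
    window_params(i, widths[i], stats_k[i],
                  topadd = stats::runif(1, 0.05, 1),
                  bottomsub = stats::runif(1, 0.05, 1),
                  std_factor = stats::runif(1, 0.5, 3),
                  use_uncertainty = sample(c(TRUE, FALSE), 1)))
  cfg <- qc_config(windows,
                   warmup_records = sample(5:30, 1),
                   cooldown_records = sample(5:30, 1),
                   uncertainty = uncertainty_spec(pct = stats::runif(1, 0, 5),
                                                  constant = stats::runif(1, 0, 0.4)))
  list(series = make_series(x), cfg = cfg)
}
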
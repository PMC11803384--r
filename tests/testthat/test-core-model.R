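test_that("sensor_series enforces its invariants", {
  ts <- as.POSIXct("2021-05-05 00:00:00", tz = "UTC") + 60 * (0:2)
  s <- sensor_series(ts, c(4.2, 4.3, NA))
  expect_s3_class(s, "sensor_series")
  expect_length(s, 3)
  expect_identical(as.character(as.data.frame(s)$status),
                   c("PENDING", "PENDING", "MISSING"))

  expect_error(sensor_series(ts, 1:2), "same length")
  expect_error(sensor_series(ts[c(1, 1, 2)], c(1, 2, 3)), "duplicate")
  expect_error(sensor_series(rev(ts), c(1, 2, 3)), "increasing")
  expect_error(sensor_series(ts[0], numeric(0)), "empty")
})

test_that("window_params validates and widens even widths", {
  w <- window_params(1, 960, "mean")
  expect_identical(w$width, 961L)  # even width -> symmetric centred window
  expect_identical(window_params(3, 49, "median")$width, 49L)
  expect_error(window_params(6, 5), "1..5")
  expect_error(window_params(1, 2), ">= 3")
  expect_error(window_params(1, 5, topadd = -1), "nonnegative")
  expect_error(window_params(1, 5, std_factor = -0.1), "nonnegative")
})

test_that("default window set matches the published widths and statistics", {
  ws <- default_qc_windows()
  expect_identical(vapply(ws, `[[`, integer(1), "width"),
                   c(961L, 961L, 49L, 5L, 5L))
  expect_identical(vapply(ws, `[[`, character(1), "statistic"),
                   c("mean", "mean", "median", "mean", "triangular_mean"))
  expect_identical(vapply(ws, `[[`, logical(1), "use_uncertainty"),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("uncertainty margin applies the larger of percent and constant", {
  spec <- uncertainty_spec(pct = 3, constant = 0.5)
  expect_equal(uncertainty_margin(10, spec), 0.5)   # 3% of 10 < 0.5
  expect_equal(uncertainty_margin(100, spec), 3.0)  # 3% of 100 > 0.5
  expect_equal(uncertainty_margin(123.4, uncertainty_spec()), 0)
  # margin nonnegative for any value, including negatives
  set.seed(1)
  v <- stats::rnorm(200, 0, 50)
  expect_true(all(uncertainty_margin(v, spec) >= 0))
  expect_error(uncertainty_spec(pct = -1), "nonnegative")
})

test_that("qc_config requires exactly five ordered windows", {
  expect_error(qc_config(default_qc_windows()[1:4]), "5 windows")
  dup <- default_qc_windows()
  dup[[2]]$window_id <- 1L
  expect_error(qc_config(dup), "1..5")
  # shuffled input is reordered by id
  cfg <- qc_config(rev(default_qc_windows()))
  expect_identical(vapply(cfg$windows, `[[`, integer(1), "window_id"), 1:5)
})

test_that("validate_config warns on insufficient warm-up/cool-down room", {
  cfg <- qc_config()
  expect_length(validate_config(cfg, 100000), 0)
  w <- validate_config(cfg, 900)
  expect_true(any(grepl("insufficient", w)))
  msgs <- capture_warnings(run_qc(make_series(rep(5, 900)), cfg))
  expect_true(any(grepl("insufficient", msgs)))
})

test_that("config serialization round-trips field-for-field", {
  cfg <- qc_config(
    default_qc_windows(topadd = c(1.2, 0.5, 0.25, 0.1, 0.1),
                       bottomsub = 0.3,
                       std_factor = c(2, 2, 3, 4, 4)),
    warmup_records = 120, cooldown_records = 240,
    uncertainty = uncertainty_spec(pct = 3, constant = 0.5),
    min_valid_in_window = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_config(cfg, path)
  expect_equal(read_qc_config(path), cfg)
})
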
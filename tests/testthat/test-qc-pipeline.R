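test_that("window bounds follow the centre +/- (constant + factor * std) form", {
  p <- window_params(1, 5, "mean", topadd = 0.5, bottomsub = 0.5,
                     std_factor = 3)
  b <- window_bounds(10.0, 1.0, p)
  expect_equal(b$topwin, 13.5)
  expect_equal(b$botwin, 6.5)

  p <- window_params(1, 5, "mean", topadd = 0.2, bottomsub = 0.2,
                     std_factor = 4)
  b <- window_bounds(5.0, 0.0, p)
  expect_equal(b$topwin, 5.2)
  expect_equal(b$botwin, 4.8)

  p <- window_params(1, 5, "mean", topadd = 0, bottomsub = 0, std_factor = 2)
  b <- window_bounds(7.0, 2.0, p)
  expect_equal(b$topwin, 11.0)
  expect_equal(b$botwin, 3.0)
})

test_that("a single pass flags a spike and respects the uncertainty margin", {
  # 101 points at 10.0 with one excursion; width-5 mean window.
  # With the centre point contributing to its own window (the default),
  # the spike inflates that window's std so strongly that std_factor = 3
  # keeps it inside the bounds - the oracle confirms zero flags; the wide
  # windows of a full run are what catch such a spike (checked below).
  params <- window_params(4, 5, "mean", topadd = 0.5, bottomsub = 0.5,
                          std_factor = 3, use_uncertainty = FALSE)
  x <- rep(10, 101)
  x[51] <- 50
  st0 <- rep(0L, 101)
  pass <- apply_window_pass(x, st0, rep(NA_integer_, 101), params)
  ora <- oracle_qc(x, list(list(width = 5, statistic = "mean", topadd = 0.5,
                                bottomsub = 0.5, std_factor = 3,
                                use_uncertainty = FALSE)))
  expect_identical(which(pass$status == 2L), which(ora$flagged))
  expect_identical(which(ora$flagged), integer(0))

  # centre excluded: the window around the spike is flat, bounds tight,
  # and the spike exceeds topwin = 10 + 0.5 + 0
  pass_x <- apply_window_pass(x, st0, rep(NA_integer_, 101), params,
                              include_center = FALSE)
  ora_x <- oracle_qc(x, list(list(width = 5, statistic = "mean",
                                  topadd = 0.5, bottomsub = 0.5,
                                  std_factor = 3, use_uncertainty = FALSE)),
                     include_center = FALSE)
  expect_identical(which(pass_x$status == 2L), which(ora_x$flagged))
  expect_identical(which(pass_x$status == 2L), 51L)
  expect_identical(pass_x$flag_window[51], 4L)

  # the full five-pass run flags the spike through its wide windows
  cfg <- qc_config(warmup_records = 10, cooldown_records = 10)
  full <- suppressWarnings(run_qc(make_series(x), cfg))
  expect_identical(flagged_indices(full), 51L)

  # a 10.6 excursion survives when the +/-1.0 uncertainty margin covers it
  params_u <- window_params(1, 5, "mean", topadd = 0.5, bottomsub = 0.5,
                            std_factor = 3, use_uncertainty = TRUE)
  x2 <- rep(10, 101)
  x2[51] <- 10.6
  pass_u <- apply_window_pass(x2, st0, rep(NA_integer_, 101), params_u,
                              uncertainty = uncertainty_spec(constant = 1.0))
  ora_u <- oracle_qc(x2, list(list(width = 5, statistic = "mean",
                                   topadd = 0.5, bottomsub = 0.5,
                                   std_factor = 3, use_uncertainty = TRUE)),
                     unc_con = 1.0)
  expect_identical(which(pass_u$status == 2L), integer(0))
  expect_identical(which(ora_u$flagged), integer(0))

  # constant series with positive topadd: no flags
  pass_c <- apply_window_pass(rep(5, 101), st0, rep(NA_integer_, 101), params)
  expect_identical(sum(pass_c$status == 2L), 0L)
})

test_that("a constant series under the default config yields no flags", {
  res <- run_qc(make_series(rep(7.5, 2000)), qc_config())
  expect_identical(unname(res$totals[c("FLAGGED", "WARMUP", "COOLDOWN",
                                       "APPROVED")]),
                   c(0L, 480L, 480L, 1040L))
  expect_equal(res$pct_flagged, 0)
  expect_identical(sum(res$totals), 2000L)
})

test_that("statuses partition the series and missing points stay missing", {
  for (seed in c(3, 14, 27)) {
    case <- random_qc_case(seed)
    res <- suppressWarnings(run_qc(case$series, case$cfg))
    n <- length(case$series)
    expect_identical(sum(res$totals), n)
    # exactly one status per point, missing never approved/flagged
    na_idx <- which(is.na(case$series$values))
    expect_true(all(res$series$status[na_idx] == 5L))
    # every flagged point has exactly one window id 1..5
    fl <- which(res$series$status == 2L)
    expect_true(all(res$flag_window[fl] %in% 1:5))
    expect_true(all(is.na(res$flag_window[-fl])) || length(fl) == 0)
  }
})

test_that("warm-up and cool-down regions are never flagged", {
  set.seed(5)
  # hostile input: huge excursions inside the protected regions
  x <- 10 + stats::rnorm(1500, 0, 0.2)
  x[c(5, 50, 120, 1450, 1490)] <- c(90, -40, 70, 95, -60)
  cfg <- qc_config(default_qc_windows(topadd = 0.1, bottomsub = 0.1,
                                      std_factor = 1),
                   warmup_records = 200, cooldown_records = 200)
  res <- run_qc(make_series(x), cfg)
  prot <- c(1:200, 1301:1500)
  expect_true(all(res$series$status[prot] %in% c(3L, 4L)))
  expect_identical(sum(res$series$status[prot] == 2L), 0L)
})

test_that("the pipeline equals the brute-force oracle on randomized series", {
  for (seed in 101:115) {
    case <- random_qc_case(seed)
    both <- run_both(case$series, case$cfg)
    expect_identical(which(both$pkg$series$status == 2L),
                     which(both$oracle$flagged),
                     info = paste("seed", seed))
    expect_identical(both$pkg$flag_window, both$oracle$flag_window,
                     info = paste("seed", seed))
  }
})

test_that("identical input and config give identical output", {
  case <- random_qc_case(777)
  r1 <- suppressWarnings(run_qc(case$series, case$cfg))
  r2 <- suppressWarnings(run_qc(case$series, case$cfg))
  expect_identical(r1$series$status, r2$series$status)
  expect_identical(r1$flag_window, r2$flag_window)
  expect_identical(r1$pct_flagged, r2$pct_flagged)
})

test_that("summary reports one-decimal percentages with both denominators", {
  res <- run_qc(make_series(rep(7.5, 2000)), qc_config())
  s <- summary(res)
  expect_equal(s$pct_flagged, 0.0)
  expect_identical(s$per_window$flagged, rep(0L, 5))

  # 58 flagged of 43,200 records rounds to 0.1% over all records
  x <- rep(10, 4320)
  spikes <- seq(150, 4150, length.out = 58)
  x[round(spikes)] <- 60
  cfg <- qc_config(warmup_records = 100, cooldown_records = 100)
  res <- run_qc(make_series(x), cfg)
  expect_identical(unname(res$totals[["FLAGGED"]]), 58L)
  expect_equal(summary(res, denominator = "all")$pct_flagged,
               round(100 * 58 / 4320, 1))
})
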
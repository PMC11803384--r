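# Shipped per-profile parameterizations. As in field deployments, the bound
# constants are tuned per sensor/profile on anomaly-free calibration runs
# (see the vignette); widths and statistics are the standard five-window
# set. Constants are in sensor units of the respective profile.

.PROFILE_PARAMS <- list(
  # columns: topadd, bottomsub, std_factor per window 1..5
  constant = list(topadd = c(0.5, 0.5, 0.5, 0.5, 0.5),
                  bottomsub = c(0.5, 0.5, 0.5, 0.5, 0.5),
                  std_factor = c(3, 3, 3, 3, 3)),
  nitrate_baseflow = list(topadd = c(0.145, 0.135, 0.06, 0.12, 0.10),
                          bottomsub = c(0.145, 0.135, 0.06, 0.12, 0.10),
                          std_factor = c(0.6, 0.6, 1.8, 1.0, 0.9)),
  turbidity_storm = list(topadd = c(60, 60, 0.48, 0.96, 0.80),
                         bottomsub = c(1.16, 1.08, 0.48, 0.96, 0.80),
                         std_factor = c(0.6, 0.6, 1.8, 1.0, 0.9)),
  oxygen_diel = list(topadd = c(0.30, 0.30, 0.30, 0.60, 0.50),
                     bottomsub = c(0.30, 0.30, 0.30, 0.60, 0.50),
                     std_factor = c(2.0, 1.8, 1.6, 1.0, 0.9)),
  ph_diel = list(topadd = c(0.10, 0.10, 0.06, 0.12, 0.10),
                 bottomsub = c(0.10, 0.10, 0.06, 0.12, 0.10),
                 std_factor = c(2.6, 2.4, 1.8, 1.0, 0.9))
)

#' Shipped parameterization for a synthetic profile
#'
#' The per-profile QC configuration used by the standard fixture suite:
#' standard widths and statistics (960/960/48/5/5; mean, mean, median,
#' mean, triangular mean) with bound constants tuned to the profile's
#' signal scale on anomaly-free calibration fixtures. The uncertainty gate
#' is disabled here because the fixtures' noise level sits far below any
#' realistic manufacturer accuracy band and anomaly magnitudes are scaled
#' to the noise; pass an [uncertainty_spec()] to re-enable it.
#'
#' @param name Profile name (see [signal_profile()]).
#' @param uncertainty Optional [uncertainty_spec()]; default disabled.
#' @param warmup_records,cooldown_records Protected record counts.
#' @return A [qc_config()].
#' @export
profile_config <- function(name = c("nitrate_baseflow", "turbidity_storm",
                                    "oxygen_diel", "ph_diel", "constant"),
                           uncertainty = uncertainty_spec(),
                           warmup_records = 480L, cooldown_records = 480L) {
  name <- match.arg(name)
  p <- .PROFILE_PARAMS[[name]]
  windows <- default_qc_windows(topadd = p$topadd, bottomsub = p$bottomsub,
                                std_factor = p$std_factor)
  gate <- uncertainty$pct > 0 || uncertainty$constant > 0
  for (i in 1:2) windows[[i]]$use_uncertainty <- gate
  for (i in 3:5) windows[[i]]$use_uncertainty <- FALSE
  qc_config(windows = windows, warmup_records = warmup_records,
            cooldown_records = cooldown_records, uncertainty = uncertainty)
}

#' The standard fixture suite
#'
#' A fixed collection of synthetic fixtures used to characterise the
#' flagger: for each profile, seeded series with global (+10 sd) and local
#' (4 sd, against the diel phase) single-point anomalies; cluster spans of
#' 30-200 points (offset 6 sd) on the profiles whose background is stable
#' enough that a sustained noise-scale offset is distinguishable from
#' natural variability (baseflow nitrate upward, turbidity downward); storm
#' peaks on the turbidity profile as valid data that must not be flagged;
#' and an anomaly-free constant profile. See the vignette for why diel
#' profiles carry no cluster injections.
#'
#' @return A list of suite entries, each with components `profile`
#'   (a [signal_profile()]), `plan` (an [anomaly_plan()]), `config`
#'   (the [profile_config()]), and `seed`.
#' @export
standard_fixture_suite <- function() {
  entries <- list(
    list(name = "nitrate_baseflow", seed = 11L,
         plan = anomaly_plan(n_global = 6, n_local = 6, n_cluster = 3)),
    list(name = "nitrate_baseflow", seed = 12L,
         plan = anomaly_plan(n_global = 6, n_local = 6, n_cluster = 3)),
    list(name = "turbidity_storm", seed = 21L,
         plan = anomaly_plan(n_global = 6, n_local = 6, n_cluster = 3,
                             cluster_mag = -6)),
    list(name = "turbidity_storm", seed = 22L,
         plan = anomaly_plan(n_global = 6, n_local = 6, n_cluster = 3,
                             cluster_mag = -6)),
    list(name = "oxygen_diel", seed = 31L,
         plan = anomaly_plan(n_global = 6, n_local = 6)),
    list(name = "oxygen_diel", seed = 32L,
         plan = anomaly_plan(n_global = 6, n_local = 6)),
    list(name = "ph_diel", seed = 41L,
         plan = anomaly_plan(n_global = 6, n_local = 6)),
    list(name = "ph_diel", seed = 42L,
         plan = anomaly_plan(n_global = 6, n_local = 6)),
    list(name = "constant", seed = 51L, plan = anomaly_plan())
  )
  lapply(entries, function(e) {
    # a week of records for the storm profile: two daily-separated peaks
    # plus three buffered cluster spans need more room than five days
    n <- if (e$name == "turbidity_storm") 10080L else 7200L
    list(profile = signal_profile(e$name, n_points = n), plan = e$plan,
         config = profile_config(e$name), seed = e$seed)
  })
}
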
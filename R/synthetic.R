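# Deterministic synthetic fixtures: water-quality-like signals with
# injected, ground-truth-labelled anomalies of the three kinds (global,
# local, cluster), plus flag-evaluation metrics.

.PROFILE_DEFAULTS <- list(
  constant = list(baseline = 10, diel_amplitude = 0, trend_per_day = 0,
                  noise_sd = 0, cadence_minutes = 1L, valid_peaks = NULL),
  nitrate_baseflow = list(baseline = 4, diel_amplitude = 0,
                          trend_per_day = -0.02, noise_sd = 0.05,
                          cadence_minutes = 1L, valid_peaks = NULL),
  turbidity_storm = list(baseline = 4, diel_amplitude = 0, trend_per_day = 0,
                         noise_sd = 0.4, cadence_minutes = 1L,
                         valid_peaks = list(n = 2, height = 60,
                                            duration = 360)),
  oxygen_diel = list(baseline = 9, diel_amplitude = 3, trend_per_day = 0,
                     noise_sd = 0.25, cadence_minutes = 1L,
                     valid_peaks = NULL),
  ph_diel = list(baseline = 8.2, diel_amplitude = 0.25, trend_per_day = 0,
                 noise_sd = 0.05, cadence_minutes = 1L, valid_peaks = NULL)
)

#' Synthetic signal profile
#'
#' Describes a clean high-frequency signal: baseline plus optional
#' sinusoidal diel cycle, linear trend, Gaussian noise, and optional
#' "valid peaks" - smooth raised-cosine excursions (storm or point-source
#' peaks) that are legitimate data and must NOT be flagged. Per-name
#' defaults emulate the magnitudes of common freshwater sensors (nitrate in
#' mg N/L, turbidity in FNU, dissolved oxygen in mg/L, pH); see the package
#' vignette for the rationale behind each value.
#'
#' @param name Profile family.
#' @param n_points Series length (default 7200 = five days at 1-min
#'   cadence; must be at least `2 * 480 + 1` for default-config runs).
#' @param cadence_minutes,baseline,diel_amplitude,trend_per_day,noise_sd
#'   Signal parameters; `NULL` takes the per-name default.
#' @param valid_peaks `NULL`, or a list `list(n =, height =, duration =)`
#'   of smooth peaks to superimpose; `NULL` takes the per-name default
#'   (only `turbidity_storm` ships peaks).
#' @return An object of class `signal_profile`.
#' @export
signal_profile <- function(name = c("nitrate_baseflow", "turbidity_storm",
                                    "oxygen_diel", "ph_diel", "constant"),
                           n_points = 7200L, cadence_minutes = NULL,
                           baseline = NULL, diel_amplitude = NULL,
                           trend_per_day = NULL, noise_sd = NULL,
                           valid_peaks = "default") {
  name <- match.arg(name)
  d <- .PROFILE_DEFAULTS[[name]]
  prof <- list(
    name = name,
    n_points = as.integer(n_points),
    cadence_minutes = as.integer(cadence_minutes %||% d$cadence_minutes),
    baseline = baseline %||% d$baseline,
    diel_amplitude = diel_amplitude %||% d$diel_amplitude,
    trend_per_day = trend_per_day %||% d$trend_per_day,
    noise_sd = noise_sd %||% d$noise_sd,
    valid_peaks = if (identical(valid_peaks, "default")) d$valid_peaks
                  else valid_peaks)
  if (prof$n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  if (prof$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (prof$cadence_minutes < 1L)
    stop("cadence_minutes must be a positive integer", call. = FALSE)
  structure(prof, class = "signal_profile")
}

#' Anomaly injection plan
#'
#' Counts and magnitudes of anomalies to inject, with magnitudes in units
#' of the profile's `noise_sd` so plans transfer across profiles. Global
#' and local anomalies are single-sample excursions placed in isolation
#' (the value is set to the clean signal plus the offset, emulating an
#' instrument glitch); cluster anomalies are contiguous spans whose noisy
#' values are all shifted by the offset (emulating fouling or burial).
#' Local anomalies oppose the diel phase where the profile has one, so
#' they stay inside the series' global range.
#'
#' @param n_global,n_local,n_cluster Anomaly counts per kind.
#' @param global_mag,local_mag,cluster_mag Signed magnitudes in noise-sd
#'   units (defaults +10, 4, +6).
#' @param cluster_len Length-2 integer range of cluster span lengths.
#' @param protect Leading/trailing records kept free of anomalies (matches
#'   the default warm-up/cool-down of 480).
#' @param min_gap Minimum spacing between isolated anomalies.
#' @return An object of class `anomaly_plan`.
#' @export
anomaly_plan <- function(n_global = 0L, n_local = 0L, n_cluster = 0L,
                         global_mag = 10, local_mag = 4, cluster_mag = 6,
                         cluster_len = c(30L, 200L), protect = 480L,
                         min_gap = 60L) {
  stopifnot(n_global >= 0, n_local >= 0, n_cluster >= 0,
            length(cluster_len) == 2L, cluster_len[1] >= 1,
            cluster_len[2] >= cluster_len[1], protect >= 0, min_gap >= 1)
  structure(
    list(n_global = as.integer(n_global), n_local = as.integer(n_local),
         n_cluster = as.integer(n_cluster), global_mag = global_mag,
         local_mag = local_mag, cluster_mag = cluster_mag,
         cluster_len = as.integer(cluster_len), protect = as.integer(protect),
         min_gap = as.integer(min_gap)),
    class = "anomaly_plan"
  )
}

# sample one position from the free pool, with retries; block around it
.place <- function(free, span_len, n_try = 5000L) {
  cand <- which(free)
  if (length(cand) == 0L) return(NA_integer_)
  for (k in seq_len(n_try)) {
    p <- cand[sample.int(length(cand), 1L)]
    if (p + span_len - 1L <= length(free) && all(free[p:(p + span_len - 1L)]))
      return(p)
  }
  NA_integer_
}

#' Generate a synthetic sensor series with labelled anomalies
#'
#' Builds the clean signal of `profile` (baseline + diel cycle + trend +
#' valid peaks), adds seeded Gaussian noise, and injects the anomalies of
#' `plan` at non-overlapping positions outside the protected leading and
#' trailing regions and away from valid peaks. Fully reproducible: the same
#' `(profile, plan, seed)` gives a bit-identical series. The caller's RNG
#' state is left untouched.
#'
#' @param profile A [signal_profile()].
#' @param plan An [anomaly_plan()].
#' @param seed Integer seed.
#' @param start Timestamp of the first record.
#' @return A list with components `series` (a [sensor_series()]) and
#'   `truth` (class `anomaly_truth`: `indices`, per-index `kinds`,
#'   `cluster_spans`, `valid_peak_spans`, `n`).
#' @export
#' @examples
#' fx <- generate_series(signal_profile("oxygen_diel", n_points = 2880),
#'                       anomaly_plan(n_global = 5), seed = 42)
#' fx$truth$indices
generate_series <- function(profile, plan = anomaly_plan(), seed,
                            start = as.POSIXct("2022-01-01 00:00:00",
                                               tz = "UTC")) {
  stopifnot(inherits(profile, "signal_profile"),
            inherits(plan, "anomaly_plan"))
  has_anom <- plan$n_global + plan$n_local + plan$n_cluster > 0L
  if (has_anom && profile$noise_sd <= 0)
    stop("anomaly magnitudes are in noise-sd units; noise_sd must be > 0 ",
         "to inject anomalies", call. = FALSE)

  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- profile$n_points
  t_min <- (seq_len(n) - 1) * profile$cadence_minutes
  diel <- if (profile$diel_amplitude != 0)
    profile$diel_amplitude * sin(2 * pi * t_min / 1440) else rep(0, n)
  clean <- profile$baseline + diel + profile$trend_per_day * t_min / 1440

  peak_spans <- list()
  if (!is.null(profile$valid_peaks)) {
    vp <- profile$valid_peaks
    free_pk <- rep(TRUE, n)
    edge <- plan$protect + 1L
    free_pk[seq_len(min(n, edge))] <- FALSE
    free_pk[max(1L, n - edge):n] <- FALSE
    for (k in seq_len(vp$n)) {
      p <- .place(free_pk, vp$duration)
      if (is.na(p)) stop("cannot place valid peaks", call. = FALSE)
      span <- p:(p + vp$duration - 1L)
      s <- seq_along(span) - 1L
      clean[span] <- clean[span] +
        vp$height * 0.5 * (1 - cos(2 * pi * s / (vp$duration - 1L)))
      peak_spans[[k]] <- c(p, p + vp$duration - 1L)
      # peaks emulate daily point-source/storm events: keep successive
      # events at least a diel period apart so they are resolvable
      lo <- max(1L, p - 1440L)
      hi <- min(n, p + vp$duration + 1440L)
      free_pk[lo:hi] <- FALSE
    }
  }

  noise <- if (profile$noise_sd > 0) rnorm(n, 0, profile$noise_sd) else
    rep(0, n)
  values <- clean + noise

  # free positions for anomalies: outside protection, away from peaks
  free <- rep(TRUE, n)
  free[seq_len(min(n, plan$protect))] <- FALSE
  if (plan$protect > 0L) free[max(1L, n - plan$protect + 1L):n] <- FALSE
  for (sp in peak_spans) {
    lo <- max(1L, sp[1] - 700L)
    hi <- min(n, sp[2] + 700L)
    free[lo:hi] <- FALSE
  }

  sd <- profile$noise_sd
  cluster_spans <- list()
  g_idx <- integer(0)
  l_idx <- integer(0)

  for (k in seq_len(plan$n_cluster)) {
    L <- sample(plan$cluster_len[1]:plan$cluster_len[2], 1L)
    p <- .place(free, L)
    if (is.na(p))
      stop("anomaly plan denser than available positions", call. = FALSE)
    span <- p:(p + L - 1L)
    values[span] <- clean[span] + noise[span] + plan$cluster_mag * sd
    cluster_spans[[k]] <- c(p, p + L - 1L)
    free[max(1L, p - 480L):min(n, p + L - 1L + 480L)] <- FALSE
  }

  for (k in seq_len(plan$n_global)) {
    p <- .place(free, 1L)
    if (is.na(p))
      stop("anomaly plan denser than available positions", call. = FALSE)
    values[p] <- clean[p] + plan$global_mag * sd
    g_idx <- c(g_idx, p)
    free[max(1L, p - plan$min_gap):min(n, p + plan$min_gap)] <- FALSE
  }

  for (k in seq_len(plan$n_local)) {
    p <- NA_integer_
    if (profile$diel_amplitude > 0) {
      phase <- sin(2 * pi * t_min / 1440)
      pool <- free & abs(phase) >= 0.5
      p <- .place(pool, 1L)
      if (!is.na(p)) sgn <- -sign(phase[p])
    }
    if (is.na(p)) {
      p <- .place(free, 1L)
      sgn <- if (k %% 2L == 0L) -1 else 1
    }
    if (is.na(p))
      stop("anomaly plan denser than available positions", call. = FALSE)
    values[p] <- clean[p] + sgn * abs(plan$local_mag) * sd
    l_idx <- c(l_idx, p)
    free[max(1L, p - plan$min_gap):min(n, p + plan$min_gap)] <- FALSE
  }

  c_idx <- unlist(lapply(cluster_spans, function(sp) sp[1]:sp[2]))
  idx <- c(g_idx, l_idx, c_idx)
  kinds <- c(rep("GLOBAL", length(g_idx)), rep("LOCAL", length(l_idx)),
             rep("CLUSTER", length(c_idx)))
  ord <- order(idx)

  series <- sensor_series(start + 60 * t_min, values, site = "synthetic",
                          parameter = profile$name)
  truth <- structure(
    list(indices = as.integer(idx[ord]), kinds = kinds[ord],
         cluster_spans = cluster_spans,
         valid_peak_spans = peak_spans, n = n),
    class = "anomaly_truth")
  list(series = series, truth = truth)
}

#' Evaluate flags against the injected truth
#'
#' Precision and recall of a QC run against an [generate_series()] truth,
#' overall and per anomaly kind. Conventions: with zero flags, precision is
#' reported as 1.0; a cluster span counts as detected when at least 80% of
#' its indices are flagged; the false-positive rate on valid peaks is the
#' flagged fraction of peak-span points. Kinds absent from the truth give
#' `NA` recall.
#'
#' @param result A `qc_result` from [run_qc()] on the same series.
#' @param truth The `anomaly_truth` of that series.
#' @return A list of class `flag_metrics`: `precision`, `recall`,
#'   `recall_global`, `recall_local`, `recall_cluster` (span-based),
#'   `cluster_point_recall`, `n_flags`, `n_false_flags`,
#'   `valid_peak_flags`, `valid_peak_fp_rate`.
#' @export
evaluate_flags <- function(result, truth) {
  stopifnot(inherits(result, "qc_result"), inherits(truth, "anomaly_truth"))
  if (length(result$series) != truth$n)
    stop("length mismatch: result has ", length(result$series),
         " points, truth describes ", truth$n, call. = FALSE)
  flags <- flagged_indices(result)
  tidx <- truth$indices
  tp <- intersect(flags, tidx)
  fp <- setdiff(flags, tidx)

  kind_recall <- function(kind) {
    k <- tidx[truth$kinds == kind]
    if (length(k) == 0L) return(NA_real_)
    length(intersect(flags, k)) / length(k)
  }
  span_recall <- if (length(truth$cluster_spans) == 0L) NA_real_ else {
    det <- vapply(truth$cluster_spans, function(sp) {
      span <- sp[1]:sp[2]
      mean(span %in% flags) >= 0.8
    }, logical(1))
    mean(det)
  }
  pk_pts <- unlist(lapply(truth$valid_peak_spans,
                          function(sp) sp[1]:sp[2]))
  pk_flags <- if (length(pk_pts)) sum(flags %in% pk_pts) else 0L

  structure(
    list(precision = if (length(flags) == 0L) 1.0 else
           length(tp) / length(flags),
         recall = if (length(tidx) == 0L) NA_real_ else
           length(tp) / length(tidx),
         recall_global = kind_recall("GLOBAL"),
         recall_local = kind_recall("LOCAL"),
         recall_cluster = span_recall,
         cluster_point_recall = kind_recall("CLUSTER"),
         n_flags = length(flags), n_false_flags = length(fp),
         valid_peak_flags = as.integer(pk_flags),
         valid_peak_fp_rate = if (length(pk_pts)) pk_flags / length(pk_pts)
                              else 0),
    class = "flag_metrics")
}

#' @export
print.flag_metrics <- function(x, ...) {
  cat("flag metrics:\n")
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("  precision %s  recall %s\n", fmt(x$precision),
              fmt(x$recall)))
  cat(sprintf("  recall: global %s  local %s  cluster(span) %s\n",
              fmt(x$recall_global), fmt(x$recall_local),
              fmt(x$recall_cluster)))
  cat(sprintf("  flags %d (false %d); valid-peak flags %d\n",
              x$n_flags, x$n_false_flags, x$valid_peak_flags))
  invisible(x)
}

#' Write / read an anomaly-truth file
#'
#' JSON serialization of the ground truth produced by [generate_series()];
#' indices are 1-based.
#'
#' @param truth An `anomaly_truth`.
#' @param path File path.
#' @return `write_anomaly_truth()`: `path` invisibly;
#'   `read_anomaly_truth()`: the `anomaly_truth`.
#' @export
write_anomaly_truth <- function(truth, path) {
  stopifnot(inherits(truth, "anomaly_truth"))
  jsonlite::write_json(
    list(n = truth$n, indices = truth$indices, kinds = truth$kinds,
         cluster_spans = truth$cluster_spans,
         valid_peak_spans = truth$valid_peak_spans),
    path, auto_unbox = FALSE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_anomaly_truth
#' @export
read_anomaly_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spans <- raw$cluster_spans
  if (is.matrix(spans)) spans <- lapply(seq_len(nrow(spans)),
                                        function(i) as.integer(spans[i, ]))
  else if (is.null(spans) || length(spans) == 0L) spans <- list()
  pks <- raw$valid_peak_spans
  if (is.matrix(pks)) pks <- lapply(seq_len(nrow(pks)),
                                    function(i) as.integer(pks[i, ]))
  else if (is.null(pks) || length(pks) == 0L) pks <- list()
  structure(
    list(indices = as.integer(raw$indices),
         kinds = as.character(raw$kinds),
         cluster_spans = spans, valid_peak_spans = pks,
         n = as.integer(raw$n)),
    class = "anomaly_truth")
}
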
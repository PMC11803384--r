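# Readers and writers: delimited series, JSON parameterization files, and
# the three run outputs (flag table CSV, summary JSON, time-series plot).

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c("," = ",", ";" = ";", "\t" = "\t"),
                   function(s) lengths(regmatches(line, gregexpr(s, line,
                                                                 fixed = TRUE))),
                   integer(1))
  if (all(counts == 0)) stop("could not detect delimiter in ", path,
                             call. = FALSE)
  c(",", ";", "\t")[which.max(counts)]
}

#' Read a sensor series from a delimited text file
#'
#' Reads a timestamp column and a value column from a CSV/TSV file, sorts by
#' time, and returns a [sensor_series()]. Unparseable values become missing
#' points; duplicated timestamps are an error. Comma-decimal dialects are
#' supported when declared via `dec = ","` (with `sep = ";"` or tab).
#'
#' @param path File path.
#' @param timestamp_col,value_col Column name or 1-based index (defaults:
#'   first and second column).
#' @param sep Field delimiter; `NULL` autodetects among `,` `;` and tab.
#' @param dec Decimal mark, `"."` (default) or `","`.
#' @param datetime_format Optional [strptime()] format; the default accepts
#'   ISO-8601 (`2021-05-05T00:01` or `2021-05-05 00:01`, with or without
#'   seconds).
#' @param tz Time zone for parsing (timestamps are treated as
#'   timezone-naive logger time by default, stored as UTC).
#' @param site,parameter Labels attached to the series.
#' @return A [sensor_series()].
#' @export
read_sensor_series <- function(path, timestamp_col = 1L, value_col = 2L,
                               sep = NULL, dec = ".", datetime_format = NULL,
                               tz = "UTC", site = "", parameter = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .detect_sep(path)
  if (identical(sep, ",") && identical(dec, ","))
    stop("sep and dec cannot both be ','", call. = FALSE)
  df <- read.csv(path, sep = sep, dec = ".", stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  pick <- function(col) {
    if (is.character(col)) {
      if (!col %in% names(df)) stop("no column named '", col, "'",
                                    call. = FALSE)
      df[[col]]
    } else df[[as.integer(col)]]
  }
  ts_raw <- pick(timestamp_col)
  val_raw <- pick(value_col)
  ts_norm <- gsub("T", " ", ts_raw, fixed = TRUE)
  if (is.null(datetime_format)) {
    ts <- as.POSIXct(ts_norm, tz = tz,
                     tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                    "%Y-%m-%d"))
  } else {
    ts <- as.POSIXct(ts_raw, tz = tz, format = datetime_format)
  }
  if (anyNA(ts)) stop("unparseable timestamp, e.g. '",
                      ts_raw[which(is.na(ts))[1]], "'", call. = FALSE)
  if (identical(dec, ",")) val_raw <- gsub(",", ".", val_raw, fixed = TRUE)
  vals <- suppressWarnings(as.numeric(val_raw))  # unparseable -> MISSING
  ord <- order(ts)
  sensor_series(ts[ord], vals[ord], site = site, parameter = parameter)
}

.window_keys <- c("window_id", "width", "statistic", "topadd", "bottomsub",
                  "std_factor", "use_uncertainty")
.config_keys <- c("sensor", "windows", "uncertainty", "warmup_records",
                  "cooldown_records", "min_valid_in_window", "include_center")

#' Read a QC parameterization file
#'
#' Loads a JSON parameterization into a [qc_config()]. Every key is
#' optional; omitted windows and window fields fall back to the default
#' five-window set (widths 960/960/48/5/5; mean/mean/median/mean/
#' triangular mean; uncertainty gating on windows 1-2). Unknown keys are
#' rejected with a message listing them. An even configured width is
#' widened by one record so the centred window is symmetric.
#'
#' @param path JSON file path.
#' @return A [qc_config()].
#' @seealso [write_qc_config()] for the schema produced by this package.
#' @export
read_qc_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- default_qc_windows()
  if (!is.null(raw$windows)) {
    if (length(raw$windows) > 5L)
      stop("exactly 5 windows are required (got ", length(raw$windows), ")",
           call. = FALSE)
    for (entry in raw$windows) {
      unknown <- setdiff(names(entry), .window_keys)
      if (length(unknown))
        stop("unknown window keys: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      if (is.null(entry$window_id))
        stop("each window entry needs a window_id", call. = FALSE)
      id <- as.integer(entry$window_id)
      if (is.na(id) || id < 1L || id > 5L)
        stop("window_id must be in 1..5", call. = FALSE)
      d <- defaults[[id]]
      defaults[[id]] <- window_params(
        id,
        width = entry$width %||% d$width,
        statistic = entry$statistic %||% d$statistic,
        topadd = entry$topadd %||% d$topadd,
        bottomsub = entry$bottomsub %||% d$bottomsub,
        std_factor = entry$std_factor %||% d$std_factor,
        use_uncertainty = entry$use_uncertainty %||% d$use_uncertainty)
    }
  }
  unc <- uncertainty_spec()
  if (!is.null(raw$uncertainty)) {
    unknown <- setdiff(names(raw$uncertainty), c("pct", "constant"))
    if (length(unknown))
      stop("unknown uncertainty keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    unc <- uncertainty_spec(pct = raw$uncertainty$pct %||% 0,
                            constant = raw$uncertainty$constant %||% 0)
  }
  qc_config(windows = defaults,
            warmup_records = raw$warmup_records %||% 480L,
            cooldown_records = raw$cooldown_records %||% 480L,
            uncertainty = unc,
            min_valid_in_window = raw$min_valid_in_window %||% 3L,
            include_center = raw$include_center %||% TRUE)
}

#' Write a QC parameterization file
#'
#' Serializes a [qc_config()] to the JSON schema read by
#' [read_qc_config()]; the round trip reproduces the configuration
#' field-for-field.
#'
#' @param cfg A [qc_config()].
#' @param path Output path.
#' @param sensor Optional sensor label stored in the file.
#' @return `path`, invisibly.
#' @export
write_qc_config <- function(cfg, path, sensor = NULL) {
  stopifnot(inherits(cfg, "qc_config"))
  obj <- list(
    windows = lapply(cfg$windows, function(w) w[.window_keys]),
    uncertainty = list(pct = cfg$uncertainty$pct,
                       constant = cfg$uncertainty$constant),
    warmup_records = cfg$warmup_records,
    cooldown_records = cfg$cooldown_records,
    min_valid_in_window = cfg$min_valid_in_window,
    include_center = cfg$include_center)
  if (!is.null(sensor)) obj <- c(list(sensor = sensor), obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the three QC outputs
#'
#' Writes (1) the per-point flag table as CSV (`timestamp,value,status,`
#' `flag_window`; the flag_window cell is empty for unflagged points),
#' (2) a time-series plot with approved points in grey and flagged
#' anomalies in red annotated with the flagging window's number, and
#' (3) a JSON summary of per-window flagged counts and status totals.
#' The CSV uses point decimals and ISO timestamps regardless of the input
#' dialect.
#'
#' @param result A `qc_result`.
#' @param outdir Output directory (created if needed).
#' @param basename Stem for the three file names.
#' @param plot Write the plot? (`FALSE` skips output 2.)
#' @param plot_format `"png"` or `"pdf"`.
#' @return Named character vector of the written paths.
#' @export
write_qc_outputs <- function(result, outdir, basename = "qc", plot = TRUE,
                             plot_format = c("png", "pdf")) {
  stopifnot(inherits(result, "qc_result"))
  plot_format <- match.arg(plot_format)
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", outdir, call. = FALSE)

  tab <- qc_flag_table(result)
  tab$timestamp <- format(tab$timestamp, "%Y-%m-%dT%H:%M:%S")
  flags_path <- file.path(outdir, paste0(basename, "_flags.csv"))
  write.csv(tab, flags_path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")

  smry <- summary(result)
  summary_path <- file.path(outdir, paste0(basename, "_summary.json"))
  jsonlite::write_json(
    list(site = result$series$site, parameter = result$series$parameter,
         n = smry$n, per_window_flagged = as.list(result$per_window_counts),
         totals = as.list(smry$totals), pct_flagged = smry$pct_flagged),
    summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  paths <- c(flags = flags_path, summary = summary_path)
  if (plot) {
    plot_path <- file.path(outdir,
                           paste0(basename, "_plot.", plot_format))
    p <- plot_qc_result(result)
    ggplot2::ggsave(plot_path, p, width = 10, height = 4, dpi = 150)
    paths <- c(paths, plot = plot_path)
  }
  paths
}

#' Plot a QC result
#'
#' Approved points in grey, flagged anomalies in red annotated with the
#' number of the window that flagged them; warm-up/cool-down points in
#' light blue.
#'
#' @param result A `qc_result`.
#' @return A ggplot object.
#' @export
plot_qc_result <- function(result) {
  stopifnot(inherits(result, "qc_result"))
  df <- qc_flag_table(result)
  df$group <- as.character(df$status)
  df$group[df$group %in% c("WARMUP", "COOLDOWN")] <- "Protected"
  df$group[df$group == "APPROVED"] <- "Approved data"
  df$group[df$group == "FLAGGED"] <- "Flagged anomalies"
  df <- df[df$group %in% c("Approved data", "Flagged anomalies",
                           "Protected"), ]
  flagged <- df[df$group == "Flagged anomalies", ]
  ggplot2::ggplot(df, ggplot2::aes(x = timestamp, y = value,
                                   colour = group)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_text(data = flagged,
                       ggplot2::aes(label = flag_window),
                       size = 2.4, vjust = -0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("Approved data" = "grey55",
                                            "Flagged anomalies" = "red",
                                            "Protected" = "skyblue3")) +
    ggplot2::labs(x = NULL,
                  y = result$series$parameter %||% "value",
                  colour = NULL,
                  title = paste0("Moving-window QC",
                                 if (nzchar(result$series$site))
                                   paste0(" - ", result$series$site)
                                 else "")) +
    ggplot2::theme_minimal()
}

#' Read a written flag table back
#'
#' Reloads the CSV written by [write_qc_outputs()]; the per-point statuses
#' and flag provenance round-trip exactly.
#'
#' @param path Flag table CSV path.
#' @param tz Time zone for timestamp parsing.
#' @return A `data.frame` with columns `timestamp` (POSIXct), `value`,
#'   `status` (factor over [qc_status_levels()]), `flag_window`.
#' @export
read_flag_table <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "value", "status", "flag_window")
  if (!all(need %in% names(df)))
    stop("not a flag table (expected columns: ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  df$timestamp <- as.POSIXct(gsub("T", " ", df$timestamp, fixed = TRUE),
                             tz = tz)
  df$status <- factor(df$status, levels = .STATUS_LEVELS)
  df$flag_window <- as.integer(df$flag_window)
  df
}
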
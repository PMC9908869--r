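#' Default analysis configuration
#'
#' All analysis constants in one overridable structure: spectral band
#' edges, Welch window settings, detector constants, cleaning policy,
#' surrogate iteration limits and pacing rates. Values follow the study
#' protocol this pipeline implements (200-Hz recordings, 5-Hz analysis
#' rate, 180-s Hann windows with 50% overlap, VLF 0.005-0.04 Hz,
#' LF 0.04-0.15 Hz, HF 0.15-0.40 Hz).
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    sampling = list(record_hz = 200, analysis_hz = 5),
    bands = list(vlf = c(0.005, 0.04), lf = c(0.04, 0.15),
                 hf = c(0.15, 0.40),
                 ten_s = c(0.08, 0.12), twenty_five_s = c(0.03, 0.05)),
    welch = list(window_s = 180, overlap = 0.5, smoothing = 0.10),
    detector = list(threshold_factor = 0.4, refractory_s = 0.25,
                    bandpass_hz = c(5, 20), search_s = 0.05,
                    running_max_s = 2),
    cleaning = list(median_beats = 11, max_rel_dev = 0.30,
                    rri_bounds_ms = c(300, 2000), warn_edit_frac = 0.10),
    breaths = list(min_breath_s = 1.5, center_window_s = 30,
                   hysteresis_frac = 0.02),
    brs = list(coherency_gate = "modulus", gate_value = 0.5),
    surrogate = list(max_iter = 100, spectrum_tol = 1e-3),
    sdnn = list(window_s = 180, step_s = 1),
    pacing = list(free_hz = 0.22, fast_hz = 0.23, slow_hz = 0.10,
                  durations_s = c(free = 900, fast = 300, slow = 240))
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]:
#' any key present in the file overrides the default, everything else
#' keeps its default value, so partial configs are valid.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

#' Write a recording to a delimited text file
#'
#' Plain comma-separated format: a `# key=value` header block carrying
#' subject/group/condition metadata, the sampling rate and per-channel
#' units, then one column per channel. Diff-able and round-trip safe to
#' the printed precision.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param digits significant digits to print (default 10).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 10) {
  units <- vapply(rec$channels, function(ch) ch$units, character(1))
  hdr <- c(
    sprintf("# subject_id=%s", rec$subject_id),
    sprintf("# group=%s", rec$group),
    sprintf("# condition=%s", rec$condition),
    sprintf("# rate_hz=%.10g", rec$rate),
    sprintf("# units=%s", paste(sprintf("%s:%s", names(units), units),
                                collapse = ","))
  )
  mat <- vapply(rec$channels, function(ch) ch$values,
                numeric(length(rec$channels[[1]]$values)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(rec$channels), collapse = ","), con)
  body <- do.call(paste, c(lapply(seq_len(ncol(mat)), function(j)
    formatC(mat[, j], digits = digits, format = "g")), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a recording from a delimited text file
#'
#' Parses the format written by [write_recording()]. The header must
#' declare a positive sampling rate; all declared channels must be
#' present with equal lengths, and every data row must be numeric.
#'
#' @param path input file path.
#' @param format_spec optional list; `required_channels` names channels
#'   that must be present (error naming the missing one otherwise).
#' @return a [recording()].
#' @export
read_recording <- function(path, format_spec = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx]
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv); val <- sub("^[^=]*=", "", kv)
    meta[[key]] <- val
  }
  rate <- suppressWarnings(as.numeric(meta$rate_hz))
  if (is.na(rate) || rate <= 0) stop("invalid sampling rate in header")
  body <- lines[-hdr_idx]
  cols <- strsplit(body[1], ",")[[1]]
  unit_map <- character(0)
  if (!is.null(meta$units)) {
    for (u in strsplit(meta$units, ",")[[1]]) {
      parts <- strsplit(u, ":")[[1]]
      if (length(parts) == 2) unit_map[parts[1]] <- parts[2]
    }
  }
  req <- format_spec$required_channels
  if (!is.null(req)) {
    miss <- setdiff(req, cols)
    if (length(miss))
      stop("channel ", paste(miss, collapse = ", "), " missing")
  }
  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(data_lines)]
  mat <- matrix(NA_real_, nrow = length(data_lines), ncol = length(cols))
  split_rows <- strsplit(data_lines, ",")
  nfield <- lengths(split_rows)
  if (any(nfield != length(cols)))
    stop("malformed row at line ",
         length(hdr) + 1 + which(nfield != length(cols))[1])
  vals <- suppressWarnings(as.numeric(unlist(split_rows)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / length(cols))
    stop("non-numeric value at line ", length(hdr) + 1 + bad_row)
  }
  mat <- matrix(vals, ncol = length(cols), byrow = TRUE)
  channels <- lapply(seq_along(cols), function(j)
    uniform_signal(mat[, j], rate,
                   units = if (cols[j] %in% names(unit_map))
                     unit_map[[cols[j]]] else "",
                   label = cols[j]))
  names(channels) <- cols
  recording(subject_id = meta$subject_id %||% "unknown",
            group = meta$group %||% "CNT",
            condition = meta$condition %||% "free",
            channels = channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an event series to CSV
#' @param es an [event_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(es, path) {
  df <- data.frame(time_s = es$times, value = es$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event series from CSV
#' @param path input path (columns `time_s`, `value`).
#' @param label,units metadata for the series.
#' @return an [event_series()].
#' @export
read_series <- function(path, label = "", units = "") {
  df <- utils::read.csv(path)
  event_series(df$time_s, df$value, label = label, units = units)
}

#' Write a power spectrum to CSV
#' @param spec a `power_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  df <- data.frame(freq_hz = spec$freqs, psd = spec$psd)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-subject index table
#'
#' One delimited row per subject x condition, mirroring the layout of the
#' study's summary tables (mean RRI/SBP, band powers per signal, pNN50,
#' BRS, coherency indices). Missing estimates (e.g. undefined BRS) are
#' written as an explicit `NA` token. Duplicate (subject, condition)
#' pairs are an error.
#'
#' @param records list of named lists (or one-row data.frames), each
#'   carrying at least `subject_id`, `group`, `condition`.
#' @param path output path.
#' @return the assembled data.frame, invisibly.
#' @export
write_indices_table <- function(records, path) {
  if (!length(records)) {
    df <- data.frame(subject_id = character(0), group = character(0),
                     condition = character(0))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  rows <- lapply(records, function(r) {
    r <- as.list(r)
    if (is.null(r$subject_id) || is.null(r$group) || is.null(r$condition))
      stop("every record needs subject_id, group and condition")
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA
    df[all_cols]
  })
  df <- do.call(rbind, rows)
  key <- paste(df$subject_id, df$condition)
  if (anyDuplicated(key))
    stop("duplicate (subject, condition): ", key[duplicated(key)][1])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(df)
}
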
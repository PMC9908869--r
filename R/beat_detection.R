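#' Parabolic refinement of a sampled peak
#'
#' Fits the parabola through three consecutive samples around a local
#' maximum and returns the sub-sample offset of its vertex, converted to
#' seconds. Offsets are confined to half a sample either side; a flat
#' triple returns 0.
#'
#' @param y_minus,y_0,y_plus sample values at k-1, k, k+1 with
#'   `y_0 >= max(y_minus, y_plus)`.
#' @param rate sampling rate in Hz.
#' @return vertex offset from the central sample, in seconds.
#' @export
refine_peak_parabolic <- function(y_minus, y_0, y_plus, rate) {
  denom <- y_minus - 2 * y_0 + y_plus
  if (denom == 0) return(0)
  # vertex of the quadratic through (-1,y_minus),(0,y_0),(1,y_plus)
  offset <- 0.5 * (y_minus - y_plus) / denom
  offset <- max(-0.5, min(0.5, offset))
  offset / rate
}

#' Detect R peaks in a one-lead ECG
#'
#' Derivative-and-threshold detector: the ECG is band-passed (5-20 Hz,
#' zero-phase), its squared derivative forms a detection energy that is
#' compared against an adaptive threshold (a fraction of the running
#' 2-s maximum). Candidate regions are reduced to the local maximum of
#' the band-passed ECG and the fiducial point is refined to sub-sample
#' precision by parabolic interpolation. A refractory period suppresses
#' double detections.
#'
#' @param ecg a `uniform_signal` (rate >= 100 Hz, duration >= 10 s).
#' @param threshold_factor fraction of the running maximum of the
#'   detection energy used as threshold (default 0.4).
#' @param refractory minimum inter-beat distance in seconds (default 0.25).
#' @param config optional configuration list (detector section).
#' @return list of class `beat_annotations` with `r_times` (s, strictly
#'   increasing, sub-sample refined) and `flags` (all "normal").
#' @export
detect_r_peaks <- function(ecg, threshold_factor = NULL, refractory = NULL,
                           config = default_config()) {
  det <- config$detector
  if (is.null(threshold_factor)) threshold_factor <- det$threshold_factor
  if (is.null(refractory)) refractory <- det$refractory_s
  fs <- ecg$rate
  if (fs < 100) stop("ECG sampling rate must be >= 100 Hz")
  if (signal_duration(ecg) < 10) stop("ECG shorter than 10 s")
  x <- ecg$values
  if (all(x == 0) || max(abs(x - mean(x))) == 0) {
    warning("no peak exceeds threshold: empty annotation")
    return(structure(list(r_times = numeric(0), flags = character(0)),
                     class = "beat_annotations"))
  }
  bp <- signal::filtfilt(signal::butter(2, det$bandpass_hz / (fs / 2),
                                        type = "pass"), x)
  e <- c(0, diff(bp))^2
  # short moving average smooths the energy (50 ms)
  ksm <- max(1L, round(0.05 * fs))
  e <- as.numeric(stats::filter(e, rep(1 / ksm, ksm), sides = 2))
  e[is.na(e)] <- 0
  thr <- threshold_factor * running_max(e, round(det$running_max_s * fs))
  above <- e > thr & e > threshold_factor^2 * max(e) * 1e-4
  if (!any(above)) {
    warning("no peak exceeds threshold: empty annotation")
    return(structure(list(r_times = numeric(0), flags = character(0)),
                     class = "beat_annotations"))
  }
  # contiguous suprathreshold regions -> one candidate each
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  half <- max(1L, round(det$search_s * fs))
  n <- length(x)
  peaks <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    a <- regions[i, 1]; b <- regions[i, 2]
    k0 <- a - 1L + which.max(e[a:b])
    lo <- max(2L, k0 - half); hi <- min(n - 1L, k0 + half)
    k <- lo - 1L + which.max(bp[lo:hi])
    if (k <= 1L || k >= n) next
    if (bp[k] < bp[k - 1] || bp[k] < bp[k + 1]) next
    off <- refine_peak_parabolic(bp[k - 1], bp[k], bp[k + 1], fs)
    peaks <- c(peaks, (k - 1) / fs + off)
  }
  peaks <- sort(unique(peaks))
  # refractory: greedy, keep earlier peak
  if (length(peaks) > 1) {
    keep <- rep(TRUE, length(peaks))
    last <- peaks[1]
    for (i in seq_along(peaks)[-1]) {
      if (peaks[i] - last < refractory) keep[i] <- FALSE else last <- peaks[i]
    }
    peaks <- peaks[keep]
  }
  structure(list(r_times = peaks,
                 flags = rep("normal", length(peaks))),
            class = "beat_annotations")
}

running_max <- function(x, w) {
  # centered running maximum, window w samples (edge-truncated)
  n <- length(x)
  h <- max(1L, w %/% 2L)
  # block trick: coarse maxima refined at block boundaries
  out <- numeric(n)
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h); hi <- pmin(n, idx + h)
  # compute via cummax over blocks of size h (O(n))
  nb <- ceiling(n / h)
  blocks <- split(x, rep(seq_len(nb), each = h)[seq_len(n)])
  fwd <- unlist(lapply(blocks, cummax), use.names = FALSE)
  bwd <- unlist(lapply(blocks, function(b) rev(cummax(rev(b)))),
                use.names = FALSE)
  pmax(fwd[pmin(n, hi)], bwd[lo])
}

#' Beat-to-beat R-R interval series
#'
#' Interval k is the distance between consecutive normal R peaks,
#' in ms, timestamped at the later beat (the interval is only known once
#' the second beat has occurred). Intervals adjacent to a flagged
#' (artifact/ectopic) beat are excluded.
#'
#' @param beats a `beat_annotations` object.
#' @return an `event_series` labelled "rri" (ms).
#' @export
derive_rri <- function(beats) {
  ok <- beats$flags == "normal"
  if (sum(ok) < 2) stop("need at least 2 normal beats")
  t <- beats$r_times
  n <- length(t)
  keep <- which(ok[-n] & ok[-1])   # both endpoints normal & consecutive
  if (!length(keep)) stop("need at least 2 normal beats in sequence")
  event_series(times = t[keep + 1L],
               values = (t[keep + 1L] - t[keep]) * 1000,
               label = "rri", units = "ms")
}

#' Per-beat systolic pressure series
#'
#' The systolic value of beat k is the maximum of the continuous arterial
#' pressure within the interval `(r_k, r_{k+1}]`, timestamped at the
#' location of that maximum. Beats whose window contains no samples are
#' flagged as artifacts and skipped.
#'
#' @param pressure a `uniform_signal` in mmHg (same recording as `beats`).
#' @param beats a `beat_annotations` object.
#' @return an `event_series` labelled "sbp" (mmHg).
#' @export
extract_sbp <- function(pressure, beats) {
  t <- beats$r_times
  if (length(t) < 2) stop("need at least 2 beats")
  fs <- pressure$rate
  n <- length(pressure$values)
  times <- values <- numeric(0)
  for (k in seq_len(length(t) - 1L)) {
    lo <- floor(t[k] * fs) + 2L          # first sample strictly after r_k
    hi <- min(n, floor(t[k + 1L] * fs) + 1L)
    if (lo > hi) next                    # empty window: skip (artifact)
    seg <- pressure$values[lo:hi]
    j <- which.max(seg)
    times <- c(times, (lo + j - 2L) / fs)
    values <- c(values, seg[j])
  }
  event_series(times, values, label = "sbp", units = "mmHg")
}

#' Remove artifacts and ectopic beats from a beat series
#'
#' Values deviating more than 30% from the running median of 11 beats
#' (or, for R-R intervals, falling outside 300-2000 ms) are treated as
#' artifacts/ectopics: they are removed and replaced by linear
#' interpolation at their own timestamps, preserving series continuity
#' for spectral analysis. The number of edits is reported; more than 10%
#' edited beats triggers a low-quality warning.
#'
#' @param series an `event_series` (>= 10 values).
#' @param policy list with `median_beats`, `max_rel_dev`,
#'   `rri_bounds_ms`, `warn_edit_frac` (see [default_config()]).
#' @return the cleaned `event_series`, with attribute `n_edits`.
#' @export
clean_beat_series <- function(series, policy = default_config()$cleaning) {
  v <- series$values
  if (length(v) < 10) stop("need at least 10 values to clean")
  k <- policy$median_beats
  if (k %% 2 == 0) k <- k + 1
  med <- stats::runmed(v, k, endrule = "median")
  bad <- abs(v - med) > policy$max_rel_dev * abs(med)
  if (identical(series$label, "rri"))
    bad <- bad | v < policy$rri_bounds_ms[1] | v > policy$rri_bounds_ms[2]
  n_edits <- sum(bad)
  if (n_edits > 0) {
    good <- !bad
    if (sum(good) >= 2) {
      v[bad] <- stats::approx(series$times[good], v[good],
                              xout = series$times[bad], rule = 2)$y
    }
  }
  if (n_edits > policy$warn_edit_frac * length(v))
    warning("low quality segment: ", n_edits, "/", length(v),
            " beats edited")
  out <- event_series(series$times, v, label = series$label,
                      units = series$units)
  attr(out, "n_edits") <- n_edits
  out
}

#' Average running-window SDNN
#'
#' The standard deviation of R-R intervals is computed over running
#' windows (default 3 min, stepped by 1 s) and averaged, giving an
#' overall variability index robust to slow trends. Records shorter than
#' one window fall back to the full-record SD with a warning.
#'
#' @param rri an `event_series` of R-R intervals (ms).
#' @param window window length in seconds (default 180).
#' @param step window step in seconds (default 1).
#' @return average SDNN in ms.
#' @export
sdnn_running <- function(rri, window = 180, step = 1) {
  span <- diff(range(rri$times))
  if (span < window) {
    warning("record shorter than SDNN window; using full-record SD")
    return(stats::sd(rri$values))
  }
  starts <- seq(rri$times[1], rri$times[length(rri$times)] - window,
                by = step)
  sds <- vapply(starts, function(t0) {
    sel <- rri$times >= t0 & rri$times < t0 + window
    if (sum(sel) < 2) NA_real_ else stats::sd(rri$values[sel])
  }, numeric(1))
  mean(sds, na.rm = TRUE)
}

#' pNN50 vagal index
#'
#' Fraction of successive R-R interval differences of at least 50 ms
#' (inclusive), an index of vagal heart-rate control. Reported as a
#' fraction in \[0, 1\].
#'
#' @param rri an `event_series` of R-R intervals (ms), >= 2 intervals.
#' @param threshold_ms difference threshold (default 50 ms).
#' @return fraction of successive differences >= threshold.
#' @export
pnn50 <- function(rri, threshold_ms = 50) {
  if (length(rri$values) < 2) stop("need at least 2 intervals")
  d <- abs(diff(rri$values))
  sum(d >= threshold_ms) / length(d)
}

#' Time-domain indices for one beat series pair
#'
#' Convenience wrapper computing mean RRI, mean SBP, average running
#' SDNN and pNN50 in one call.
#'
#' @param rri,sbp `event_series` objects (RRI in ms, SBP in mmHg).
#' @param sdnn_window SDNN window length in seconds.
#' @return named list `mean_rri`, `mean_sbp`, `sdnn`, `pnn50`.
#' @export
time_domain_indices <- function(rri, sbp, sdnn_window = 180) {
  list(mean_rri = mean(rri$values),
       mean_sbp = mean(sbp$values),
       sdnn = suppressWarnings(sdnn_running(rri, window = sdnn_window)),
       pnn50 = pnn50(rri))
}
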
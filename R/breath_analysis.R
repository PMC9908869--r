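#' Segment a respiratory signal into breaths
#'
#' Breath starts are located at upward zero crossings of the centered
#' respiratory signal. Centering subtracts a 30-s moving average so that
#' very-low-frequency baseline wander does not destroy segmentation;
#' the raw (uncentered) values are kept for the volume series, where the
#' baseline modulation is itself the phenomenon of interest. A
#' hysteresis of 2% of the running tidal amplitude rejects noise-induced
#' double crossings, and breaths shorter than `min_breath` are merged
#' with the next.
#'
#' @param rsp a `uniform_signal` (duration >= 30 s).
#' @param min_breath minimum breath duration in seconds (default 1.5).
#' @param config optional configuration list (breaths section).
#' @return numeric vector of breath-start times (s), strictly increasing.
#' @export
segment_breaths <- function(rsp, min_breath = NULL,
                            config = default_config()) {
  br <- config$breaths
  if (is.null(min_breath)) min_breath <- br$min_breath_s
  fs <- rsp$rate
  if (signal_duration(rsp) < 30) stop("respiratory record shorter than 30 s")
  x <- rsp$values
  n <- length(x)
  xc <- x - moving_average(x, round(br$center_window_s * fs))
  # crossing detection runs on a short-smoothed copy (0.3 s moving
  # average) so sample-level sensor noise cannot re-arm the hysteresis
  # mid-upstroke; volumes always come from the raw signal
  xs <- moving_average(xc, round(0.3 * fs))
  # running tidal amplitude on a coarse 1-s grid (30-s windows)
  amp <- running_amplitude(xs, fs, window_s = br$center_window_s)
  h <- br$hysteresis_frac * amp
  if (all(h <= 0)) stop("respiratory signal unusable: no amplitude")
  # state machine: must dip below -h before the next upward crossing above +h
  armed <- FALSE
  starts <- numeric(0)
  hi <- h[pmin(length(h), ceiling(seq_len(n) / fs))]
  below <- xs < -hi
  above <- xs > hi
  for (i in seq_len(n)) {
    if (below[i]) armed <- TRUE
    if (armed && above[i]) {
      # locate the zero crossing just before i
      j <- i
      while (j > 1 && xs[j - 1] > 0) j <- j - 1
      tcross <- if (j > 1 && xs[j - 1] <= 0 && xs[j] > 0)
        ((j - 2) + (-xs[j - 1]) / (xs[j] - xs[j - 1])) / fs
      else (i - 1) / fs
      starts <- c(starts, tcross)
      armed <- FALSE
    }
  }
  starts <- sort(unique(starts))
  # merge breaths shorter than min_breath with the next: a boundary is
  # kept only when at least min_breath after the last kept boundary
  if (length(starts) > 1) {
    kept <- starts[1]
    for (s in starts[-1])
      if (s - kept[length(kept)] >= min_breath) kept <- c(kept, s)
    starts <- kept
  }
  if (length(starts) < 3) stop("respiratory signal unusable: < 3 breaths")
  starts
}

moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- w %/% 2L
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

running_amplitude <- function(xc, fs, window_s = 30) {
  n <- length(xc)
  nblk <- max(1L, ceiling(n / fs))        # one value per second
  half <- round(window_s / 2)
  vapply(seq_len(nblk), function(b) {
    lo <- max(1L, round((b - 1 - half) * fs))
    hi <- min(n, round((b + half) * fs))
    seg <- xc[lo:hi]
    (max(seg) - min(seg)) / 2
  }, numeric(1))
}

#' Breath-by-breath respiratory series
#'
#' Decomposes the respiratory volume signal into the five breath-by-breath
#' series: for breath b, the end-inspiratory volume EI(b) is the maximum
#' volume within the breath; the end-expiratory volume EE(b) is the
#' minimum between the EI of breaths b and b+1; the inspired volume
#' I(b) = EI(b) - EE(b-1); the expired volume E(b) = EI(b) - EE(b); and
#' the breathing interval BI(b) is the time between consecutive EI
#' events. The first breath has no I (it needs the previous EE); the
#' last has no EE, E or BI. Raw (uncentered) volumes are used so that
#' slow baseline modulation of EI/EE is preserved.
#'
#' @param rsp a `uniform_signal` of respiratory volume (au).
#' @param boundaries breath-start times from [segment_breaths()].
#' @return data.frame of class `breath_table` with columns `breath`,
#'   `ei_time`, `ei_vol`, `ee_time`, `ee_vol`, `insp_vol`, `exp_vol`,
#'   `bi` (NA where undefined).
#' @export
breath_series <- function(rsp, boundaries) {
  if (length(boundaries) < 3) stop("need at least 3 breaths")
  if (any(diff(boundaries) <= 0)) stop("non-monotone breath boundaries")
  fs <- rsp$rate
  x <- rsp$values
  n <- length(x)
  nb <- length(boundaries)
  ends <- c(boundaries[-1], n / fs)
  ei_time <- ei_vol <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- max(1L, floor(boundaries[b] * fs) + 1L)
    hi <- min(n, ceiling(ends[b] * fs))
    seg <- x[lo:hi]
    j <- which.max(seg)
    ei_vol[b] <- seg[j]
    ei_time[b] <- (lo + j - 2L) / fs
  }
  ee_time <- ee_vol <- rep(NA_real_, nb)
  for (b in seq_len(nb - 1L)) {
    lo <- max(1L, floor(ei_time[b] * fs) + 1L)
    hi <- min(n, ceiling(ei_time[b + 1L] * fs) + 1L)
    seg <- x[lo:hi]
    j <- which.min(seg)
    ee_vol[b] <- seg[j]
    ee_time[b] <- (lo + j - 2L) / fs
  }
  insp <- c(NA_real_, ei_vol[-1L] - ee_vol[-nb])
  expv <- ei_vol - ee_vol
  bi <- c(diff(ei_time), NA_real_)
  out <- data.frame(breath = seq_len(nb), ei_time = ei_time,
                    ei_vol = ei_vol, ee_time = ee_time, ee_vol = ee_vol,
                    insp_vol = insp, exp_vol = expv, bi = bi)
  class(out) <- c("breath_table", class(out))
  out
}

#' Breath-by-breath event series from a breath table
#'
#' Extracts one of the five series (EI, EE, I, E, BI) as an
#' `event_series` stamped at its defining event (EI-time for EI/I/E/BI,
#' EE-time for EE), ready for 5-Hz resampling and spectral analysis.
#'
#' @param bt a `breath_table`.
#' @param which one of "ei", "ee", "i", "e", "bi".
#' @return an `event_series` (NA rows dropped).
#' @export
breath_event_series <- function(bt, which = c("ei", "ee", "i", "e", "bi")) {
  which <- match.arg(which)
  col <- switch(which, ei = "ei_vol", ee = "ee_vol", i = "insp_vol",
                e = "exp_vol", bi = "bi")
  tms <- if (which == "ee") bt$ee_time else bt$ei_time
  ok <- !is.na(bt[[col]]) & !is.na(tms)
  event_series(tms[ok], bt[[col]][ok], label = which,
               units = if (which == "bi") "s" else "au")
}
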
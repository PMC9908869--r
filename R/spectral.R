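#' Resample an event series onto a uniform grid
#'
#' Cubic-spline interpolation of a beat-by-beat or breath-by-breath
#' series evaluated on a uniform grid (default 5 Hz) covering the span
#' from first to last timestamp. Linear interpolation is available for
#' sensitivity checks.
#'
#' @param series an `event_series` with >= 4 points spanning >= 2 s.
#' @param rate target rate in Hz (default 5).
#' @param method "spline" (default) or "linear".
#' @param grid optional explicit vector of evaluation times overriding
#'   the internal grid (must lie within the series span).
#' @return a `uniform_signal` at `rate`; attribute `t0` records the time
#'   of the first grid sample.
#' @export
resample_uniform <- function(series, rate = 5, method = c("spline", "linear"),
                             grid = NULL) {
  method <- match.arg(method)
  t <- series$times; v <- series$values
  if (anyDuplicated(t)) stop("duplicate timestamps")
  if (length(t) < 4) stop("need at least 4 points to resample")
  if (diff(range(t)) < 2) stop("series span shorter than 2 s")
  if (is.null(grid))
    grid <- seq(t[1], t[length(t)], by = 1 / rate)
  y <- if (method == "spline")
    stats::spline(t, v, xout = grid, method = "fmm")$y
  else stats::approx(t, v, xout = grid, rule = 2)$y
  out <- uniform_signal(y, rate, units = series$units, label = series$label)
  attr(out, "t0") <- grid[1]
  out
}

#' Decimate a raw signal to the analysis rate
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth, cutoff 0.8 of
#' the target Nyquist) followed by sample picking. The decimation factor
#' must be an integer (200 Hz -> 5 Hz keeps every 40th sample).
#'
#' @param rsp a `uniform_signal` whose rate is an integer multiple of
#'   `rate`.
#' @param rate target rate in Hz (default 5).
#' @return a `uniform_signal` at `rate` (attribute `t0` = 0).
#' @export
decimate_rsp <- function(rsp, rate = 5) {
  q <- rsp$rate / rate
  if (abs(q - round(q)) > 1e-9) stop("non-integer decimation factor")
  q <- as.integer(round(q))
  if (q == 1L) {
    out <- rsp
    attr(out, "t0") <- 0
    return(out)
  }
  cutoff <- 0.8 * (rate / 2)
  flt <- signal::butter(4, cutoff / (rsp$rate / 2), type = "low")
  y <- signal::filtfilt(flt, rsp$values)
  out <- uniform_signal(y[seq(1, length(y), by = q)], rate,
                        units = rsp$units, label = rsp$label)
  attr(out, "t0") <- 0
  out
}

# Segment a series for Welch estimation: returns the FFT of each
# Hann-windowed, linearly detrended segment plus the one-sided scaling.
welch_segments <- function(values, fs, window_s, overlap) {
  nwin <- round(window_s * fs)
  n <- length(values)
  if (n < nwin) stop("record too short: ", n / fs, " s < ", window_s, " s")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  # running windows cover the whole record: add a flush-right segment
  # when stepping leaves a meaningful tail (> 10% of a step) uncovered
  if (n - nwin + 1L - starts[length(starts)] >= step %/% 10L)
    starts <- c(starts, n - nwin + 1L)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  idx <- seq_len(nwin)
  ffts <- lapply(starts, function(s0) {
    seg <- values[s0 + idx - 1L]
    fit <- stats::lm.fit(cbind(1, idx), seg)   # per-segment linear detrend
    stats::fft(w * fit$residuals)
  })
  nf <- nwin %/% 2L
  freqs <- seq_len(nf) * fs / nwin
  # one-sided PSD scale: 2 / (fs * sum(w^2)); Nyquist bin unpaired
  scale <- 2 / (fs * sum(w^2))
  list(ffts = ffts, freqs = freqs, nf = nf, nwin = nwin,
       scale = scale, n_segments = length(starts))
}

# Broadband smoothing: moving average over frequency whose half-width
# grows with frequency (constant relative bandwidth), minimum one line.
smooth_broadband <- function(p, freqs, smoothing) {
  if (is.null(smoothing) || smoothing <= 0) return(p)
  df <- freqs[2] - freqs[1]
  nf <- length(freqs)
  half <- pmax(1L, as.integer(round(smoothing * freqs / df)))
  out <- p
  for (i in seq_len(nf)) {
    lo <- max(1L, i - half[i]); hi <- min(nf, i + half[i])
    out[i] <- mean(p[lo:hi])
  }
  out
}

#' Welch power spectral density with broadband smoothing
#'
#' Averages Hann-windowed, per-segment linearly detrended periodograms
#' over 50%-overlapped running windows (default 180 s), then applies
#' broadband smoothing: a frequency-domain moving average whose
#' half-width is a fixed fraction of the center frequency (default 10%,
#' minimum one spectral line), giving a constant relative bandwidth.
#' The density is scaled so its integral approximates the variance of
#' the detrended series.
#'
#' @param x a `uniform_signal` (typically 5 Hz).
#' @param window_s segment length in seconds (default 180).
#' @param overlap fractional overlap (default 0.5).
#' @param smoothing relative half-bandwidth of the broadband smoother
#'   (default 0.10; 0 disables smoothing).
#' @return object of class `power_spectrum`: `freqs` (Hz, excluding DC),
#'   `psd` (units^2/Hz), `total_power` (trapezoidal integral) and `meta`.
#' @export
welch_psd <- function(x, window_s = 180, overlap = 0.5, smoothing = 0.10) {
  ws <- welch_segments(x$values, x$rate, window_s, overlap)
  nf <- ws$nf
  p <- Reduce(`+`, lapply(ws$ffts, function(f)
    Mod(f[2:(nf + 1L)])^2)) / ws$n_segments * ws$scale
  if (nf * 2L == ws$nwin) p[nf] <- p[nf] / 2   # Nyquist bin is unpaired
  p <- smooth_broadband(p, ws$freqs, smoothing)
  structure(list(freqs = ws$freqs, psd = p,
                 total_power = trapz(ws$freqs, p),
                 meta = list(window_s = window_s, overlap = overlap,
                             n_segments = ws$n_segments,
                             smoothing = smoothing, units = x$units,
                             label = x$label)),
            class = "power_spectrum")
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum '%s': %d lines to %.3g Hz, total %.4g, %d segment(s)>\n",
              x$meta$label %||% "", length(x$freqs), max(x$freqs),
              x$total_power, x$meta$n_segments))
  invisible(x)
}

#' Integrate a power spectrum over a band
#'
#' Trapezoidal integral of the density over the half-open band
#' `[f_lo, f_hi)`, so adjacent standard bands (VLF/LF/HF sharing edges
#' at 0.04 and 0.15 Hz) never double-count a line.
#'
#' @param spec a `power_spectrum`.
#' @param f_lo,f_hi band edges in Hz, within the grid span.
#' @return band power in the squared units of the source series.
#' @export
band_power <- function(spec, f_lo, f_hi) {
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (f_hi <= spec$freqs[1] || f_lo >= max(spec$freqs))
    stop("band outside the frequency grid")
  sel <- spec$freqs >= f_lo & spec$freqs < f_hi
  if (sum(sel) < 2) stop("band contains fewer than 2 grid lines")
  trapz(spec$freqs[sel], spec$psd[sel])
}

#' Standard VLF/LF/HF band powers
#'
#' @param spec a `power_spectrum`.
#' @param bands list of band edge pairs (defaults: VLF 0.005-0.04,
#'   LF 0.04-0.15, HF 0.15-0.40 Hz).
#' @return named list `vlf_p`, `lf_p`, `hf_p` plus the band edges used.
#' @export
standard_band_powers <- function(spec, bands = default_config()$bands) {
  list(vlf_p = band_power(spec, bands$vlf[1], bands$vlf[2]),
       lf_p = band_power(spec, bands$lf[1], bands$lf[2]),
       hf_p = band_power(spec, bands$hf[1], bands$hf[2]),
       bands = bands[c("vlf", "lf", "hf")])
}

#' Normalize a spectrum to unit total power
#'
#' Divides the density by its total power so the integral equals one.
#' Applied to the uncalibrated respiratory volume spectra, whose absolute
#' scale is arbitrary; band fractions are unchanged.
#'
#' @param spec a `power_spectrum` with positive total power.
#' @return the normalized `power_spectrum`.
#' @export
normalize_total_power <- function(spec) {
  if (spec$total_power <= 0) stop("cannot normalize a zero-power spectrum")
  spec$psd <- spec$psd / spec$total_power
  spec$total_power <- trapz(spec$freqs, spec$psd)
  spec$meta$normalized <- TRUE
  spec
}
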
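#' Coherency spectrum between two uniformly sampled series
#'
#' Estimates auto- and cross-spectra with the same segmentation, Hann
#' windowing, per-segment detrending and broadband smoothing as
#' [welch_psd()], and derives the squared coherence modulus
#' `k2 = |S_xy|^2 / (S_xx S_yy)`, the cross-phase `arg(S_xy)` and the
#' open-loop transfer gain `|S_xy| / S_xx` from x to y. Segment
#' averaging and frequency smoothing use identical non-negative weights
#' for all three spectra, so `0 <= k2 <= 1` holds by the Cauchy-Schwarz
#' inequality (asserted to 1e-9).
#'
#' The phase convention is `S_xy = mean(Conj(X) * Y)`: a pure delay of y
#' behind x produces a negative phase with slope `-2*pi*tau`. With
#' x = SBP and y = RRI, baroreflex lag therefore shows as negative phase
#' in the LF band.
#'
#' @param x,y `uniform_signal` objects with equal rate and length
#'   (duration >= `window_s`).
#' @param window_s,overlap,smoothing Welch settings as in [welch_psd()].
#' @param pair label for the signal pair (e.g. "SBP-RRI").
#' @return object of class `coherency_result`: `freqs`, `k2`, `phase`
#'   (radians), `gain` (units_y / units_x), `pair`, `meta`.
#' @export
coherency <- function(x, y, window_s = 180, overlap = 0.5,
                      smoothing = 0.10, pair = paste(x$label, y$label,
                                                     sep = "-")) {
  if (x$rate != y$rate) stop("signals must share one sampling rate")
  if (length(x$values) != length(y$values))
    stop("signals must have equal length")
  wx <- welch_segments(x$values, x$rate, window_s, overlap)
  wy <- welch_segments(y$values, y$rate, window_s, overlap)
  nf <- wx$nf
  idx <- 2:(nf + 1L)
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in seq_len(wx$n_segments)) {
    fx <- wx$ffts[[s]][idx]; fy <- wy$ffts[[s]][idx]
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + Conj(fx) * fy
  }
  sxx <- sxx / wx$n_segments * wx$scale
  syy <- syy / wx$n_segments * wx$scale
  sxy <- sxy / wx$n_segments * wx$scale
  f <- wx$freqs
  sxx <- smooth_broadband(sxx, f, smoothing)
  syy <- smooth_broadband(syy, f, smoothing)
  sxy_r <- smooth_broadband(Re(sxy), f, smoothing)
  sxy_i <- smooth_broadband(Im(sxy), f, smoothing)
  sxy <- complex(real = sxy_r, imaginary = sxy_i)
  denom <- sxx * syy
  k2 <- ifelse(denom > 0, Mod(sxy)^2 / denom, 0)
  if (any(k2 > 1 + 1e-9) || any(k2 < -1e-9))
    stop("internal error: coherence outside [0,1] (smoothing inconsistency)")
  k2 <- pmin(1, pmax(0, k2))
  structure(list(freqs = f, k2 = k2, phase = Arg(sxy),
                 gain = ifelse(sxx > 0, Mod(sxy) / sxx, 0),
                 pair = pair,
                 meta = list(window_s = window_s, overlap = overlap,
                             smoothing = smoothing,
                             n_segments = wx$n_segments)),
            class = "coherency_result")
}

#' @export
print.coherency_result <- function(x, ...) {
  cat(sprintf("<coherency %s: %d lines, %d segment(s), max k2 = %.3f>\n",
              x$pair, length(x$freqs), x$meta$n_segments, max(x$k2)))
  invisible(x)
}

#' Band-averaged coherency index
#'
#' Arithmetic mean of the squared coherence modulus over the grid lines
#' in a closed band. The two standard indices are the 10-s coherency
#' (0.08-0.12 Hz, the Mayer-wave peak of SBP-RRI coupling) and the 25-s
#' coherency (0.03-0.05 Hz, its characteristic trough).
#'
#' @param coh a `coherency_result`.
#' @param band length-2 numeric band in Hz, or "ten_s" / "twenty_five_s".
#' @return coherency index in \[0, 1\].
#' @export
band_coherency <- function(coh, band = "ten_s") {
  if (is.character(band)) {
    band <- match.arg(band, c("ten_s", "twenty_five_s"))
    band <- default_config()$bands[[band]]
  }
  sel <- coh$freqs >= band[1] & coh$freqs <= band[2]
  if (!any(sel)) stop("no grid line in band")
  mean(coh$k2[sel])
}

#' Transfer-function baroreflex sensitivity
#'
#' BRS is the average of the SBP-to-RRI transfer-function modulus over
#' the LF band (0.04-0.15 Hz), restricted to spectral lines where the
#' coherency modulus exceeds 0.5 and the phase between SBP and RRI is
#' negative (RRI lagging SBP, the baroreflex direction). When no line
#' qualifies, the estimate is undefined (`defined = FALSE`, `brs = NA`)
#' -- a valid outcome, not an error.
#'
#' @param coh a `coherency_result` computed with x = SBP (mmHg) and
#'   y = RRI (ms).
#' @param band LF band edges in Hz (default 0.04-0.15).
#' @param gate "modulus" gates on `sqrt(k2) > gate_value` (default);
#'   "squared" gates on `k2 > gate_value`.
#' @param gate_value coherency gate threshold (default 0.5).
#' @return object of class `brs_estimate`: `brs` (ms/mmHg or NA),
#'   `n_lines_used`, `band`, `defined`.
#' @export
estimate_brs <- function(coh, band = c(0.04, 0.15),
                         gate = c("modulus", "squared"), gate_value = 0.5) {
  gate <- match.arg(gate)
  in_band <- coh$freqs >= band[1] & coh$freqs <= band[2]
  cohval <- if (gate == "modulus") sqrt(coh$k2) else coh$k2
  ok <- in_band & cohval > gate_value & coh$phase > -pi & coh$phase < 0
  n <- sum(ok)
  structure(list(brs = if (n >= 1) mean(coh$gain[ok]) else NA_real_,
                 n_lines_used = n, band = band, defined = n >= 1),
            class = "brs_estimate")
}

#' @export
print.brs_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<BRS %.3f ms/mmHg from %d LF lines>\n", x$brs,
                x$n_lines_used))
  else cat("<BRS undefined: no coherent negative-phase LF line>\n")
  invisible(x)
}

#' Fisher z-transform of a coherency value
#'
#' `atanh(k)`, mapping \[0, 1) onto \[0, Inf) so that coherency indices
#' become approximately Normal for group statistics. Values at or above
#' 1 are clipped to `1 - 1e-6` with a warning.
#'
#' @param k coherency value(s) in \[0, 1\].
#' @return transformed value(s).
#' @export
fisher_z <- function(k) {
  if (any(k < 0)) stop("coherency must be non-negative")
  if (any(k >= 1)) {
    warning("coherency >= 1 clipped before z-transform")
    k <- pmin(k, 1 - 1e-6)
  }
  atanh(k)
}
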
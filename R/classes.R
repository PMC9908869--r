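#' Uniformly sampled signal
#'
#' Container for one uniformly sampled channel: a numeric vector of values,
#' a sampling rate in Hz and unit/label metadata. This is the currency for
#' raw recordings (200 Hz) and for the 5-Hz resampled series fed to the
#' spectral estimators.
#'
#' @param values numeric vector of finite samples.
#' @param rate sampling rate in Hz, positive scalar.
#' @param units unit string (e.g. "ms", "mmHg", "au").
#' @param label channel label (e.g. "ecg", "rri").
#' @return An object of class `uniform_signal` with fields `values`,
#'   `rate`, `units`, `label`.
#' @export
uniform_signal <- function(values, rate, units = "", label = "") {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive scalar (Hz)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("signal values must be finite")
  structure(list(values = values, rate = as.numeric(rate),
                 units = units, label = label),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal '%s': %d samples @ %g Hz (%.1f s), units '%s'>\n",
              x$label, length(x$values), x$rate,
              length(x$values) / x$rate, x$units))
  invisible(x)
}

#' Signal duration in seconds
#' @param x a `uniform_signal`.
#' @return duration in seconds (n / rate).
#' @export
signal_duration <- function(x) length(x$values) / x$rate

#' Sample times of a uniform signal
#' @param x a `uniform_signal`.
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
signal_times <- function(x) (seq_along(x$values) - 1) / x$rate

#' Event series (beat-by-beat or breath-by-breath values)
#'
#' Timestamped non-uniform series such as R-R intervals (ms), per-beat
#' systolic pressure (mmHg) or breath-by-breath volumes (au). Times are
#' seconds from recording start and must be strictly increasing.
#'
#' @param times numeric vector of timestamps, strictly increasing (s).
#' @param values numeric vector, same length as `times`.
#' @param label series label (e.g. "rri", "sbp", "ei").
#' @param units unit string.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times, values, label = "", units = "") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  structure(list(times = times, values = values, label = label,
                 units = units),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series '%s': %d events over %.1f s, units '%s'>\n",
              x$label, length(x$times),
              if (length(x$times)) diff(range(x$times)) else 0, x$units))
  invisible(x)
}

#' Multichannel physiological recording
#'
#' Bundles the synchronously sampled channels of one recording session
#' (ecg, pressure, rsp) with subject/group/condition metadata. All channels
#' must share one sampling rate and length.
#'
#' @param subject_id subject identifier.
#' @param group "CNT" or "HF".
#' @param condition "free", "fast" or "slow".
#' @param channels named list of `uniform_signal` objects.
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, group, condition, channels) {
  group <- match.arg(group, c("CNT", "HF"))
  condition <- match.arg(condition, c("free", "fast", "slow"))
  if (!length(channels) || is.null(names(channels)))
    stop("`channels` must be a named list of uniform_signal objects")
  rates <- vapply(channels, function(ch) ch$rate, numeric(1))
  lens  <- vapply(channels, function(ch) length(ch$values), integer(1))
  if (length(unique(rates)) != 1L)
    stop("all channels must share one sampling rate")
  if (length(unique(lens)) != 1L)
    stop("channel length mismatch: ",
         paste(sprintf("%s=%d", names(channels), lens), collapse = ", "))
  structure(list(subject_id = subject_id, group = group,
                 condition = condition, channels = channels,
                 rate = rates[[1]], duration = lens[[1]] / rates[[1]]),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s [%s/%s]: %s @ %g Hz, %.0f s>\n",
              x$subject_id, x$group, x$condition,
              paste(names(x$channels), collapse = "+"),
              x$rate, x$duration))
  invisible(x)
}
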
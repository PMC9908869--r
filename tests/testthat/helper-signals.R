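# shared fixtures built in code

sine_signal <- function(freq, dur, rate = 5, amp = 1, phase = 0) {
  tt <- seq(0, dur, by = 1 / rate)
  uniform_signal(amp * sin(2 * pi * freq * tt + phase), rate)
}

# noiseless Gaussian R-wave train for detector tests
gaussian_ecg <- function(beat_times, dur, rate = 200, width = 0.01) {
  tt <- seq(0, dur - 1 / rate, by = 1 / rate)
  v <- numeric(length(tt))
  for (tb in beat_times)
    v <- v + exp(-(tt - tb)^2 / (2 * width^2))
  uniform_signal(v, rate, units = "mV", label = "ecg")
}

# beat-and-SBP pair from the generator without waveform rendering,
# resampled onto one 5-Hz grid; the fast route to coherency/BRS tests
sim_beat_pair <- function(seed, group = "CNT", condition = "fast", ...) {
  p <- sim_params(group, condition, seed = seed, ...)
  r <- simulate_respiration(p, seed = seed)
  h <- simulate_hemodynamics(r, p, seed = seed + 1000L)
  al <- baroresp:::align_on_grid(list(sbp = h$sbp, rri = h$rri))
  list(params = p, resp = r, hemo = h, sbp5 = al$sbp, rri5 = al$rri)
}

tiny_recording <- function(dur = 60, rate = 200, subject = "S1") {
  n <- dur * rate
  recording(subject, "CNT", "free", channels = list(
    ecg = uniform_signal(sin(2 * pi * seq_len(n) / rate), rate, "mV", "ecg"),
    pressure = uniform_signal(rep(100, n), rate, "mmHg", "pressure"),
    rsp = uniform_signal(cos(2 * pi * 0.2 * seq_len(n) / rate), rate,
                         "au", "rsp")))
}
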
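#' Simulation parameters for a synthetic subject
#'
#' Builds the parameter set for one synthetic recording, emulating the
#' statistical structure the analysis chain assumes: a respiratory
#' volume with a tidal oscillation (free ~13 breaths/min with natural
#' rate and depth variability; fast-paced constant rate in 12-15
#' breaths/min; slow-paced 6 breaths/min) riding on a very-low-frequency
#' baseline whose amplitude distinguishes the HF-like profile (large
#' end-inspiratory/end-expiratory modulation at constant tidal volume)
#' from the CNT-like profile; beat-by-beat SBP carrying a 0.1-Hz Mayer
#' wave plus a mechanical respiratory component; and RRI driven from SBP
#' through a baroreflex arm of known gain and delay plus respiratory
#' sinus arrhythmia. Durations follow the study protocol: 900 s free,
#' 300 s fast, 240 s slow.
#'
#' @param group "CNT" or "HF" profile.
#' @param condition "free", "fast" or "slow".
#' @param ... overrides for any default parameter.
#' @return named list of class `sim_params`.
#' @export
sim_params <- function(group = c("CNT", "HF"),
                       condition = c("free", "fast", "slow"), ...) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  p <- list(
    group = group, condition = condition,
    rate = 200,
    duration = c(free = 900, fast = 300, slow = 240)[[condition]],
    mean_rri = if (group == "CNT") 900 else 920,    # ms
    mean_sbp = if (group == "CNT") 120 else 113,    # mmHg
    brs_gain = if (group == "CNT") 6 else 4.5,      # ms/mmHg
    brs_delay = 1.5,                                # s
    mayer_amp = 3,                                  # mmHg at 0.1 Hz
    mayer_freq = 0.1,
    mayer_bw = 0.02,                                # Lorentzian linewidth, Hz
    rsa_gain = 30,                                  # ms per au of rsp
    resp_rate = c(free = 0.22, fast = 0.23, slow = 0.10)[[condition]],
    resp_rate_mod = if (condition == "free") 0.10 else 0,
    tidal_vol = 1,                                  # au peak-to-trough
    tidal_cv = if (condition == "free") 0.15 else 0.03,
    vlf_amp = if (group == "HF") 0.25 else 0.05,    # au
    vlf_freq = 0.012,                               # Hz
    mech_gain = 2,                                  # mmHg per au
    noise_sbp_sd = 1,                               # mmHg per beat
    noise_rri_sd = 8,                               # ms per beat
    rsp_noise_sd = 0.02,                            # au per sample
    snr_db = 20,                                    # ECG rendering SNR
    dbp = 70,                                       # rendered diastolic
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  stopifnot(p$duration >= 180, p$vlf_amp >= 0, p$mayer_amp >= 0,
            p$tidal_vol > 0)
  class(p) <- "sim_params"
  p
}

# slowly varying unit-variance noise: white noise at 1 Hz, moving-average
# smoothed over `smooth_s`, interpolated to the sample grid
slow_noise <- function(n_samples, fs, smooth_s = 25) {
  nsec <- ceiling(n_samples / fs) + 2 * smooth_s
  w <- stats::rnorm(nsec)
  m <- moving_average(w, smooth_s)
  m <- m[(smooth_s + 1):(smooth_s + ceiling(n_samples / fs))]
  m <- m / max(stats::sd(m), 1e-12)
  stats::approx(seq_along(m) - 1, m, xout = (seq_len(n_samples) - 1) / fs,
                rule = 2)$y
}

#' Simulate a respiratory volume signal
#'
#' Generates `rsp(t) = A_vlf sin(2 pi f_vlf t + psi) + a(t) sin(phi(t))
#' + noise`, where the tidal phase advances at the condition's breathing
#' rate (randomly modulated +/-10% for free breathing, constant when
#' paced) and the tidal amplitude `a(t)` carries slow depth variability.
#' The very-low-frequency baseline shifts end-inspiratory and
#' end-expiratory levels together, leaving tidal volume unchanged -- the
#' HF-profile respiratory signature.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed (defaults to `params$seed`).
#' @return list with `rsp` (a `uniform_signal` at `params$rate`) and
#'   `truth` (data.frame of per-breath EI/EE times and noise-free
#'   volumes, plus attributes with the component amplitudes).
#' @export
simulate_respiration <- function(params, seed = params$seed) {
  fs <- params$rate
  n <- round(params$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  with_local_seed(seed, {
    psi <- stats::runif(1, 0, 2 * pi)
    fr <- rep(params$resp_rate, n)
    if (params$resp_rate_mod > 0) {
      m <- slow_noise(n, fs, smooth_s = 30)
      fr <- params$resp_rate * (1 + params$resp_rate_mod *
                                  pmax(-1, pmin(1, m)))
    }
    phase <- 2 * pi * cumsum(fr) / fs
    amp <- params$tidal_vol / 2
    a_t <- rep(amp, n)
    if (params$tidal_cv > 0) {
      ma <- slow_noise(n, fs, smooth_s = 20)
      a_t <- amp * pmax(0.2, 1 + params$tidal_cv * ma)
    }
    baseline <- params$vlf_amp * sin(2 * pi * params$vlf_freq * tt + psi)
    clean <- baseline + a_t * sin(phase)
    rsp <- clean + stats::rnorm(n, sd = params$rsp_noise_sd)
    # ground-truth breath events from the tidal phase: EI at phase =
    # pi/2 + 2k pi, EE at 3 pi/2 + 2k pi (phase is strictly increasing)
    ei_ph <- seq(pi / 2, phase[n], by = 2 * pi)
    ei_ph <- ei_ph[ei_ph >= phase[1]]
    ee_ph <- ei_ph + pi
    ee_ph <- ee_ph[ee_ph <= phase[n]]
    ei_time <- stats::approx(phase, tt, xout = ei_ph)$y
    ee_time <- stats::approx(phase, tt, xout = ee_ph)$y
    nb <- length(ei_time)
    bval <- function(times) stats::approx(tt, baseline, xout = times,
                                          rule = 2)$y
    aval <- function(times) stats::approx(tt, a_t, xout = times,
                                          rule = 2)$y
    truth <- data.frame(
      breath = seq_len(nb),
      ei_time = ei_time,
      ei_vol = bval(ei_time) + aval(ei_time),
      ee_time = c(ee_time, rep(NA_real_, nb - length(ee_time))),
      ee_vol = c(bval(ee_time) - aval(ee_time),
                 rep(NA_real_, nb - length(ee_time))))
    attr(truth, "vlf_amp") <- params$vlf_amp
    attr(truth, "tidal_vol") <- params$tidal_vol
    attr(truth, "resp_rate") <- params$resp_rate
    sig <- uniform_signal(rsp, fs, units = "au", label = "rsp")
    list(rsp = sig, truth = truth,
         internals = list(baseline = baseline, tidal = a_t * sin(phase)))
  })
}

#' Simulate beat-by-beat hemodynamics driven by a respiratory signal
#'
#' Beat times accumulate as `t_{k+1} = t_k + RRI_k / 1000`. Per beat k:
#' `SBP_k = S0 + a_M sin(2 pi 0.1 t_k + phi) + g_mech (rsp(t_k) - mean)
#' + eps_S`, and `RRI_k = R0 + G (SBP(t_k - delay) - S0) + c_RSA
#' (rsp(t_k) - mean) + eps_R`, where the delayed SBP is linearly
#' interpolated from the emitted per-beat values -- the open-loop
#' baroreflex arm with known gain `G` and delay. Parameter sets driving
#' RRI outside 300-2000 ms are rejected as non-physiologic.
#'
#' @param resp output of [simulate_respiration()] (the physiologic,
#'   noise-free respiratory drive is used for the autonomic and
#'   mechanical arms; sensor noise stays in the recorded channel), or a
#'   bare `uniform_signal`.
#' @param params a [sim_params()] object.
#' @param seed integer seed (defaults to `params$seed + 1`).
#' @return list with `beats` (vector of beat times), `sbp` and `rri`
#'   (`event_series`; RRI stamped at the later beat) and `truth`
#'   (gain, delay, component amplitudes).
#' @export
simulate_hemodynamics <- function(resp, params, seed = params$seed + 1L) {
  if (inherits(resp, "uniform_signal")) {
    fs <- resp$rate
    rc <- resp$values
  } else {
    fs <- resp$rsp$rate
    rc <- resp$internals$baseline + resp$internals$tidal
  }
  rc <- rc - mean(rc)
  dur <- length(rc) / fs
  with_local_seed(seed, {
    # Mayer wave: narrowband stochastic oscillation around 0.1 Hz,
    # modeled as a phase-diffusing sinusoid (Lorentzian line of width
    # `mayer_bw`), not a deterministic sine -- spontaneous pressure
    # oscillations drift in phase, spreading coupling over the LF band
    phiM <- stats::runif(1, 0, 2 * pi)
    sig_phi <- sqrt(2 * pi * params$mayer_bw)        # rad per sqrt(s)
    phase_m <- phiM + 2 * pi * params$mayer_freq * (seq_len(length(rc)) - 1) / fs +
      cumsum(stats::rnorm(length(rc), sd = sig_phi / sqrt(fs)))
    mayer <- params$mayer_amp * sin(phase_m)
    nmax <- ceiling(dur / (params$mean_rri / 1000) * 2) + 10
    t_k <- numeric(nmax); sbp_k <- numeric(nmax); rri_k <- numeric(nmax)
    eS <- stats::rnorm(nmax, sd = params$noise_sbp_sd)
    eR <- stats::rnorm(nmax, sd = params$noise_rri_sd)
    # recordings do not start on an R peak: random phase of the first
    # beat; stop early enough that the last beat's waveform fits
    k <- 0L; t <- stats::runif(1, 0.2, 1.0)
    while (t < dur - 0.3 && k < nmax) {
      k <- k + 1L
      t_k[k] <- t
      ridx <- min(length(rc), max(1L, round(t * fs) + 1L))
      sbp_k[k] <- params$mean_sbp + mayer[ridx] +
        params$mech_gain * rc[ridx] + eS[k]
      tpast <- t - params$brs_delay
      sbp_past <- if (k >= 2 && tpast >= t_k[1])
        stats::approx(t_k[1:k], sbp_k[1:k], xout = tpast, rule = 2)$y
      else params$mean_sbp
      rri <- params$mean_rri +
        params$brs_gain * (sbp_past - params$mean_sbp) +
        params$rsa_gain * rc[ridx] + eR[k]
      if (rri < 300 || rri > 2000)
        stop("non-physiologic parameters: RRI ", round(rri), " ms")
      rri_k[k] <- rri
      t <- t + rri / 1000
    }
    t_k <- t_k[1:k]; sbp_k <- sbp_k[1:k]; rri_k <- rri_k[1:k]
    # drop the last interval if its end falls beyond the record
    nr <- if (t_k[k] + rri_k[k] / 1000 > dur) k - 1L else k
    list(beats = t_k,
         sbp = event_series(t_k, sbp_k, label = "sbp", units = "mmHg"),
         rri = event_series(t_k[seq_len(nr)] + rri_k[seq_len(nr)] / 1000,
                            rri_k[seq_len(nr)], label = "rri",
                            units = "ms"),
         truth = list(brs_gain = params$brs_gain,
                      brs_delay = params$brs_delay,
                      mayer_amp = params$mayer_amp,
                      rsa_gain = params$rsa_gain,
                      mean_rri = params$mean_rri,
                      mean_sbp = params$mean_sbp))
  })
}

#' Render ECG and arterial-pressure waveforms from beat series
#'
#' The ECG is a train of Gaussian R bumps (10-ms width) at the beat
#' times plus white noise at the requested SNR; the pressure channel is
#' a per-beat raised pulse scaled so its maximum equals the beat's
#' systolic value, placed mid-interval. These waveforms close the loop:
#' running the detection chain on them must recover the generator's beat
#' times and SBP values.
#'
#' @param beats vector of beat times (s); intervals < 300 ms are an
#'   error.
#' @param sbp per-beat systolic values (`event_series` or numeric).
#' @param params a [sim_params()] object.
#' @param seed integer seed for the ECG noise (defaults to
#'   `params$seed + 2`).
#' @return list with `ecg` and `pressure` (`uniform_signal` at
#'   `params$rate`).
#' @export
render_waveforms <- function(beats, sbp, params, seed = params$seed + 2L) {
  if (any(diff(beats) < 0.3)) stop("overlapping beats: interval < 300 ms")
  sbp_v <- if (inherits(sbp, "event_series")) sbp$values else sbp
  fs <- params$rate
  dur <- params$duration
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  ecg <- numeric(n)
  sd_r <- 0.010                       # R-wave width, s
  for (tb in beats) {
    lo <- max(1L, floor((tb - 4 * sd_r) * fs) + 1L)
    hi <- min(n, ceiling((tb + 4 * sd_r) * fs) + 1L)
    if (lo > hi) next
    seg <- tt[lo:hi]
    ecg[lo:hi] <- ecg[lo:hi] + exp(-(seg - tb)^2 / (2 * sd_r^2))
  }
  pressure <- rep(params$dbp, n)
  nb <- length(beats)
  for (k in seq_len(min(nb - 1L, length(sbp_v)))) {
    lo <- floor(beats[k] * fs) + 2L
    hi <- min(n, floor(beats[k + 1L] * fs) + 1L)
    if (lo > hi) next
    u <- (tt[lo:hi] - beats[k]) / (beats[k + 1L] - beats[k])
    pressure[lo:hi] <- params$dbp +
      (sbp_v[k] - params$dbp) * sin(pi * u)^2
  }
  with_local_seed(seed, {
    if (is.finite(params$snr_db)) {
      psig <- mean(ecg^2)
      ecg <- ecg + stats::rnorm(n, sd = sqrt(psig *
                                               10^(-params$snr_db / 10)))
    }
    list(ecg = uniform_signal(ecg, fs, units = "mV", label = "ecg"),
         pressure = uniform_signal(pressure, fs, units = "mmHg",
                                   label = "pressure"))
  })
}

#' Simulate one complete synthetic recording
#'
#' Full chain: respiration, beat-by-beat hemodynamics, rendered ECG and
#' pressure waveforms, assembled into a [recording()] with its ground
#' truth attached.
#'
#' @param subject_id subject identifier.
#' @param group,condition profile and breathing condition.
#' @param seed integer master seed for this recording.
#' @param ... parameter overrides passed to [sim_params()].
#' @return list with `recording` and `truth` (beat times, breath truth,
#'   baroreflex gain/delay, component amplitudes).
#' @export
simulate_recording <- function(subject_id, group = "CNT",
                               condition = "free", seed = 1L, ...) {
  params <- sim_params(group = group, condition = condition,
                       seed = seed, ...)
  resp <- simulate_respiration(params, seed = derive_seed(seed, 1))
  hemo <- simulate_hemodynamics(resp, params,
                                seed = derive_seed(seed, 2))
  wave <- render_waveforms(hemo$beats, hemo$sbp, params,
                           seed = derive_seed(seed, 3))
  rec <- recording(subject_id = subject_id, group = group,
                   condition = condition,
                   channels = list(ecg = wave$ecg,
                                   pressure = wave$pressure,
                                   rsp = trim_to(resp$rsp,
                                                 length(wave$ecg$values))))
  list(recording = rec,
       truth = list(beats = hemo$beats, sbp = hemo$sbp, rri = hemo$rri,
                    breaths = resp$truth, params = params,
                    brs_gain = params$brs_gain,
                    brs_delay = params$brs_delay))
}

trim_to <- function(sig, n) {
  uniform_signal(sig$values[seq_len(min(n, length(sig$values)))],
                 sig$rate, units = sig$units, label = sig$label)
}

#' Simulate a cohort of synthetic subjects
#'
#' Reproducible cohort generation: per-subject parameters are drawn
#' around the group profile (modest between-subject variability in mean
#' levels, baroreflex gain, Mayer amplitude and VLF respiratory
#' modulation), and every source of randomness flows from one master
#' seed through deterministic child seeds, which are recorded in the
#' manifest. With `dir` set, recordings and truth tables are written as
#' delimited text.
#'
#' @param n_cnt,n_hf subjects per group.
#' @param conditions breathing conditions to simulate per subject.
#' @param master_seed integer master seed.
#' @param dir optional output directory for recordings + truth CSVs.
#' @param ... parameter overrides applied to every subject.
#' @return list with `subjects` (nested list: subject -> condition ->
#'   simulate_recording() output) and `manifest` (data.frame of subject,
#'   group, condition, child seed).
#' @export
simulate_cohort <- function(n_cnt = 10, n_hf = 30,
                            conditions = c("free", "fast", "slow"),
                            master_seed = 1L, dir = NULL, ...) {
  stopifnot(n_cnt >= 1, n_hf >= 1)
  groups <- c(rep("CNT", n_cnt), rep("HF", n_hf))
  ids <- sprintf("%s%02d", ifelse(groups == "CNT", "C", "H"),
                 c(seq_len(n_cnt), seq_len(n_hf)))
  subjects <- list()
  manifest <- list()
  sidx <- 0L
  for (i in seq_along(ids)) {
    subj <- list()
    subj_seed <- derive_seed(master_seed, i * 101)
    draws <- with_local_seed(subj_seed, {
      base <- sim_params(group = groups[i], condition = "free")
      list(mean_rri = base$mean_rri * stats::rnorm(1, 1, 0.05),
           mean_sbp = base$mean_sbp * stats::rnorm(1, 1, 0.05),
           brs_gain = base$brs_gain * exp(stats::rnorm(1, 0, 0.2)),
           mayer_amp = base$mayer_amp * exp(stats::rnorm(1, 0, 0.2)),
           vlf_amp = base$vlf_amp * exp(stats::rnorm(1, 0, 0.2)),
           resp_rate_free = stats::runif(1, 0.18, 0.27))
    })
    for (cond in conditions) {
      sidx <- sidx + 1L
      seed_c <- derive_seed(subj_seed, match(cond, c("free", "fast",
                                                     "slow")))
      overrides <- list(subject_id = ids[i], group = groups[i],
                        condition = cond, seed = seed_c,
                        mean_rri = draws$mean_rri,
                        mean_sbp = draws$mean_sbp,
                        brs_gain = draws$brs_gain,
                        mayer_amp = draws$mayer_amp,
                        vlf_amp = draws$vlf_amp)
      if (cond == "free") overrides$resp_rate <- draws$resp_rate_free
      overrides <- utils::modifyList(overrides, list(...))
      subj[[cond]] <- do.call(simulate_recording, overrides)
      manifest[[sidx]] <- data.frame(subject_id = ids[i],
                                     group = groups[i], condition = cond,
                                     seed = seed_c)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        write_recording(subj[[cond]]$recording,
                        file.path(dir, sprintf("rec_%s_%s.csv", ids[i],
                                               cond)))
        utils::write.csv(
          data.frame(beat_time_s = subj[[cond]]$truth$beats),
          file.path(dir, sprintf("truth_beats_%s_%s.csv", ids[i], cond)),
          row.names = FALSE)
      }
    }
    subjects[[ids[i]]] <- subj
  }
  list(subjects = subjects, manifest = do.call(rbind, manifest))
}
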
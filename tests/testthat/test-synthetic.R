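test_that("same seed reproduces a recording exactly", {
  a <- simulate_recording("R1", "CNT", "fast", seed = 5)
  b <- simulate_recording("R1", "CNT", "fast", seed = 5)
  expect_identical(a$recording$channels$ecg$values,
                   b$recording$channels$ecg$values)
  expect_identical(a$truth$beats, b$truth$beats)
  c <- simulate_recording("R1", "CNT", "fast", seed = 6)
  expect_false(identical(a$truth$beats, c$truth$beats))
})

test_that("cohort has the expected cardinality and manifest", {
  coh <- simulate_cohort(n_cnt = 2, n_hf = 2, master_seed = 9,
                         conditions = c("fast", "slow"))
  expect_equal(length(coh$subjects), 4)
  expect_equal(nrow(coh$manifest), 8)
  expect_equal(sort(unique(coh$manifest$group)), c("CNT", "HF"))
  expect_true(all(coh$manifest$seed < 2^31))
})

test_that("noiseless paced respiration recovers rate and levels", {
  p <- sim_params("CNT", "fast", seed = 2, vlf_amp = 0,
                  rsp_noise_sd = 0, tidal_cv = 0)
  r <- simulate_respiration(p)
  bt <- breath_series(r$rsp, segment_breaths(r$rsp))
  mid <- bt[3:(nrow(bt) - 2), ]
  expect_equal(mean(mid$bi), 1 / p$resp_rate, tolerance = 0.01)
  expect_lt(sd(mid$ei_vol), 0.01)
  expect_lt(sd(mid$ee_vol), 0.01)
})

test_that("slow-paced respiration peaks at 0.1 Hz", {
  p <- sim_params("CNT", "slow", seed = 3)
  r <- simulate_respiration(p)
  sp <- welch_psd(decimate_rsp(r$rsp))
  f_peak <- sp$freqs[which.max(sp$psd)]
  expect_gte(f_peak, 0.095)
  expect_lte(f_peak, 0.105)
})

test_that("fixed-point hemodynamics: no drivers, no noise, constant RRI", {
  p <- sim_params("CNT", "fast", seed = 4, brs_gain = 0, mayer_amp = 0,
                  rsa_gain = 0, mech_gain = 0, noise_sbp_sd = 0,
                  noise_rri_sd = 0)
  r <- simulate_respiration(p)
  h <- simulate_hemodynamics(r, p)
  expect_true(all(abs(h$rri$values - p$mean_rri) < 1e-9))
  expect_true(all(abs(h$sbp$values - p$mean_sbp) < 1e-9))
})

test_that("non-physiologic parameter sets are rejected", {
  p <- sim_params("CNT", "fast", seed = 4, mean_rri = 350,
                  mayer_amp = 30, brs_gain = 20)
  r <- simulate_respiration(p)
  expect_error(simulate_hemodynamics(r, p), "non-physiologic")
})

test_that("generator monotonicity on paired seeds", {
  # more Mayer wave -> more SBP LF power
  lf <- vapply(c(1, 6), function(a) {
    pair <- sim_beat_pair(41, condition = "fast", mayer_amp = a)
    standard_band_powers(welch_psd(pair$sbp5))$lf_p
  }, numeric(1))
  expect_gt(lf[2], lf[1])
  # more VLF respiratory modulation -> more normalized RSP VLF power
  vlf <- vapply(c(0.05, 0.3), function(a) {
    p <- sim_params("CNT", "free", seed = 42, vlf_amp = a)
    r <- simulate_respiration(p, seed = 42)
    sp <- normalize_total_power(welch_psd(decimate_rsp(r$rsp)))
    band_power(sp, 0.005, 0.04)
  }, numeric(1))
  expect_gt(vlf[2], vlf[1])
})

test_that("slow breathing inflates measured BRS above the true gain", {
  # respiratory sinus arrhythmia enters the LF band at 6 breaths/min and
  # entrains the transfer estimate: measured BRS exceeds G by design
  brs <- vapply(1:4, function(s) {
    pair <- sim_beat_pair(50 + s, condition = "slow", brs_gain = 5)
    estimate_brs(coherency(pair$sbp5, pair$rri5))$brs
  }, numeric(1))
  expect_gt(mean(brs, na.rm = TRUE), 5)
})

test_that("rendered waveforms close the loop and reject overlaps", {
  p <- sim_params("CNT", "fast", seed = 8, snr_db = Inf)
  r <- simulate_respiration(p)
  h <- simulate_hemodynamics(r, p)
  w1 <- render_waveforms(h$beats, h$sbp, p)
  w2 <- render_waveforms(h$beats, h$sbp, p)
  expect_identical(w1$ecg$values, w2$ecg$values)   # noiseless determinism
  expect_error(render_waveforms(c(1, 1.2), c(120, 120), p),
               "overlapping")
})

test_that("cohort writes readable recordings when dir is given", {
  dir <- withr::local_tempdir()
  simulate_cohort(n_cnt = 1, n_hf = 1, conditions = "slow",
                  master_seed = 10, dir = dir)
  files <- list.files(dir, pattern = "^rec_")
  expect_equal(length(files), 2)
  rec <- read_recording(file.path(dir, files[1]))
  expect_equal(sort(names(rec$channels)), c("ecg", "pressure", "rsp"))
  expect_equal(rec$rate, 200)
})
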
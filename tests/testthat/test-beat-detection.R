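test_that("parabolic refinement matches the exact quadratic fit", {
  # symmetric triple: vertex at the center
  expect_equal(refine_peak_parabolic(1, 2, 1, 200), 0)
  # boundary of a symmetric pair: vertex half a sample right
  expect_equal(refine_peak_parabolic(0, 1, 1, 200), 0.5 / 200)
  # general triple: solve the 3x3 Vandermonde system as the oracle
  y <- c(1, 3, 2)
  co <- solve(cbind(1, c(-1, 0, 1), c(-1, 0, 1)^2), y)
  vertex <- -co[2] / (2 * co[3])
  expect_equal(refine_peak_parabolic(1, 3, 2, 200), vertex / 200)
  # flat triple
  expect_equal(refine_peak_parabolic(2, 2, 2, 200), 0)
  # offsets never exceed half a sample
  for (y3 in list(c(0, 1, 0.999), c(0.2, 0.2001, 0.2)))
    expect_lte(abs(refine_peak_parabolic(y3[1], y3[2], y3[3], 200)),
               0.5 / 200)
})

test_that("periodic noiseless ECG yields exact beats and intervals", {
  beats <- seq(0.5, 59.5, by = 1)
  ecg <- gaussian_ecg(beats, dur = 60)
  ann <- detect_r_peaks(ecg)
  expect_equal(length(ann$r_times), 60)
  rri <- derive_rri(ann)
  expect_equal(length(rri$values), 59)
  expect_equal(rri$values, rep(1000, 59), tolerance = 1e-6)
})

test_that("zero or flat signal gives empty annotation with a warning", {
  z <- uniform_signal(rep(0, 200 * 15), 200)
  expect_warning(ann <- detect_r_peaks(z), "no peak")
  expect_equal(length(ann$r_times), 0)
})

test_that("detection recovers generator beats at 20 dB SNR", {
  sim <- simulate_recording("D1", "CNT", "fast", seed = 11)
  ann <- detect_r_peaks(sim$recording$channels$ecg)
  true_t <- sim$truth$beats
  err <- vapply(true_t, function(tb) min(abs(ann$r_times - tb)),
                numeric(1))
  expect_gte(mean(err <= 0.0025), 0.999)
  expect_lte(max(err), 0.0025)
})

test_that("derive_rri subtracts consecutive beats and skips ectopics", {
  ann <- structure(list(r_times = c(0, 0.8, 1.7),
                        flags = rep("normal", 3)),
                   class = "beat_annotations")
  rri <- derive_rri(ann)
  expect_equal(rri$values, c(800, 900))
  expect_equal(rri$times, c(0.8, 1.7))   # stamped at the later beat
  # flagged middle beat removes both adjacent intervals
  ann$flags[2] <- "ectopic"
  expect_error(derive_rri(ann), "normal beats")
  ann4 <- structure(list(r_times = c(0, 0.8, 1.7, 2.5),
                         flags = c("normal", "ectopic", "normal",
                                   "normal")),
                    class = "beat_annotations")
  rri4 <- derive_rri(ann4)
  expect_equal(rri4$values, 800)         # only the 1.7 -> 2.5 interval
  expect_error(derive_rri(structure(list(r_times = 1,
                                         flags = "normal"),
                                    class = "beat_annotations")))
})

test_that("extract_sbp takes the per-beat maximum of pressure", {
  press <- uniform_signal(rep(100, 200 * 10), 200, "mmHg")
  ann <- structure(list(r_times = c(1, 2, 3), flags = rep("normal", 3)),
                   class = "beat_annotations")
  sbp <- extract_sbp(press, ann)
  expect_equal(sbp$values, c(100, 100))
  ann2 <- structure(list(r_times = c(1, 2), flags = rep("normal", 2)),
                    class = "beat_annotations")
  expect_equal(length(extract_sbp(press, ann2)$values), 1)
  # generator pressure pulses reproduce the per-beat systolic truth
  sim <- simulate_recording("D2", "CNT", "fast", seed = 12)
  beats <- detect_r_peaks(sim$recording$channels$ecg)
  got <- extract_sbp(sim$recording$channels$pressure, beats)
  truth <- sim$truth$sbp
  k <- findInterval(got$times, truth$times)
  expect_lte(max(abs(got$values - truth$values[k])), 0.1)
})

test_that("cleaning removes an injected spike and is a no-op otherwise", {
  set.seed(4)
  tt <- cumsum(rep(0.9, 60))
  v <- 900 + rnorm(60, 0, 10)
  clean <- clean_beat_series(event_series(tt, v, "rri", "ms"))
  expect_equal(attr(clean, "n_edits"), 0)
  expect_equal(clean$values, v)
  v2 <- v; v2[30] <- 300                 # ectopic-like short interval
  fixed <- clean_beat_series(event_series(tt, v2, "rri", "ms"))
  expect_gte(attr(fixed, "n_edits"), 1)
  expect_lte(attr(fixed, "n_edits"), 2)
  expect_gt(min(fixed$values), 700)      # spike replaced by interpolation
  same <- clean_beat_series(event_series(tt, rep(900, 60), "rri", "ms"))
  expect_equal(same$values, rep(900, 60))
  expect_error(clean_beat_series(event_series(1:5, rep(1, 5))), "at least")
})

test_that("running SDNN matches closed forms", {
  tt <- cumsum(rep(0.9, 700))            # ~10.5 min
  expect_equal(sdnn_running(event_series(tt, rep(900, 700), "rri")), 0)
  alt <- rep(c(800, 1000), 350)
  got <- sdnn_running(event_series(tt, alt, "rri"))
  expect_equal(got, 100, tolerance = 0.01)
  # stationary series: running estimate close to full-record SD
  set.seed(9)
  v <- 900 + rnorm(700, 0, 30)
  expect_equal(sdnn_running(event_series(tt, v, "rri")), sd(v),
               tolerance = 0.05)
  # short record falls back with warning
  expect_warning(s <- sdnn_running(event_series(cumsum(rep(0.9, 20)),
                                                rep(c(800, 900), 10),
                                                "rri")),
                 "shorter")
  expect_equal(s, sd(rep(c(800, 900), 10)))
})

test_that("pNN50 counts inclusive 50-ms differences", {
  es <- function(v) event_series(seq_along(v), v, "rri", "ms")
  expect_equal(pnn50(es(c(800, 860, 820, 825))), 1 / 3)
  expect_equal(pnn50(es(seq(800, 1000, by = 10))), 0)
  expect_equal(pnn50(es(800 + c(0, 50, 0, 50, 0))), 1)   # boundary
  expect_error(pnn50(es(800)), "at least 2")
  # invariant to adding a constant
  set.seed(2)
  v <- 900 + cumsum(rnorm(100, 0, 40))
  expect_equal(pnn50(es(v)), pnn50(es(v + 123)))
})
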
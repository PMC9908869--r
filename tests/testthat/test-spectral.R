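test_that("resampling is the identity on an already-uniform grid", {
  tt <- seq(0, 60, by = 0.2)
  v <- rnorm(length(tt))
  out <- resample_uniform(event_series(tt, v), rate = 5)
  expect_equal(out$values, v, tolerance = 1e-9)
})

test_that("spline resampling recovers a sine from beat-like samples", {
  set.seed(7)
  tt <- cumsum(runif(300, 0.8, 1.2))
  es <- event_series(tt, sin(2 * pi * 0.1 * tt))
  out <- resample_uniform(es, rate = 5)
  grid <- tt[1] + (seq_along(out$values) - 1) / 5
  expect_lt(max(abs(out$values - sin(2 * pi * 0.1 * grid))), 0.01)
})

test_that("resampling rejects degenerate inputs", {
  expect_error(resample_uniform(event_series(c(1, 2, 3), 1:3)),
               "at least 4")
  es <- event_series(c(1, 2, 3, 4), 1:4)
  es$times <- c(1, 2, 2, 4)   # bypass constructor to hit the check
  expect_error(resample_uniform(es), "duplicate")
})

test_that("decimation preserves the passband and kills the stopband", {
  tt <- seq(0, 60, by = 1 / 200)
  dc <- decimate_rsp(uniform_signal(rep(2, length(tt)), 200))
  expect_equal(dc$rate, 5)
  expect_equal(dc$values[100], 2, tolerance = 1e-6)
  lo <- decimate_rsp(uniform_signal(sin(2 * pi * 0.1 * tt), 200))
  expect_equal(max(abs(lo$values[50:250])), 1, tolerance = 0.01)
  hi <- decimate_rsp(uniform_signal(sin(2 * pi * 3 * tt), 200))
  expect_lt(mean(hi$values^2) / 0.5, 0.01)
  expect_error(decimate_rsp(uniform_signal(1:100, 150), 4^0.5 * 2),
               "non-integer")
})

test_that("Welch spectrum satisfies the sine Parseval oracle", {
  A <- 3
  x <- sine_signal(0.1, 900, amp = A)
  sp <- welch_psd(x)
  expect_equal(band_power(sp, 0.08, 0.12), A^2 / 2, tolerance = 0.05)
  expect_true(all(sp$psd >= 0))
  expect_equal(sp$freqs[1], 1 / 180, tolerance = 1e-9)
  expect_equal(sp$meta$n_segments, 9)
})

test_that("white-noise total power matches the variance", {
  ratio <- vapply(1:20, function(s) {
    set.seed(s)
    v <- rnorm(4501)
    sp <- welch_psd(uniform_signal(v, 5))
    sp$total_power / var(v)
  }, numeric(1))
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("degenerate Welch inputs behave as declared", {
  z <- welch_psd(uniform_signal(rep(0, 1000), 5))
  expect_true(all(z$psd == 0))
  expect_error(welch_psd(uniform_signal(rnorm(100), 5)), "too short")
})

test_that("band powers land in their bands and never exceed the total", {
  for (case in list(c(0.02, 1), c(0.10, 2), c(0.25, 3))) {
    x <- sine_signal(case[1], 900, amp = 20)
    sp <- welch_psd(x)
    bp <- standard_band_powers(sp)
    target <- c(vlf_p = 0, lf_p = 0, hf_p = 0)
    target[case[2]] <- 200
    expect_equal(bp$vlf_p, target[["vlf_p"]], tolerance = 10)
    expect_equal(bp$lf_p, target[["lf_p"]], tolerance = 10)
    expect_equal(bp$hf_p, target[["hf_p"]], tolerance = 10)
    expect_lte(bp$vlf_p + bp$lf_p + bp$hf_p, sp$total_power * (1 + 1e-9))
  }
  # off-band leakage of a 0.1-Hz line is < 2% of its LF power
  sp <- welch_psd(sine_signal(0.1, 900, amp = 20))
  bp <- standard_band_powers(sp)
  expect_lt(bp$vlf_p, 0.02 * bp$lf_p)
  expect_lt(bp$hf_p, 0.02 * bp$lf_p)
  expect_error(band_power(sp, 3, 4), "outside")
})

test_that("normalization fixes unit total power and keeps band ratios", {
  set.seed(3)
  sp <- welch_psd(uniform_signal(rnorm(2000), 5))
  nm <- normalize_total_power(sp)
  expect_equal(nm$total_power, 1, tolerance = 1e-9)
  nm2 <- normalize_total_power(nm)
  expect_equal(nm2$psd, nm$psd, tolerance = 1e-12)
  r1 <- band_power(sp, 0.04, 0.15) / band_power(sp, 0.15, 0.40)
  r2 <- band_power(nm, 0.04, 0.15) / band_power(nm, 0.15, 0.40)
  expect_equal(r1, r2, tolerance = 1e-12)
  zero <- sp; zero$psd[] <- 0; zero$total_power <- 0
  expect_error(normalize_total_power(zero), "zero-power")
})

test_that("band powers are stable across noise realizations", {
  bp <- vapply(1:4, function(s) {
    pair <- sim_beat_pair(300 + s, condition = "fast")
    standard_band_powers(welch_psd(pair$rri5))$lf_p
  }, numeric(1))
  # same generator conditions, different seeds: spread stays within
  # Monte-Carlo range (no seed gives a qualitatively different spectrum)
  expect_lt(max(bp) / min(bp), 4)
  expect_gt(min(bp), 0)
})
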
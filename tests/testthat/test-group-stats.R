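make_spec <- function(psd, freqs = seq(0.01, 0.5, by = 0.01)) {
  structure(list(freqs = freqs, psd = psd,
                 total_power = sum(psd) * 0.01, meta = list()),
            class = "power_spectrum")
}

test_that("identical groups give t = 0 at all frequencies", {
  set.seed(20)
  base <- lapply(1:4, function(i) make_spec(rexp(50) + 1))
  res <- compare_spectra(base, base, transform = "log")
  expect_true(all(res$t_stat == 0))
  expect_true(all(res$p == 1))
})

test_that("log transform turns a global scale into a constant shift", {
  set.seed(21)
  A <- lapply(1:5, function(i) make_spec(rexp(50) + 1))
  B <- lapply(A, function(s) { s$psd <- s$psd * 4; s })
  res <- compare_spectra(A, B, transform = "log")
  # the log turns the x4 scale into a fixed shift: the sign is uniform
  # and the numerator of every per-frequency t equals -log(4)
  expect_true(all(res$t_stat < 0))
  expect_equal(log(res$meanA) - log(res$meanB), rep(-log(4), 50),
               tolerance = 1e-9)
  # invariance: scaling BOTH groups leaves t untouched
  A2 <- lapply(A, function(s) { s$psd <- s$psd * 17; s })
  B2 <- lapply(B, function(s) { s$psd <- s$psd * 17; s })
  res2 <- compare_spectra(A2, B2, transform = "log")
  expect_equal(res2$t_stat, res$t_stat, tolerance = 1e-9)
  # geometric summaries are exp of log-scale means
  expect_equal(res$meanB / res$meanA, rep(4, 50), tolerance = 1e-9)
})

test_that("coherency spectra use the Fisher z-transform path", {
  set.seed(22)
  mk <- function(k2) structure(list(freqs = seq(0.01, 0.5, by = 0.01),
                                    k2 = k2),
                               class = "coherency_result")
  A <- lapply(1:4, function(i) mk(runif(50, 0.3, 0.5)))
  B <- lapply(1:4, function(i) mk(runif(50, 0.6, 0.8)))
  res <- compare_spectra(A, B, transform = "fisher_z")
  expect_equal(attr(res, "transform"), "fisher_z")
  expect_true(mean(res$t_stat) < 0)      # B more coherent
  expect_equal(length(attr(res, "thresholds")), 2)
})

test_that("zero-variance index gives NA factors and no pairwise tests", {
  d <- expand.grid(subject_id = paste0("s", 1:8),
                   condition = c("free", "fast"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 4,
                    "CNT", "HF")
  d$value <- 5
  res <- compare_indices(d, "flat")
  expect_true(is.na(res$p_condition))
  expect_null(res$pairwise)
})

test_that("injected interaction opens the LSD gate on the right contrast", {
  set.seed(23)
  d <- expand.grid(subject_id = paste0("s", 1:16),
                   condition = c("free", "fast"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 8,
                    "CNT", "HF")
  d$value <- rnorm(nrow(d), 10, 1)
  # condition effect in the HF group only
  sel <- d$group == "HF" & d$condition == "fast"
  d$value[sel] <- d$value[sel] + 4
  res <- compare_indices(d, "injected")
  expect_lt(res$p_interaction, 0.05)
  expect_false(is.null(res$pairwise))
  hfrow <- grep("within HF", res$pairwise$contrast)
  cntrow <- grep("within CNT", res$pairwise$contrast)
  expect_lt(res$pairwise$p[hfrow], 0.05)
  expect_gt(res$pairwise$p[cntrow], 0.05)
})

test_that("non-normal residuals trigger the rank fallback", {
  set.seed(24)
  d <- expand.grid(subject_id = paste0("s", 1:12),
                   condition = c("slow", "fast"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 6,
                    "CNT", "HF")
  d$value <- exp(rnorm(nrow(d), 0, 2)) + c(rep(0, 20), rep(50, 4))
  res <- compare_indices(d, "heavy")
  expect_equal(res$method, "anova_on_ranks")
  expect_lt(res$shapiro_p, 0.05)
})

test_that("LSD contrasts appear only when the trend gate opens", {
  set.seed(25)
  for (i in 1:5) {
    d <- expand.grid(subject_id = paste0("s", 1:10),
                     condition = c("free", "fast"))
    d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 5,
                      "CNT", "HF")
    d$value <- rnorm(nrow(d))
    res <- compare_indices(d, "null")
    ps <- c(res$p_condition, res$p_group, res$p_interaction)
    if (any(!is.na(ps) & ps < 0.10)) expect_false(is.null(res$pairwise))
    else expect_null(res$pairwise)
  }
})

test_that("incomplete subjects are dropped; small groups are an error", {
  d <- expand.grid(subject_id = paste0("s", 1:8),
                   condition = c("free", "fast"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 4,
                    "CNT", "HF")
  set.seed(26)
  d$value <- rnorm(nrow(d))
  d <- d[!(d$subject_id == "s1" & d$condition == "fast"), ]  # incomplete
  res <- compare_indices(d, "drop")
  expect_equal(res$n_subjects, 7)
  expect_error(compare_indices(d[d$subject_id %in%
                                   paste0("s", c(1, 2, 5, 6)), ], "tiny"),
               "3 subjects")
})

test_that("Fisher exact matches a full hypergeometric enumeration", {
  # oracle: P(X <= x or as extreme), X ~ Hypergeom, two-sided by
  # summing all tables with probability <= that of the observed one
  fisher_enum <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    x_obs <- tab[1, 1]
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    sum(probs[probs <= dhyper(x_obs, m, n, k) * (1 + 1e-7)])
  }
  tab <- matrix(c(10, 27, 0, 3), nrow = 2)  # sex split, 10/0 vs 27/3
  df <- data.frame(group = rep(c("CNT", "HF"), c(10, 30)),
                   sex = c(rep("M", 10), rep("M", 27), rep("F", 3)))
  res <- demographics_tests(df)
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$p, fisher_enum(t(matrix(c(0, 10, 3, 27), 2))),
               tolerance = 1e-9)
  # balanced table: p = 1
  df2 <- data.frame(group = rep(c("A", "B"), each = 10),
                    sex = rep(c("M", "F"), 10))
  expect_equal(demographics_tests(df2)$p, 1)
})

test_that("Mann-Whitney p falls monotonically with location shift", {
  set.seed(27)
  base <- rnorm(20)
  ps <- vapply(c(0, 1, 2), function(shift) {
    df <- data.frame(group = rep(c("A", "B"), each = 20),
                     age = c(base, base + shift))
    demographics_tests(df)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(demographics_tests(data.frame(group = rep("A", 5),
                                             age = 1:5)),
               "two non-empty groups")
})
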
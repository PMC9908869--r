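#' Per-frequency group comparison of spectra
#'
#' Compares two groups of spectra line by line with the Student t
#' statistic after a normalizing transform: `log` for power spectra
#' (multiplicative scatter becomes additive) or `fisher_z` for
#' coherency spectra (applied to the coherency modulus `sqrt(k2)`).
#' Group summaries are returned as geometric mean and geometric sem for
#' log-transformed spectra. Per-frequency tests are exploratory: no
#' multiplicity correction is applied, and the 0.05 / 0.01 two-sided t
#' thresholds are returned as reference lines.
#'
#' @param groupA,groupB lists of `power_spectrum` (or `coherency_result`)
#'   objects sharing one frequency grid, >= 2 subjects each.
#' @param transform "log" or "fisher_z".
#' @return data.frame of class `spectra_comparison` with `freq_hz`,
#'   `t_stat`, `p`, group summaries (`meanA`, `semA`, `meanB`, `semB`,
#'   geometric for log); attributes `thresholds` and `transform`.
#' @export
compare_spectra <- function(groupA, groupB,
                            transform = c("log", "fisher_z")) {
  transform <- match.arg(transform)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need at least 2 subjects per group")
  getv <- function(s) if (!is.null(s$psd)) s$psd else sqrt(s$k2)
  f <- groupA[[1]]$freqs
  for (s in c(groupA, groupB))
    if (!isTRUE(all.equal(s$freqs, f))) stop("frequency grid mismatch")
  tr <- function(v) {
    if (transform == "log") log(pmax(v, .Machine$double.xmin))
    else suppressWarnings(fisher_z(pmin(v, 1 - 1e-6)))
  }
  A <- vapply(groupA, function(s) tr(getv(s)), numeric(length(f)))
  B <- vapply(groupB, function(s) tr(getv(s)), numeric(length(f)))
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  tt <- ifelse(sp2 > 0, (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB)), 0)
  df <- nA + nB - 2
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  semA <- sqrt(vA / nA); semB <- sqrt(vB / nB)
  out <- data.frame(freq_hz = f, t_stat = tt, p = p)
  if (transform == "log") {
    out$meanA <- exp(mA); out$semA <- exp(semA)   # geometric mean / sem
    out$meanB <- exp(mB); out$semB <- exp(semB)
  } else {
    out$meanA <- mA; out$semA <- semA
    out$meanB <- mB; out$semB <- semB
  }
  attr(out, "thresholds") <- stats::qt(c(0.975, 0.995), df)
  attr(out, "transform") <- transform
  class(out) <- c("spectra_comparison", class(out))
  out
}

#' Repeated-measures comparison of an index across conditions and groups
#'
#' Two-way repeated-measures ANOVA with the breathing condition as the
#' within-subject factor and the clinical group as the between-subject
#' factor, on complete cases for one condition pair (free vs fast, or
#' slow vs fast). When any factor (condition, group, interaction) shows
#' a trend at p < 0.10, unadjusted pairwise contrasts are emitted in the
#' Least-Significant-Difference style: paired t within each group across
#' conditions, two-sample t between groups within each condition. When a
#' Shapiro-Wilk test rejects normality of the model residuals at
#' p = 0.05, the whole analysis is rerun on ranks ("ANOVA on ranks") and
#' the method is recorded. Power spectra should be passed
#' log-transformed and coherency indices z-transformed by the caller
#' (see `transform`).
#'
#' @param values data.frame with columns `subject_id`, `group`,
#'   `condition`, `value`; exactly two conditions.
#' @param index name of the index (carried into the output).
#' @param transform optional "log" or "fisher_z" applied to `value`
#'   before analysis (default "none").
#' @return object of class `index_comparison`: factor p-values, the
#'   method used ("rm_anova" or "anova_on_ranks"), and `pairwise`
#'   (data.frame, NULL when no factor passed the p < 0.10 gate).
#' @export
compare_indices <- function(values, index = "index",
                            transform = c("none", "log", "fisher_z")) {
  transform <- match.arg(transform)
  req <- c("subject_id", "group", "condition", "value")
  if (!all(req %in% names(values))) stop("values must have columns ",
                                         paste(req, collapse = ", "))
  conds <- unique(values$condition)
  if (length(conds) != 2) stop("exactly two conditions are required")
  # complete cases: subjects with both conditions
  tab <- table(values$subject_id)
  keep <- names(tab)[tab == 2]
  d <- values[values$subject_id %in% keep, ]
  d$value <- switch(transform, none = d$value, log = log(d$value),
                    fisher_z = fisher_z(d$value))
  d$subject_id <- factor(d$subject_id)
  d$group <- factor(d$group)
  d$condition <- factor(d$condition)
  ngrp <- table(unique(d[c("subject_id", "group")])$group)
  if (any(ngrp < 3)) stop("need at least 3 subjects per group")
  fit <- fit_rm_anova(d)
  method <- "rm_anova"
  sw_p <- NA_real_
  if (stats::var(d$value) > 0) {
    # normality is judged on the within-cell scatter (cell-means model)
    resid <- stats::residuals(stats::lm(value ~ group * condition,
                                        data = d))
    if (stats::var(resid) > 0) {
      sw_p <- stats::shapiro.test(resid)$p.value
      if (sw_p < 0.05) {
        d$value <- rank(d$value)
        fit <- fit_rm_anova(d)
        method <- "anova_on_ranks"
      }
    }
  }
  gate <- any(!is.na(unlist(fit)) & unlist(fit) < 0.10)
  pairwise <- NULL
  if (isTRUE(gate)) pairwise <- lsd_contrasts(d)
  structure(list(index = index, p_condition = fit$condition,
                 p_group = fit$group, p_interaction = fit$interaction,
                 method = method, shapiro_p = sw_p,
                 transform = transform, pairwise = pairwise,
                 n_subjects = length(levels(droplevels(d$subject_id)))),
            class = "index_comparison")
}

fit_rm_anova <- function(d) {
  if (stats::var(d$value) == 0)
    return(list(condition = NA_real_, group = NA_real_,
                interaction = NA_real_))
  fit <- stats::aov(value ~ group * condition + Error(subject_id),
                    data = d)
  sm <- summary(fit)
  getp <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- grep(term, trimws(rownames(tab)), fixed = TRUE)
    if (!length(row)) return(NA_real_)
    tab[row[1], "Pr(>F)"]
  }
  list(condition = getp("Error: Within", "condition"),
       group = getp("Error: subject_id", "group"),
       interaction = getp("Error: Within", "group:condition"))
}

lsd_contrasts <- function(d) {
  out <- list()
  for (g in levels(d$group)) {
    dg <- d[d$group == g, ]
    wide <- stats::reshape(dg[c("subject_id", "condition", "value")],
                           idvar = "subject_id", timevar = "condition",
                           direction = "wide")
    cols <- grep("^value\\.", names(wide), value = TRUE)
    if (length(cols) == 2 && nrow(wide) >= 2) {
      dd <- wide[[cols[1]]] - wide[[cols[2]]]
      p <- if (stats::sd(dd) > 0) stats::t.test(dd)$p.value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        contrast = sprintf("%s vs %s within %s",
                           sub("value\\.", "", cols[1]),
                           sub("value\\.", "", cols[2]), g),
        estimate = mean(dd), p = p)
    }
  }
  for (cc in levels(d$condition)) {
    dc <- d[d$condition == cc, ]
    a <- dc$value[dc$group == levels(d$group)[1]]
    b <- dc$value[dc$group == levels(d$group)[2]]
    if (length(a) >= 2 && length(b) >= 2) {
      p <- if (stats::sd(c(a, b)) > 0)
        stats::t.test(a, b, var.equal = TRUE)$p.value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        contrast = sprintf("%s vs %s within %s", levels(d$group)[1],
                           levels(d$group)[2], cc),
        estimate = mean(a) - mean(b), p = p)
    }
  }
  do.call(rbind, out)
}

#' @export
print.index_comparison <- function(x, ...) {
  cat(sprintf("<index_comparison '%s' (%s): p[condition]=%.3g p[group]=%.3g p[interaction]=%.3g>\n",
              x$index, x$method, x$p_condition, x$p_group,
              x$p_interaction))
  if (!is.null(x$pairwise)) {
    cat("  LSD contrasts:\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s: est=%.3g p=%.3g\n", x$pairwise$contrast[i],
                  x$pairwise$estimate[i], x$pairwise$p[i]))
  }
  invisible(x)
}

#' Demographic comparisons between groups
#'
#' Mann-Whitney (Wilcoxon rank-sum) tests for numeric columns and
#' Fisher's exact test for two-level categorical columns, comparing two
#' groups in a general-characteristics table.
#'
#' @param table data.frame with a `group` column and any mix of numeric
#'   and categorical columns.
#' @return data.frame with `variable`, `test`, `p`.
#' @export
demographics_tests <- function(table) {
  if (!"group" %in% names(table)) stop("table must have a `group` column")
  g <- factor(table$group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("need two non-empty groups")
  vars <- setdiff(names(table), "group")
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      p <- stats::wilcox.test(x ~ g, exact = FALSE)$p.value
      data.frame(variable = v, test = "mann_whitney", p = p)
    } else {
      tab <- table(factor(x), g)
      p <- stats::fisher.test(tab)$p.value
      data.frame(variable = v, test = "fisher_exact", p = p)
    }
  })
  do.call(rbind, rows)
}
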
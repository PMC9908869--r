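# Put event series / decimated signals on one shared 5-Hz grid covering
# their common time span (grid aligned to t = 0 so decimated raw-signal
# samples fall exactly on it).
align_on_grid <- function(series_list, rate = 5) {
  spans <- lapply(series_list, function(s) {
    if (inherits(s, "event_series")) range(s$times)
    else c(attr(s, "t0") %||% 0,
           (attr(s, "t0") %||% 0) + (length(s$values) - 1) / s$rate)
  })
  t0 <- max(vapply(spans, `[`, numeric(1), 1))
  t1 <- min(vapply(spans, `[`, numeric(1), 2))
  if (t1 - t0 < 2) stop("signals share less than 2 s")
  grid <- seq(ceiling(t0 * rate) / rate, floor(t1 * rate) / rate,
              by = 1 / rate)
  lapply(series_list, function(s) {
    if (inherits(s, "event_series"))
      resample_uniform(s, rate = rate, grid = grid)
    else {
      st0 <- attr(s, "t0") %||% 0
      idx <- round((grid - st0) * s$rate) + 1L
      out <- uniform_signal(s$values[idx], rate, units = s$units,
                            label = s$label)
      attr(out, "t0") <- grid[1]
      out
    }
  })
}

#' Analyze one recording end to end
#'
#' Runs the full per-subject chain: R-peak detection, RRI/SBP series
#' extraction and cleaning, time-domain indices, breath decomposition,
#' 5-Hz resampling, Welch spectra with band powers (RSP spectrum
#' normalized to unit total power), the three coherency pairs, the
#' band coherency indices and transfer-function BRS. Deterministic
#' given the recording and configuration.
#'
#' @param rec a [recording()] with channels `ecg`, `pressure`, `rsp`.
#' @param config configuration list (see [default_config()]).
#' @return list of class `subject_analysis` with `indices` (named list:
#'   the summary-table row), `spectra`, `coherency`, `series`, `breaths`
#'   and `brs`.
#' @export
analyze_subject <- function(rec, config = default_config()) {
  stopifnot(inherits(rec, "recording"))
  need <- c("ecg", "pressure", "rsp")
  miss <- setdiff(need, names(rec$channels))
  if (length(miss)) stop("channel ", paste(miss, collapse = ", "),
                         " missing")
  wl <- config$welch
  beats <- detect_r_peaks(rec$channels$ecg, config = config)
  if (length(beats$r_times) < 10)
    stop("subject ", rec$subject_id, ": too few beats detected")
  rri <- clean_beat_series(derive_rri(beats), config$cleaning)
  sbp <- clean_beat_series(extract_sbp(rec$channels$pressure, beats),
                           config$cleaning)
  td <- time_domain_indices(rri, sbp, sdnn_window = config$sdnn$window_s)
  bounds <- segment_breaths(rec$channels$rsp, config = config)
  breaths <- breath_series(rec$channels$rsp, bounds)
  rsp5 <- decimate_rsp(rec$channels$rsp, config$sampling$analysis_hz)
  al <- align_on_grid(list(rri = rri, sbp = sbp, rsp = rsp5),
                      rate = config$sampling$analysis_hz)
  spec <- list(
    rri = welch_psd(al$rri, wl$window_s, wl$overlap, wl$smoothing),
    sbp = welch_psd(al$sbp, wl$window_s, wl$overlap, wl$smoothing),
    rsp = normalize_total_power(
      welch_psd(al$rsp, wl$window_s, wl$overlap, wl$smoothing)))
  bp <- lapply(spec, standard_band_powers, bands = config$bands)
  coh <- list(
    sbp_rri = coherency(al$sbp, al$rri, wl$window_s, wl$overlap,
                        wl$smoothing, pair = "SBP-RRI"),
    rsp_rri = coherency(al$rsp, al$rri, wl$window_s, wl$overlap,
                        wl$smoothing, pair = "RSP-RRI"),
    rsp_sbp = coherency(al$rsp, al$sbp, wl$window_s, wl$overlap,
                        wl$smoothing, pair = "RSP-SBP"))
  brs <- estimate_brs(coh$sbp_rri, band = config$bands$lf,
                      gate = config$brs$coherency_gate,
                      gate_value = config$brs$gate_value)
  idx <- list(
    subject_id = rec$subject_id, group = rec$group,
    condition = rec$condition,
    mean_rri = td$mean_rri, mean_sbp = td$mean_sbp,
    sdnn = td$sdnn, pnn50 = td$pnn50,
    rri_vlf_p = bp$rri$vlf_p, rri_lf_p = bp$rri$lf_p,
    rri_hf_p = bp$rri$hf_p,
    sbp_vlf_p = bp$sbp$vlf_p, sbp_lf_p = bp$sbp$lf_p,
    sbp_hf_p = bp$sbp$hf_p,
    rsp_vlf_p = bp$rsp$vlf_p, rsp_lf_p = bp$rsp$lf_p,
    rsp_hf_p = bp$rsp$hf_p,
    mean_bi = mean(breaths$bi, na.rm = TRUE),
    brs = if (brs$defined) brs$brs else NA_real_,
    k_sbp_rri_10s = band_coherency(coh$sbp_rri, "ten_s"),
    k_rsp_rri_25s = band_coherency(coh$rsp_rri, "twenty_five_s"),
    k_rsp_sbp_25s = band_coherency(coh$rsp_sbp, "twenty_five_s"))
  structure(list(indices = idx, spectra = spec, coherency = coh,
                 series = list(rri = rri, sbp = sbp, aligned = al),
                 breaths = breaths, brs = brs),
            class = "subject_analysis")
}

#' Run the full study analysis over a cohort
#'
#' Analyzes every recording, assembles the per-subject index table, and
#' produces the study's comparison outputs: index-level repeated-measures
#' comparisons for the two condition pairings (free vs fast and slow vs
#' fast; never free vs slow), per-frequency group t statistics on the
#' log spectra of each signal for each condition, and (optionally)
#' surrogate-based coherence significance masks per pair and condition.
#' Subjects missing a condition are dropped from the affected
#' comparison only.
#'
#' @param cohort output of [simulate_cohort()] (or a compatible nested
#'   list subject -> condition -> list(recording = ...)), or a directory
#'   of recording files written by it.
#' @param config configuration list.
#' @param surrogate_masks logical; compute surrogate significance masks
#'   (slower; default TRUE).
#' @param surrogate_seed seed for the surrogate generation.
#' @param out_dir optional directory where the index table and
#'   comparison CSVs are written.
#' @return list of class `study_result` with `index_table`,
#'   `index_comparisons`, `spectra_comparisons`, `surrogate_masks`.
#' @export
run_study <- function(cohort, config = default_config(),
                      surrogate_masks = TRUE, surrogate_seed = 1L,
                      out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  subjects <- cohort$subjects
  analyses <- list()
  for (sid in names(subjects)) {
    for (cond in names(subjects[[sid]])) {
      key <- paste(sid, cond, sep = ".")
      analyses[[key]] <- tryCatch(
        analyze_subject(subjects[[sid]][[cond]]$recording, config),
        error = function(e) {
          message("dropping ", sid, "/", cond, ": ", conditionMessage(e))
          NULL
        })
    }
  }
  analyses <- Filter(Negate(is.null), analyses)
  if (!length(analyses)) stop("no subject analyzed successfully")
  index_table <- do.call(rbind, lapply(analyses, function(a)
    as.data.frame(a$indices, stringsAsFactors = FALSE)))
  rownames(index_table) <- NULL
  grp_of <- vapply(analyses, function(a) a$indices$group, character(1))
  if (length(unique(grp_of)) < 2)
    stop("need at least 2 groups in the cohort")
  # index-level comparisons for the two table designs
  pairings <- list(free_vs_fast = c("free", "fast"),
                   slow_vs_fast = c("slow", "fast"))
  log_idx <- c("rri_vlf_p", "rri_lf_p", "rri_hf_p", "sbp_vlf_p",
               "sbp_lf_p", "sbp_hf_p", "rsp_vlf_p", "rsp_lf_p",
               "rsp_hf_p")
  z_idx <- c("k_sbp_rri_10s", "k_rsp_rri_25s", "k_rsp_sbp_25s")
  plain_idx <- c("mean_rri", "mean_sbp", "pnn50", "brs", "mean_bi")
  index_comparisons <- list()
  for (pn in names(pairings)) {
    conds <- pairings[[pn]]
    sub <- index_table[index_table$condition %in% conds, ]
    if (length(unique(sub$condition)) < 2) next
    comp <- list()
    for (ix in c(plain_idx, log_idx, z_idx)) {
      vals <- data.frame(subject_id = sub$subject_id, group = sub$group,
                         condition = sub$condition, value = sub[[ix]])
      vals <- vals[!is.na(vals$value), ]
      tr <- if (ix %in% log_idx) "log"
      else if (ix %in% z_idx) "fisher_z" else "none"
      comp[[ix]] <- tryCatch(
        compare_indices(vals, index = ix, transform = tr),
        error = function(e) NULL)
    }
    index_comparisons[[pn]] <- Filter(Negate(is.null), comp)
  }
  # per-frequency group comparisons of spectra, per condition
  spectra_comparisons <- list()
  conds_present <- unique(vapply(analyses, function(a)
    a$indices$condition, character(1)))
  for (cond in conds_present) {
    sel <- vapply(analyses, function(a)
      a$indices$condition == cond, logical(1))
    cnt <- analyses[sel & grp_of == "CNT"]
    hf <- analyses[sel & grp_of == "HF"]
    if (length(cnt) < 2 || length(hf) < 2) next
    for (sig in c("rri", "sbp", "rsp")) {
      key <- paste(sig, cond, sep = ".")
      spectra_comparisons[[key]] <- tryCatch(
        compare_spectra(lapply(cnt, function(a) a$spectra[[sig]]),
                        lapply(hf, function(a) a$spectra[[sig]]),
                        transform = "log"),
        error = function(e) NULL)
    }
    for (pair in c("sbp_rri", "rsp_rri", "rsp_sbp")) {
      key <- paste(pair, cond, sep = ".")
      spectra_comparisons[[key]] <- tryCatch(
        compare_spectra(lapply(cnt, function(a) a$coherency[[pair]]),
                        lapply(hf, function(a) a$coherency[[pair]]),
                        transform = "fisher_z"),
        error = function(e) NULL)
    }
  }
  masks <- NULL
  if (surrogate_masks)
    masks <- surrogate_masks_for(analyses, config, surrogate_seed)
  res <- structure(list(index_table = index_table,
                        index_comparisons = index_comparisons,
                        spectra_comparisons = spectra_comparisons,
                        surrogate_masks = masks),
                   class = "study_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_indices_table(split(index_table, seq_len(nrow(index_table))),
                        file.path(out_dir, "index_table.csv"))
    for (key in names(spectra_comparisons))
      utils::write.csv(spectra_comparisons[[key]],
                       file.path(out_dir, paste0("compare_", key, ".csv")),
                       row.names = FALSE)
    if (!is.null(masks))
      for (key in names(masks))
        utils::write.csv(masks[[key]],
                         file.path(out_dir, paste0("mask_", key, ".csv")),
                         row.names = FALSE)
  }
  res
}

# surrogate coherence masks per signal pair and condition: one surrogate
# per subject per channel, coherency recomputed with identical settings
surrogate_masks_for <- function(analyses, config, seed) {
  wl <- config$welch
  conds <- unique(vapply(analyses, function(a) a$indices$condition,
                         character(1)))
  pairs <- list(sbp_rri = c("sbp", "rri"), rsp_rri = c("rsp", "rri"),
                rsp_sbp = c("rsp", "sbp"))
  masks <- list()
  for (cond in conds) {
    sel <- Filter(function(a) a$indices$condition == cond, analyses)
    if (length(sel) < 3) next
    for (pn in names(pairs)) {
      ch <- pairs[[pn]]
      orig <- lapply(sel, function(a) a$coherency[[pn]])
      surr <- lapply(seq_along(sel), function(i) {
        al <- sel[[i]]$series$aligned
        sx <- make_surrogate(al[[ch[1]]],
                             seed = derive_seed(seed, i * 13 + 1),
                             max_iter = config$surrogate$max_iter,
                             tol = config$surrogate$spectrum_tol)
        sy <- make_surrogate(al[[ch[2]]],
                             seed = derive_seed(seed, i * 13 + 2),
                             max_iter = config$surrogate$max_iter,
                             tol = config$surrogate$spectrum_tol)
        coherency(sx, sy, wl$window_s, wl$overlap, wl$smoothing,
                  pair = pn)
      })
      masks[[paste(pn, cond, sep = ".")]] <-
        coherence_vs_surrogate_test(orig, surr)
    }
  }
  masks
}

read_cohort_dir <- function(dir) {
  files <- list.files(dir, pattern = "^rec_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no recording files in ", dir)
  subjects <- list()
  for (f in files) {
    rec <- read_recording(f)
    subjects[[rec$subject_id]][[rec$condition]] <- list(recording = rec)
  }
  list(subjects = subjects)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d subject-condition rows, %d index comparisons, %d spectra comparisons>\n",
              nrow(x$index_table),
              sum(lengths(x$index_comparisons)),
              length(x$spectra_comparisons)))
  invisible(x)
}
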
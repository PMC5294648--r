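#' End-to-end analysis of a cohort
#'
#' Orchestrates the full workflow on a cohort of trial power tables:
#' per-subject trial equalization, time-delayed cross-frequency and
#' within-frequency networks, bipartite filtration (barcodes per partition,
#' single-linkage matrices), the Wilcoxon network-type contrast, the
#' barcode-level and elementwise SLM condition permutation tests, the
#' good/poor group permutation test, and behavior correlations
#' (Bonferroni-corrected over the flagged pairs) for instruction compliance
#' and memory performance.
#'
#' @param cohort An `xf_cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param n_perm_barcode,n_perm_slm,n_perm_group Permutation iteration counts
#'   (paper defaults 200, 5000, 5000).
#' @param alpha Per-pair significance level for the elementwise tests
#'   (paper default 0.0005).
#' @param m_tests Bonferroni family size for behavior correlations; `NULL`
#'   uses the number of flagged pairs.
#' @param seed Integer seed driving every random draw.
#' @param verbose 0 (quiet), 1 (stage progress), 2 (adds permutation
#'   progress every 10%).
#' @return A list of result records (see details in the README) of class
#'   `xf_analysis`.
#' @export
analyze_cohort <- function(cohort, n_perm_barcode = 200, n_perm_slm = 5000,
                           n_perm_group = 5000, alpha = 0.0005,
                           m_tests = NULL, seed = 1, verbose = 0) {
  t0 <- proc.time()[["elapsed"]]
  subjects <- .cohort_subjects(cohort)
  ns <- length(subjects)
  say <- function(lvl, fmt, ...) {
    if (verbose >= lvl)
      message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0),
              sprintf(fmt, ...))
  }
  for (sub in subjects) {
    miss <- setdiff(c("ca_R", "ig_R", "ca_NR", "ig_NR"), names(sub))
    if (length(miss))
      .xfnet_error(sprintf("subject %s: missing band-epoch table(s) %s",
                           sub$subject_id, paste(miss, collapse = ", ")),
                   "xfnet_error_io")
  }

  say(1, "network-type contrast (cross- vs within-frequency, Wilcoxon)")
  set.seed(.subseed(seed, 0L))
  p <- ncol(subjects[[1]]$ca_R)
  wt_dm <- list(cue_alpha = list(R = numeric(ns), NR = numeric(ns)),
                item_gamma = list(R = numeric(ns), NR = numeric(ns)))
  for (s in seq_len(ns)) {
    sub <- subjects[[s]]
    nR <- nrow(sub$ca_R); nNR <- nrow(sub$ca_NR); n <- min(nR, nNR)
    idx <- list(R = .equalize_idx(nR, n), NR = .equalize_idx(nNR, n))
    for (cond in c("R", "NR")) {
      ca <- sub[[paste0("ca_", cond)]][idx[[cond]], , drop = FALSE]
      ig <- sub[[paste0("ig_", cond)]][idx[[cond]], , drop = FALSE]
      k <- .subject_kernel(ca, ig)
      for (part in c("cue_alpha", "item_gamma")) {
        cross <- .new_betti_curve(.deaths_for(k, part), p, part)
        wf <- filtrate(within_frequency_distance(
          if (part == "cue_alpha") ca else ig))
        within <- partition_betti_curve(wf, "all")
        wt_dm[[part]][[cond]][s] <- diff_max(cross, within)$value
      }
    }
  }
  network_type <- list()
  for (part in c("cue_alpha", "item_gamma")) for (cond in c("R", "NR")) {
    network_type[[paste(part, cond, sep = "_")]] <-
      if (ns >= 5) network_type_contrast(wt_dm[[part]][[cond]])
      else list(statistic = NA_real_, p_value = NA_real_,
                note = "skipped: fewer than 5 subjects")
  }

  say(1, "barcode condition permutation (%d iterations)", n_perm_barcode)
  barcode_tests <- list(
    cue_alpha = barcode_condition_permutation(subjects, "cue_alpha",
                                              n_perm_barcode, seed),
    item_gamma = barcode_condition_permutation(subjects, "item_gamma",
                                               n_perm_barcode, seed))

  say(1, "elementwise SLM condition permutation (%d iterations)", n_perm_slm)
  slm_test <- slm_condition_permutation(subjects, n_perm_slm, alpha, seed)

  say(1, "group permutation (%d iterations)", n_perm_group)
  groups <- cohort$behavior$performer_group
  group_test <- if (length(unique(groups)) == 2) {
    group_permutation(slm_test$diffs, groups, n_perm_group, alpha, seed)
  } else NULL

  say(1, "behavior correlations")
  compliance <- cohort$behavior$compliance
  memory <- cohort$behavior$memory_performance
  flagged <- slm_test$pairs
  m <- if (is.null(m_tests)) max(1, nrow(flagged)) else m_tests
  labs <- colnames(subjects[[1]]$ca_R)
  if (is.null(labs)) labs <- paste0("V", seq_len(p))
  behavior_cors <- NULL
  if (nrow(flagged) > 0 && ns >= 4) {
    rows <- lapply(seq_len(nrow(flagged)), function(k) {
      i <- match(flagged$cue_roi[k], labs); j <- match(flagged$item_roi[k], labs)
      v <- slm_test$diffs[, i, j]
      cc <- tryCatch(behavior_correlation(v, compliance, m), error = function(e) NULL)
      cm <- tryCatch(behavior_correlation(v, memory, m), error = function(e) NULL)
      data.frame(cue_roi = flagged$cue_roi[k], item_roi = flagged$item_roi[k],
                 r_compliance = if (is.null(cc)) NA else cc$r,
                 p_compliance = if (is.null(cc)) NA else cc$p,
                 p_compliance_bonf = if (is.null(cc)) NA else cc$p_bonferroni,
                 r_memory = if (is.null(cm)) NA else cm$r,
                 p_memory = if (is.null(cm)) NA else cm$p,
                 p_memory_bonf = if (is.null(cm)) NA else cm$p_bonferroni,
                 stringsAsFactors = FALSE)
    })
    behavior_cors <- do.call(rbind, rows)
  }

  # diff_max between conditions vs compliance, per partition
  dm_cors <- list()
  for (part in c("cue_alpha", "item_gamma")) {
    v <- barcode_tests[[part]]$subject_diffmax
    dm_cors[[part]] <- if (ns >= 4 && stats::sd(v) > 0 && stats::sd(compliance) > 0)
      behavior_correlation(v, compliance, 1) else NULL
  }

  say(1, "done")
  structure(list(network_type = network_type,
                 barcode_tests = barcode_tests,
                 slm_test = slm_test,
                 group_test = group_test,
                 behavior_correlations = behavior_cors,
                 diffmax_compliance = dm_cors,
                 alpha = alpha, seed = seed, n_subjects = ns),
            class = "xf_analysis")
}

#' Write an analysis results bundle
#'
#' Emits `results.json` (all test records) and `pair_table.tsv`, a
#' human-readable table of the flagged regional pairs with their mean
#' condition difference, standard error, range, t value and behavior
#' correlations.
#'
#' @param res An `xf_analysis` from [analyze_cohort()].
#' @param out_dir Output directory (created if needed).
#' @export
write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- res$slm_test$pairs
  if (!is.null(res$behavior_correlations) && nrow(tab) > 0) {
    tab <- merge(tab, res$behavior_correlations,
                 by = c("cue_roi", "item_roi"), sort = FALSE)
  }
  write.table(tab, file.path(out_dir, "pair_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rec <- list(
    n_subjects = res$n_subjects, alpha = res$alpha, seed = res$seed,
    network_type = res$network_type,
    barcode_tests = lapply(res$barcode_tests, function(x)
      list(partition = x$partition, observed_t = x$observed_stat,
           p_value = x$p_value, n_perm = x$n_perm)),
    slm_flagged_pairs = res$slm_test$pairs,
    group_flagged_pairs = if (!is.null(res$group_test)) res$group_test$pairs else NULL,
    behavior_correlations = res$behavior_correlations,
    diffmax_compliance = res$diffmax_compliance)
  jsonlite::write_json(rec, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.xf_analysis <- function(x, ...) {
  cat("cross-frequency network analysis:", x$n_subjects, "subjects\n")
  for (nm in names(x$barcode_tests))
    cat(sprintf("  barcode permutation (%s): t = %.3f, p = %.4g\n", nm,
                x$barcode_tests[[nm]]$observed_stat,
                x$barcode_tests[[nm]]$p_value))
  cat(sprintf("  SLM pairs flagged at alpha = %g: %d\n", x$alpha,
              nrow(x$slm_test$pairs)))
  invisible(x)
}
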
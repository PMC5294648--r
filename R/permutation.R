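#' @title Trial-relabeling and group-relabeling permutation tests
#' @description
#' All engines share the same null construction: within every subject the
#' trials of both conditions are pooled and randomly re-split into
#' pseudo-conditions of the original sizes, the full observed pipeline
#' (trial equalization, correlation, negative-distance transform, filtration)
#' is re-run on the pseudo-data, and the statistic is recomputed. P-values
#' use the add-one estimator `p = (1 + #{|t_null| >= |t_obs|}) / (1 + n_perm)`
#' so p is always in `(0, 1]`, and all tests are two-sided on the absolute
#' statistic. Trial equalization is re-applied inside every iteration with an
#' iteration-derived sub-seed so that the null mirrors the observed pipeline
#' exactly.
#' @name permutation
NULL

# iteration-derived sub-seed; keeps every derived seed below 2^31
.subseed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483629) + 1L
}

# Subject record normalization: each subject is a list with matrices
# ca_R, ig_R, ca_NR, ig_NR (trials x p, same ROI order across all four).
.cohort_subjects <- function(cohort) {
  if (inherits(cohort, "xf_cohort")) return(cohort$subjects)
  cohort
}

# lean product-moment correlation for the hot loop; zero-variance columns
# yield NaN, which .negdist maps to the non-edge sentinel like stats::cor NA
.fast_cor <- function(x, y) {
  n <- nrow(x)
  x <- x - rep(colMeans(x), each = n)
  y <- y - rep(colMeans(y), each = n)
  crossprod(x, y) / tcrossprod(sqrt(colSums(x * x)), sqrt(colSums(y * y)))
}

# per-subject pipeline: equalized tables -> bipartite kernel output
.subject_kernel <- function(ca, ig) {
  .filt_core_cpp(.negdist(.fast_cor(ca, ig)), TRUE)
}

# equalize (joint across band epochs), then kernels for both conditions
.subject_pair_kernels <- function(sub) {
  nR <- nrow(sub$ca_R); nNR <- nrow(sub$ca_NR)
  n <- min(nR, nNR)
  iR <- .equalize_idx(nR, n); iNR <- .equalize_idx(nNR, n)
  list(R = .subject_kernel(sub$ca_R[iR, , drop = FALSE],
                           sub$ig_R[iR, , drop = FALSE]),
       NR = .subject_kernel(sub$ca_NR[iNR, , drop = FALSE],
                            sub$ig_NR[iNR, , drop = FALSE]))
}

# pooled trial store, built once per engine run (cue-alpha and item-gamma
# rows of a condition are the same trials, so one index permutes both)
.subject_pool <- function(sub) {
  list(ca = rbind(sub$ca_R, sub$ca_NR), ig = rbind(sub$ig_R, sub$ig_NR),
       nR = nrow(sub$ca_R), nTot = nrow(sub$ca_R) + nrow(sub$ca_NR))
}

# one pseudo-condition iteration: re-split sizes preserved, trial counts
# re-equalized, both condition kernels computed
.pool_pair_kernels <- function(pool) {
  n <- min(pool$nR, pool$nTot - pool$nR)
  perm <- sample.int(pool$nTot)
  iR <- perm[seq_len(pool$nR)]; iNR <- perm[-seq_len(pool$nR)]
  iR <- iR[.equalize_idx(length(iR), n)]
  iNR <- iNR[.equalize_idx(length(iNR), n)]
  list(R = .subject_kernel(pool$ca[iR, , drop = FALSE],
                           pool$ig[iR, , drop = FALSE]),
       NR = .subject_kernel(pool$ca[iNR, , drop = FALSE],
                            pool$ig[iNR, , drop = FALSE]))
}

.deaths_for <- function(kern, partition) {
  if (partition == "cue_alpha") kern$deaths_x else kern$deaths_y
}

#' Barcode-level condition permutation test
#'
#' Observed statistic: the one-sample t statistic, across subjects, of the
#' per-subject `diff_max` between the Remember and No-Remember Betti-0 curves
#' of the chosen partition. Null distribution: in every iteration each
#' subject's R and NR trials are pooled and randomly re-split into
#' pseudo-conditions of the original sizes, and the t statistic is recomputed
#' end to end.
#'
#' @param cohort An `xf_cohort` (see [generate_cohort()]) or a bare list of
#'   subjects, each a list of matrices `ca_R`, `ig_R`, `ca_NR`, `ig_NR`
#'   (trials x ROI; cue-alpha and item-gamma rows of a condition are the same
#'   trials).
#' @param partition `"cue_alpha"` or `"item_gamma"`.
#' @param n_perm Number of permutation iterations (paper default 200).
#' @param seed Integer seed; drives the observed equalization draw and every
#'   iteration's re-split and re-equalization.
#' @return A `permutation_result`: `observed_stat`, `null_stats`, `p_value`,
#'   `n_perm`, `seed`, `sidedness`, `partition`, and the per-subject observed
#'   `diff_max` values (`subject_diffmax`).
#' @export
barcode_condition_permutation <- function(cohort,
                                          partition = c("cue_alpha", "item_gamma"),
                                          n_perm = 200, seed = 1) {
  partition <- match.arg(partition)
  subjects <- .cohort_subjects(cohort)
  ns <- length(subjects)
  if (ns < 3)
    .xfnet_error("need at least 3 subjects", "xfnet_error_n")
  p <- ncol(subjects[[1]]$ca_R)

  set.seed(.subseed(seed, 0L))
  obs_dm <- vapply(subjects, function(sub) {
    k <- .subject_pair_kernels(sub)
    .diffmax_value(.deaths_for(k$R, partition), .deaths_for(k$NR, partition), p)
  }, numeric(1))
  t_obs <- .tstat(obs_dm)

  pools <- lapply(subjects, .subject_pool)
  t_null <- numeric(n_perm)
  dm <- numeric(ns)
  for (it in seq_len(n_perm)) {
    set.seed(.subseed(seed, it))
    for (s in seq_len(ns)) {
      k <- .pool_pair_kernels(pools[[s]])
      dm[s] <- .diffmax_value(.deaths_for(k$R, partition),
                              .deaths_for(k$NR, partition), p)
    }
    t_null[it] <- .tstat(dm)
  }
  p_value <- (1 + sum(abs(t_null) >= abs(t_obs))) / (1 + n_perm)
  structure(list(observed_stat = t_obs, null_stats = t_null, p_value = p_value,
                 n_perm = n_perm, seed = seed, sidedness = "two_sided",
                 partition = partition, subject_diffmax = obs_dm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed t = %.4g, p = %.4g (%d iterations, seed %d)\n",
              if (!is.null(x$partition)) x$partition else "elementwise",
              x$observed_stat, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

# observed per-subject SLM pair and condition difference array
.observed_slm <- function(subjects, seed) {
  set.seed(.subseed(seed, 0L))
  lapply(subjects, function(sub) {
    k <- .subject_pair_kernels(sub)
    list(R = k$R$slm, NR = k$NR$slm)
  })
}

#' Observed paired-t statistics over the single-linkage matrices
#'
#' Computes, without any permutation, the per-subject single-linkage matrices
#' of both conditions (after trial equalization), their condition differences
#' `SLM_R - SLM_NR`, and the elementwise paired t statistic across subjects.
#' This is the observed half of [slm_condition_permutation()], exposed
#' separately because effect ranking and behavior correlations only need the
#' observed statistics.
#'
#' @inheritParams barcode_condition_permutation
#' @return A list with `t_matrix`, `mean_diff`, `se` (all p x p, labeled when
#'   the cohort carries ROI labels) and `diffs` (subjects x p x p array).
#' @export
slm_condition_stats <- function(cohort, seed = 1) {
  subjects <- .cohort_subjects(cohort)
  ns <- length(subjects)
  p <- ncol(subjects[[1]]$ca_R)
  labs <- colnames(subjects[[1]]$ca_R)
  obs <- .observed_slm(subjects, seed)
  Dm <- t(vapply(obs, function(o) as.vector(o$R - o$NR), numeric(p * p)))
  t_obs <- matrix(.tstat_cols(Dm), p, p)
  mean_diff <- matrix(colMeans(Dm), p, p)
  se <- matrix(sqrt(apply(Dm, 2, stats::var) / ns), p, p)
  diffs <- array(Dm, dim = c(ns, p, p))
  if (!is.null(labs)) {
    dimnames(t_obs) <- dimnames(mean_diff) <- dimnames(se) <- list(labs, labs)
  }
  list(t_matrix = t_obs, mean_diff = mean_diff, se = se, diffs = diffs)
}

.pair_table <- function(p_mat, t_mat, mean_diff, se, diffs, alpha,
                        row_labels, col_labels) {
  sig <- which(p_mat < alpha, arr.ind = TRUE)
  if (nrow(sig) == 0) {
    return(data.frame(cue_roi = character(0), item_roi = character(0),
                      mean_diff = numeric(0), se = numeric(0),
                      range_min = numeric(0), range_max = numeric(0),
                      t = numeric(0), p = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    cue_roi = row_labels[sig[, 1]],
    item_roi = col_labels[sig[, 2]],
    mean_diff = mean_diff[sig],
    se = se[sig],
    range_min = apply(sig, 1, function(ij) min(diffs[, ij[1], ij[2]])),
    range_max = apply(sig, 1, function(ij) max(diffs[, ij[1], ij[2]])),
    t = t_mat[sig],
    p = p_mat[sig],
    stringsAsFactors = FALSE)
  df$direction <- ifelse(df$mean_diff < 0, "R < NR", "R > NR")
  df[order(-abs(df$t)), , drop = FALSE]
}

#' Elementwise SLM condition permutation test
#'
#' For every (cue-alpha ROI, item-gamma ROI) pair, the paired t statistic
#' across subjects of `SLM_R - SLM_NR` is compared with a null built by the
#' same trial-relabeling scheme as [barcode_condition_permutation()]:
#' per iteration every subject's trials are pooled, re-split and the
#' single-linkage matrices recomputed. Elementwise two-sided p-values carry
#' no multiple-comparison correction (the design tests at a conservative
#' per-pair alpha instead). Flagged pairs are tagged `"R < NR"` (stronger
#' negative coupling under Remember) or `"R > NR"`.
#'
#' @inheritParams barcode_condition_permutation
#' @param n_perm Number of iterations (paper default 5000).
#' @param alpha Per-pair significance level (paper default 0.0005).
#' @return A list with `p_matrix`, `t_matrix`, `mean_diff`, `se`,
#'   `pairs` (data frame of flagged pairs mirroring the report table),
#'   `diffs`, `n_perm`, `alpha`, `seed`.
#' @export
slm_condition_permutation <- function(cohort, n_perm = 5000, alpha = 0.0005,
                                      seed = 1) {
  subjects <- .cohort_subjects(cohort)
  ns <- length(subjects)
  if (ns < 3)
    .xfnet_error("need at least 3 subjects", "xfnet_error_n")
  p <- ncol(subjects[[1]]$ca_R)
  labs <- colnames(subjects[[1]]$ca_R)
  if (is.null(labs)) labs <- paste0("V", seq_len(p))

  st <- slm_condition_stats(subjects, seed)
  t_obs <- as.vector(st$t_matrix)

  pools <- lapply(subjects, .subject_pool)
  exceed <- integer(p * p)
  Dm <- matrix(0, ns, p * p)
  for (it in seq_len(n_perm)) {
    set.seed(.subseed(seed, it))
    for (s in seq_len(ns)) {
      k <- .pool_pair_kernels(pools[[s]])
      Dm[s, ] <- k$R$slm - k$NR$slm
    }
    exceed <- exceed + (abs(.tstat_cols(Dm)) >= abs(t_obs))
  }
  p_mat <- matrix((1 + exceed) / (1 + n_perm), p, p,
                  dimnames = list(labs, labs))
  pairs <- .pair_table(p_mat, st$t_matrix, st$mean_diff, st$se, st$diffs,
                       alpha, labs, labs)
  list(p_matrix = p_mat, t_matrix = st$t_matrix, mean_diff = st$mean_diff,
       se = st$se, pairs = pairs, diffs = st$diffs,
       n_perm = n_perm, alpha = alpha, seed = seed)
}

#' Good/poor performer group permutation test
#'
#' Observed statistic per (i, j): difference between group means of the
#' per-subject SLM condition differences `(SLM_R - SLM_NR)[i, j]`. The null
#' permutes subject group labels, preserving group sizes. Elementwise
#' two-sided p-values with add-one smoothing.
#'
#' @param per_subject_condition_diffs List of p x p matrices (one per
#'   subject, `SLM_R - SLM_NR`), or the `diffs` array from
#'   [slm_condition_stats()].
#' @param groups Character/factor vector per subject: `"good"` or `"poor"`;
#'   both groups must be non-empty.
#' @inheritParams slm_condition_permutation
#' @return A list with `p_matrix`, `stat_matrix` (good minus poor),
#'   `pairs`, `n_perm`, `alpha`, `seed`.
#' @export
group_permutation <- function(per_subject_condition_diffs, groups,
                              n_perm = 5000, alpha = 0.0005, seed = 1) {
  if (is.array(per_subject_condition_diffs) &&
      length(dim(per_subject_condition_diffs)) == 3) {
    a <- per_subject_condition_diffs
    ns <- dim(a)[1]; p <- dim(a)[2]
    G <- matrix(a, ns, p * p)
    labs <- dimnames(a)[[2]]
  } else {
    mats <- per_subject_condition_diffs
    ns <- length(mats); p <- nrow(mats[[1]])
    G <- t(vapply(mats, as.vector, numeric(p * p)))
    labs <- rownames(mats[[1]])
  }
  if (is.null(labs)) labs <- paste0("V", seq_len(p))
  groups <- as.character(groups)
  if (length(groups) != ns)
    .xfnet_error("one group label per subject required", "xfnet_error_n")
  good <- groups == "good"
  if (!any(good) || all(good))
    .xfnet_error("both groups must be non-empty", "xfnet_error_groups")

  stat <- colMeans(G[good, , drop = FALSE]) - colMeans(G[!good, , drop = FALSE])
  set.seed(.subseed(seed, 0L))
  exceed <- integer(p * p)
  for (it in seq_len(n_perm)) {
    pg <- sample(good)
    s <- colMeans(G[pg, , drop = FALSE]) - colMeans(G[!pg, , drop = FALSE])
    exceed <- exceed + (abs(s) >= abs(stat))
  }
  p_mat <- matrix((1 + exceed) / (1 + n_perm), p, p,
                  dimnames = list(labs, labs))
  stat_mat <- matrix(stat, p, p, dimnames = list(labs, labs))
  sig <- which(p_mat < alpha, arr.ind = TRUE)
  pairs <- if (nrow(sig)) {
    df <- data.frame(cue_roi = labs[sig[, 1]], item_roi = labs[sig[, 2]],
                     group_diff = stat_mat[sig], p = p_mat[sig],
                     stringsAsFactors = FALSE)
    df[order(-abs(df$group_diff)), , drop = FALSE]
  } else {
    data.frame(cue_roi = character(0), item_roi = character(0),
               group_diff = numeric(0), p = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(p_matrix = p_mat, stat_matrix = stat_mat, pairs = pairs,
       n_perm = n_perm, alpha = alpha, seed = seed)
}
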
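#' Simulation configuration for synthetic cohorts
#'
#' Describes a desk-scale cohort of trial-level ROI power tables with known
#' planted structure. Cue-alpha powers are independent Gaussians around
#' per-ROI baselines; at each planted (cue ROI, item ROI) pair the item-gamma
#' column is generated with an exact planted Pearson correlation
#' `gamma <= 0` (drawn per subject and condition around the configured
#' coupling with `subject_coupling_sd` jitter), emulating the negative
#' cue-alpha -> item-gamma coupling that gates memory encoding. Behavioral
#' hit/false-alarm counts are drawn binomially from rates tied to a latent
#' compliance ability linearly linked (`behavior_link_slope`) to the
#' subject's coupling contrast, so stronger Remember-condition coupling
#' implies higher compliance.
#'
#' @param n_subjects Number of subjects (study scale: 23).
#' @param n_rois Number of ROIs; labels are taken from the head of
#'   `roi_labels` (default: the packaged 76-label cortical node set).
#' @param trials_per_condition Named pair `c(R = , NR = )`; slightly unequal
#'   by default (190/200) to exercise trial equalization, mimicking
#'   per-condition artifact rejection.
#' @param planted_pairs Data frame with columns `cue_roi`, `item_roi`,
#'   `coupling_R`, `coupling_NR` (couplings in `[-1, 0]`). Default: one pair,
#'   left superior occipital (cue-alpha) to left superior frontal
#'   (item-gamma), `-0.6` under R versus `-0.1` under NR. Item ROIs must be
#'   distinct across pairs so each planted correlation is exact.
#' @param subject_coupling_sd Per-subject jitter of the planted couplings.
#' @param behavior_link_slope Maps the per-subject coupling contrast
#'   `gamma_NR - gamma_R` to the latent compliance d-prime.
#' @param group_effect Extra R-condition negative coupling (magnitude) for
#'   latent-good subjects at the planted pairs; 0 disables the
#'   group x condition interaction.
#' @param noise_sd Trial-to-trial power noise (normalized-power units).
#' @param baseline_mean,baseline_sd Mean and spread of the per-ROI baseline
#'   normalized power (dimensionless ratio versus the inter-trial interval;
#'   centered at 1).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param roi_labels Optional explicit label vector (length >= n_rois).
#' @param shared_subject_jitter If `TRUE`, each subject's coupling jitter is
#'   drawn once and applied to both conditions, so conditions with equal
#'   configured couplings are exchangeable at trial level. [null_cohort()]
#'   switches this on.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 23,
                              n_rois = 76,
                              trials_per_condition = c(R = 190, NR = 200),
                              planted_pairs = NULL,
                              subject_coupling_sd = 0.1,
                              behavior_link_slope = 1.2,
                              group_effect = 0,
                              noise_sd = 0.25,
                              baseline_mean = 1,
                              baseline_sd = 0.2,
                              seed = 1,
                              roi_labels = NULL,
                              shared_subject_jitter = FALSE) {
  if (is.null(roi_labels)) roi_labels <- roi_node_set()$labels
  if (n_rois > length(roi_labels))
    .xfnet_error("n_rois exceeds the available ROI labels", "xfnet_error_config")
  labels <- roi_labels[seq_len(n_rois)]
  if (is.null(planted_pairs)) {
    planted_pairs <- if (all(c("Occipital_Sup.L", "Frontal_Sup.L") %in% labels)) {
      data.frame(cue_roi = "Occipital_Sup.L", item_roi = "Frontal_Sup.L",
                 coupling_R = -0.6, coupling_NR = -0.1,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cue_roi = labels[1], item_roi = labels[2],
                 coupling_R = -0.6, coupling_NR = -0.1,
                 stringsAsFactors = FALSE)
    }
  }
  if (length(trials_per_condition) != 2)
    .xfnet_error("trials_per_condition must be a pair", "xfnet_error_config")
  if (is.null(names(trials_per_condition)))
    names(trials_per_condition) <- c("R", "NR")
  if (any(trials_per_condition < 10))
    .xfnet_error("need at least 10 trials per condition", "xfnet_error_config")
  if (nrow(planted_pairs) > 0) {
    if (!all(planted_pairs$cue_roi %in% labels) ||
        !all(planted_pairs$item_roi %in% labels))
      .xfnet_error("planted ROI names must come from the node set",
                   "xfnet_error_config")
    if (anyDuplicated(planted_pairs$item_roi))
      .xfnet_error("planted item ROIs must be distinct", "xfnet_error_config")
    cps <- c(planted_pairs$coupling_R, planted_pairs$coupling_NR)
    if (any(cps < -1 | cps > 0))
      .xfnet_error("couplings must lie in [-1, 0]", "xfnet_error_config")
  }
  structure(list(n_subjects = n_subjects, n_rois = n_rois,
                 trials_per_condition = trials_per_condition,
                 planted_pairs = planted_pairs,
                 subject_coupling_sd = subject_coupling_sd,
                 behavior_link_slope = behavior_link_slope,
                 group_effect = group_effect,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed), roi_labels = labels,
                 shared_subject_jitter = isTRUE(shared_subject_jitter)),
            class = "simulation_config")
}

#' Generate a synthetic cohort with planted couplings
#'
#' Produces per-subject trial power tables for both conditions and both
#' band-epochs, behavioral records (hit/false-alarm counts, derived d-prime
#' compliance and memory-performance scores, good/poor split at memory
#' performance 1.0), and a ground-truth manifest recording every latent draw.
#'
#' Generative model, per subject s and condition c: cue-alpha powers are
#' `x_i = mu_i + noise_sd * z`, independent across ROIs and trials. At a
#' planted pair (i, j) the item-gamma column is
#' `y_j = nu_j + noise_sd * (gamma_sc * z_i + sqrt(1 - gamma_sc^2) * w_j)`
#' with `gamma_sc` the per-subject coupling, so the population Pearson
#' correlation between `x_i` and `y_j` equals `gamma_sc` exactly; unplanted
#' item-gamma columns are independent noise. Behavioral counts: the latent
#' compliance ability is `behavior_link_slope * (gamma_NR - gamma_R)` (mean
#' over planted pairs) plus noise, shifting the R-hit rate above the NR-hit
#' rate; the latent memory ability sets the false-alarm rate. Defaults are
#' calibrated so the mean R-hit, NR-hit and false-alarm ratios sit near 57%,
#' 33% and 24%.
#'
#' @param config A [simulation_config()].
#' @return An `xf_cohort`: list with `subjects` (per subject: matrices
#'   `ca_R`, `ig_R`, `ca_NR`, `ig_NR`), `behavior` (data frame of
#'   `BehavioralRecord` fields), `manifest` (latent ground truth) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    .xfnet_error("config must be a simulation_config", "xfnet_error_config")
  set.seed(config$seed)
  p <- config$n_rois
  labels <- config$roi_labels
  ns <- config$n_subjects
  nR <- config$trials_per_condition[["R"]]
  nNR <- config$trials_per_condition[["NR"]]
  pp <- config$planted_pairs
  npp <- nrow(pp)
  ci <- match(pp$cue_roi, labels)
  ii <- match(pp$item_roi, labels)

  # recognition-session trial totals (study scale: 200 per class)
  n_recog <- 200L

  subjects <- vector("list", ns)
  beh <- vector("list", ns)
  man_gamma_R <- matrix(NA_real_, ns, max(npp, 1))
  man_gamma_NR <- matrix(NA_real_, ns, max(npp, 1))
  m_lat <- a_lat <- numeric(ns)
  designated_good <- logical(ns)

  for (s in seq_len(ns)) {
    sid <- sprintf("S%02d", s)
    mu_ca <- rnorm(p, config$baseline_mean, config$baseline_sd)
    mu_ig <- rnorm(p, config$baseline_mean, config$baseline_sd)

    # latent memory ability (d-prime scale); good subjects get the extra
    # R-condition coupling when a group effect is configured
    m_lat[s] <- rnorm(1, 0.9, 0.45)
    designated_good[s] <- m_lat[s] > 1.0

    gR <- gNR <- numeric(npp)
    if (npp > 0) {
      extra <- if (designated_good[s]) config$group_effect else 0
      jit_R <- rnorm(npp, 0, config$subject_coupling_sd)
      jit_NR <- if (config$shared_subject_jitter) jit_R
                else rnorm(npp, 0, config$subject_coupling_sd)
      gR <- pmin(0, pmax(-0.99, pp$coupling_R - extra + jit_R))
      gNR <- pmin(0, pmax(-0.99, pp$coupling_NR + jit_NR))
      man_gamma_R[s, seq_len(npp)] <- gR
      man_gamma_NR[s, seq_len(npp)] <- gNR
    }

    gen_cond <- function(n, gamma) {
      Z <- matrix(rnorm(n * p), n, p)
      W <- matrix(rnorm(n * p), n, p)
      ca <- sweep(config$noise_sd * Z, 2, mu_ca, "+")
      igz <- W
      if (npp > 0) {
        for (k in seq_len(npp)) {
          igz[, ii[k]] <- gamma[k] * Z[, ci[k]] +
            sqrt(1 - gamma[k]^2) * W[, ii[k]]
        }
      }
      ig <- sweep(config$noise_sd * igz, 2, mu_ig, "+")
      colnames(ca) <- colnames(ig) <- labels
      list(ca = ca, ig = ig)
    }
    cR <- gen_cond(nR, gR)
    cNR <- gen_cond(nNR, gNR)

    # behavioral link: coupling contrast -> latent compliance d-prime
    contrast <- if (npp > 0) mean(gNR - gR) else 0
    a_lat[s] <- config$behavior_link_slope * contrast + rnorm(1, 0, 0.25)
    z_nr <- qnorm(0.33)
    z_r <- z_nr + a_lat[s]
    z_fa <- z_r - m_lat[s]
    r_hits <- rbinom(1, n_recog, pnorm(z_r))
    nr_hits <- rbinom(1, n_recog, pnorm(z_nr))
    fas <- rbinom(1, n_recog, pnorm(z_fa))
    compliance <- dprime(r_hits, n_recog, nr_hits, n_recog)
    memory <- dprime(r_hits, n_recog, fas, n_recog)

    subjects[[s]] <- list(subject_id = sid,
                          ca_R = cR$ca, ig_R = cR$ig,
                          ca_NR = cNR$ca, ig_NR = cNR$ig)
    beh[[s]] <- data.frame(subject_id = sid,
                           r_hits = r_hits, r_trials = n_recog,
                           nr_hits = nr_hits, nr_trials = n_recog,
                           false_alarms = fas, new_trials = n_recog,
                           compliance = compliance,
                           memory_performance = memory,
                           performer_group = if (memory > 1.0) "good" else "poor",
                           stringsAsFactors = FALSE)
  }
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  behavior <- do.call(rbind, beh)
  manifest <- list(seed = config$seed,
                   planted_pairs = pp,
                   gamma_R = man_gamma_R, gamma_NR = man_gamma_NR,
                   latent_memory = m_lat, latent_compliance = a_lat,
                   designated_good = designated_good)
  structure(list(subjects = subjects, behavior = behavior,
                 manifest = manifest, config = config),
            class = "xf_cohort")
}

#' @export
print.xf_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, %d ROIs, trials R/NR = %d/%d, %d planted pair(s)\n",
              x$config$n_subjects, x$config$n_rois,
              x$config$trials_per_condition[["R"]],
              x$config$trials_per_condition[["NR"]],
              nrow(x$config$planted_pairs)))
  invisible(x)
}

#' Null cohort for type-I calibration
#'
#' A cohort in which the Remember and No-Remember conditions are exchangeable
#' by construction: every planted pair gets the same coupling in both
#' conditions (the configured `coupling_R`, with one shared per-subject
#' jitter draw) and the group effect is disabled.
#'
#' @inheritParams generate_cohort
#' @export
null_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    .xfnet_error("config must be a simulation_config", "xfnet_error_config")
  if (nrow(config$planted_pairs) > 0)
    config$planted_pairs$coupling_NR <- config$planted_pairs$coupling_R
  config$group_effect <- 0
  config$shared_subject_jitter <- TRUE
  generate_cohort(config)
}
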
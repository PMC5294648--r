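test_that("generate_cohort is deterministic and shapes are right", {
  cfg <- simulation_config(n_subjects = 4, n_rois = 6,
                           trials_per_condition = c(R = 20, NR = 24), seed = 13)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$behavior, c2$behavior)
  expect_length(c1$subjects, 4)
  sub <- c1$subjects[[1]]
  expect_equal(dim(sub$ca_R), c(20, 6))
  expect_equal(dim(sub$ig_NR), c(24, 6))
  expect_equal(colnames(sub$ca_R), cfg$roi_labels)
  # behavioral invariants
  b <- c1$behavior
  expect_true(all(b$r_hits <= b$r_trials & b$false_alarms <= b$new_trials))
  expect_identical(b$performer_group, ifelse(b$memory_performance > 1, "good", "poor"))
})

test_that("planted couplings surface as empirical correlations, unplanted stay at noise level", {
  cfg <- simulation_config(n_subjects = 6, n_rois = 6,
                           trials_per_condition = c(R = 200, NR = 200),
                           planted_pairs = data.frame(
                             cue_roi = "Precentral.L", item_roi = "Frontal_Sup.R",
                             coupling_R = -0.9, coupling_NR = 0,
                             stringsAsFactors = FALSE),
                           subject_coupling_sd = 0.02, seed = 29)
  coh <- generate_cohort(cfg)
  i <- match("Precentral.L", cfg$roi_labels)
  j <- match("Frontal_Sup.R", cfg$roi_labels)
  rs <- vapply(coh$subjects, function(s) cor(s$ca_R[, i], s$ig_R[, j]), 0)
  expect_true(all(rs < -0.7))
  # unplanted entries: mean |r| within the sampling-noise bound 2/sqrt(n)
  other <- vapply(coh$subjects, function(s) {
    r <- cor(s$ca_NR, s$ig_NR)
    mean(abs(r))
  }, 0)
  expect_true(mean(other) <= 2 / sqrt(200))
})

test_that("null_cohort makes conditions exchangeable and passes zero-coupling checks", {
  cfg <- simulation_config(n_subjects = 5, n_rois = 5,
                           trials_per_condition = c(R = 40, NR = 40),
                           planted_pairs = data.frame(
                             cue_roi = "Precentral.L", item_roi = "Precentral.R",
                             coupling_R = -0.4, coupling_NR = -0.9,
                             stringsAsFactors = FALSE), seed = 31)
  nc <- null_cohort(cfg)
  # per-subject couplings equal across conditions
  expect_equal(nc$manifest$gamma_R, nc$manifest$gamma_NR)
  expect_true(all(nc$manifest$gamma_R <= 0))
  # no behavioral link under the null: latent compliance is pure noise around 0
  expect_lt(abs(mean(nc$manifest$latent_compliance)), 0.5)
})

test_that("behavioral link ties the coupling contrast to compliance with the configured sign", {
  cfg <- simulation_config(n_subjects = 40, n_rois = 4,
                           trials_per_condition = c(R = 20, NR = 20),
                           planted_pairs = data.frame(
                             cue_roi = "Precentral.L", item_roi = "Precentral.R",
                             coupling_R = -0.6, coupling_NR = -0.1,
                             stringsAsFactors = FALSE),
                           subject_coupling_sd = 0.15, seed = 37)
  coh <- generate_cohort(cfg)
  contrast <- coh$manifest$gamma_NR[, 1] - coh$manifest$gamma_R[, 1]
  # stronger R coupling (larger contrast) -> higher realized compliance
  expect_gt(cor(contrast, coh$behavior$compliance), 0)
})

test_that("config validation rejects bad inputs", {
  expect_error(simulation_config(trials_per_condition = c(R = 5, NR = 20)),
               class = "xfnet_error_config")
  expect_error(simulation_config(planted_pairs = data.frame(
    cue_roi = "NotARegion.L", item_roi = "Precentral.R",
    coupling_R = -0.5, coupling_NR = -0.1)), class = "xfnet_error_config")
  expect_error(simulation_config(planted_pairs = data.frame(
    cue_roi = "Precentral.L", item_roi = "Precentral.R",
    coupling_R = 0.5, coupling_NR = -0.1)), class = "xfnet_error_config")
})
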
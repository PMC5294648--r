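test_that("permutation engines are reproducible and respect the p floor", {
  coh <- tiny_cohort(seed = 9)
  r1 <- barcode_condition_permutation(coh, "item_gamma", n_perm = 40, seed = 5)
  r2 <- barcode_condition_permutation(coh, "item_gamma", n_perm = 40, seed = 5)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 41)
  expect_lte(r1$p_value, 1)
  expect_length(r1$null_stats, 40)

  s1 <- slm_condition_permutation(coh, n_perm = 30, alpha = 0.05, seed = 5)
  s2 <- slm_condition_permutation(coh, n_perm = 30, alpha = 0.05, seed = 5)
  expect_identical(s1$p_matrix, s2$p_matrix)
  expect_true(all(s1$p_matrix >= 1 / 31))
})

test_that("identical trials across conditions give null statistics and p = 1", {
  coh <- tiny_cohort(n_subjects = 4, seed = 3)
  for (s in seq_along(coh$subjects)) {
    coh$subjects[[s]]$ca_NR <- coh$subjects[[s]]$ca_R
    coh$subjects[[s]]$ig_NR <- coh$subjects[[s]]$ig_R
  }
  pb <- barcode_condition_permutation(coh, "cue_alpha", n_perm = 25, seed = 2)
  expect_true(all(pb$subject_diffmax == 0))
  expect_equal(pb$observed_stat, 0)
  expect_equal(pb$p_value, 1)

  ps <- slm_condition_permutation(coh, n_perm = 25, alpha = 0.05, seed = 2)
  expect_true(all(ps$t_matrix == 0))
  expect_equal(nrow(ps$pairs), 0)
})

test_that("a strongly planted pair is recovered with the R < NR tag", {
  coh <- tiny_cohort(n_subjects = 10, n_rois = 5, trials = c(R = 60, NR = 66),
                     coupling_R = -0.8, coupling_NR = -0.05, seed = 21)
  st <- slm_condition_stats(coh, seed = 4)
  top <- which(abs(st$t_matrix) == max(abs(st$t_matrix)), arr.ind = TRUE)[1, ]
  expect_equal(rownames(st$t_matrix)[top[1]], "Frontal_Sup.L")
  expect_equal(colnames(st$t_matrix)[top[2]], "Precentral.R")
  ps <- slm_condition_permutation(coh, n_perm = 60, alpha = 0.05, seed = 4)
  expect_true(any(ps$pairs$cue_roi == "Frontal_Sup.L" &
                  ps$pairs$item_roi == "Precentral.R"))
  hit <- ps$pairs[ps$pairs$cue_roi == "Frontal_Sup.L" &
                  ps$pairs$item_roi == "Precentral.R", ]
  expect_equal(hit$direction, "R < NR")
  expect_lt(hit$mean_diff, 0)
})

test_that("group_permutation: identical groups give p = 1, planted contrast is found", {
  set.seed(77)
  p <- 4
  base <- lapply(1:8, function(i) matrix(rnorm(p * p, 0, 0.05), p, p))
  # identical groups: duplicate subjects, observed stat exactly 0
  mats <- c(base, base)
  groups <- rep(c("good", "poor"), each = 8)
  g0 <- group_permutation(mats, groups, n_perm = 50, alpha = 0.05, seed = 1)
  expect_true(all(g0$stat_matrix == 0))
  expect_true(all(g0$p_matrix == 1))

  # planted group difference at entry (2, 3)
  mats2 <- lapply(seq_along(mats), function(i) {
    m <- matrix(rnorm(p * p, 0, 0.05), p, p)
    if (groups[i] == "good") m[2, 3] <- m[2, 3] - 0.8
    m
  })
  g1 <- group_permutation(mats2, groups, n_perm = 400, alpha = 0.01, seed = 2)
  expect_equal(unname(which(g1$p_matrix == min(g1$p_matrix), arr.ind = TRUE)[1, ]),
               c(2, 3))
  expect_error(group_permutation(mats2, rep("good", 16), n_perm = 10),
               class = "xfnet_error_groups")
})

test_that("group_permutation calibrates at the nominal level under a null", {
  set.seed(99)
  nrep <- 150
  rej <- 0
  for (r in seq_len(nrep)) {
    mats <- lapply(1:10, function(i) matrix(rnorm(9), 3, 3))
    g <- group_permutation(mats, rep(c("good", "poor"), 5),
                           n_perm = 99, alpha = 0.05, seed = r)
    rej <- rej + (g$p_matrix[1, 1] <= 0.05)
  }
  ci <- qbinom(c(0.025, 0.975), nrep, 0.05)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})
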
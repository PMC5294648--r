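make_tpt <- function(values, labels = paste0("ROI", seq_len(ncol(values)), ".L"),
                     condition = "R", band = "cue_alpha") {
  trial_power_table(values, labels, "S01", condition, band)
}

test_that("equalize_trials keeps the smaller table byte-identical and subsamples the larger", {
  set.seed(1)
  a <- make_tpt(matrix(rnorm(200 * 4), 200, 4))
  b <- make_tpt(matrix(rnorm(195 * 4), 195, 4), condition = "NR")
  eq <- equalize_trials(a, b, seed = 7)
  expect_identical(eq$b, b)
  expect_equal(nrow(eq$a$values), 195)
  # every kept row appears verbatim in the input, in preserved order
  kept <- match(apply(eq$a$values, 1, paste, collapse = ","),
                apply(a$values, 1, paste, collapse = ","))
  expect_false(anyNA(kept))
  expect_true(all(diff(kept) > 0))

  # equal counts: identity
  eq2 <- equalize_trials(a, make_tpt(matrix(rnorm(200 * 4), 200, 4), condition = "NR"),
                         seed = 3)
  expect_identical(eq2$a, a)

  # reproducibility under a fixed seed
  a5 <- make_tpt(matrix(rnorm(5 * 3), 5, 3))
  b3 <- make_tpt(matrix(rnorm(3 * 3), 3, 3), condition = "NR")
  r1 <- equalize_trials(a5, b3, seed = 11)
  r2 <- equalize_trials(a5, b3, seed = 11)
  expect_identical(r1, r2)
})

test_that("equalize_trials errors are labeled", {
  a <- make_tpt(matrix(rnorm(12), 4, 3))
  b <- make_tpt(matrix(rnorm(12), 4, 3), labels = c("X.L", "Y.L", "Z.L"))
  expect_error(equalize_trials(a, b, 1), class = "xfnet_error_labels")
  expect_error(
    trial_power_table(matrix(rnorm(6), 2, 3), paste0("R", 1:3)),
    class = "xfnet_error_table")
})

test_that("pearson_matrix matches hand-computed values and flags zero variance", {
  x <- make_tpt(cbind(a = c(1, 2, 3)))
  y <- make_tpt(cbind(b = c(3, 1, 2)), band = "item_gamma")
  r <- pearson_matrix(x, y)
  expect_equal(unname(r[1, 1]), -0.5)

  # perfect anticorrelation
  x2 <- make_tpt(cbind(c(1, 4, 2, 5)))
  y2 <- make_tpt(cbind(-c(1, 4, 2, 5)), band = "item_gamma")
  expect_equal(unname(pearson_matrix(x2, y2)[1, 1]), -1)

  # constant column -> undefined, reported, not substituted
  yc <- make_tpt(cbind(k = c(2, 2, 2, 2)), band = "item_gamma")
  expect_warning(rc <- pearson_matrix(x2, yc), "undefined")
  expect_true(is.na(rc[1, 1]))
  expect_equal(nrow(attr(rc, "undefined")), 1)
})

test_that("pearson_matrix transpose symmetry gives transposed bipartite distances", {
  set.seed(5)
  x <- make_tpt(matrix(rnorm(40), 10, 4))
  y <- make_tpt(matrix(rnorm(40), 10, 4), band = "item_gamma")
  rxy <- pearson_matrix(x, y)
  ryx <- pearson_matrix(y, x)
  expect_equal(unclass(rxy), t(unclass(ryx)), ignore_attr = TRUE)
  Dxy <- negative_distance(rxy)
  Dyx <- negative_distance(ryx)
  expect_equal(Dxy$D, t(Dyx$D), ignore_attr = TRUE)
})

test_that("negative_distance implements the negative-only transform", {
  r <- matrix(c(-1, 0.8, -0.5, 0), 2, 2)
  d <- negative_distance(r)$D
  expect_equal(as.vector(d), c(0, 1, 0.5, 1))
  expect_true(all(d >= 0 & d <= 1))

  # monotone non-increasing in |r| on the negative branch
  rs <- sort(runif(25, -1, 0))
  ds <- as.vector(negative_distance(matrix(rs, 5, 5))$D)
  expect_true(all(diff(ds) >= 0))

  # undefined policy
  rn <- matrix(c(-0.2, NA, -0.5, 0.3), 2, 2)
  expect_equal(as.vector(negative_distance(rn)$D), c(0.8, 1, 0.5, 1))
  expect_error(negative_distance(rn, "strict"), class = "xfnet_error_undefined")
})

test_that("within_frequency_distance composes pearson + transform with unit diagonal", {
  set.seed(9)
  x <- make_tpt(matrix(rnorm(60, 1, 0.3), 15, 4))
  wd <- within_frequency_distance(x)
  expect_s3_class(wd, "symmetric_dist")
  ref <- negative_distance(suppressWarnings(pearson_matrix(x, x)))$D
  diag(ref) <- 1
  expect_equal(wd$D, ref, ignore_attr = TRUE)
  expect_true(all(diag(wd$D) == 1))
  expect_equal(wd$D, t(wd$D))

  # exact anticorrelation between two columns -> distance 0, symmetric
  v <- rnorm(10)
  x2 <- make_tpt(cbind(v, -v, rnorm(10)))
  wd2 <- within_frequency_distance(x2)
  expect_equal(unname(wd2$D[1, 2]), 0)
  expect_equal(unname(wd2$D[2, 1]), 0)

  # mutually positively correlated columns -> empty network
  base <- rnorm(12)
  x3 <- make_tpt(cbind(base + rnorm(12, 0, 0.01), base + rnorm(12, 0, 0.01),
                       base + rnorm(12, 0, 0.01)))
  expect_true(all(within_frequency_distance(x3)$D == 1))
})
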
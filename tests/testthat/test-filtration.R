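# Hand-worked 2x2 fixture used throughout: rows cue-alpha (x1, x2),
# columns item-gamma (y1, y2); edges x1-y1 = 0.2, x2-y1 = 0.9, x2-y2 = 0.4,
# x1-y2 = 1 (non-edge).
fixture_D <- function() bipartite_dist(matrix(c(0.2, 0.9, 1.0, 0.4), 2, 2))

test_that("filtrate records the hand-derived merge sequence", {
  f <- filtrate(fixture_D())
  expect_equal(f$events$epsilon, c(0.2, 0.4, 0.9))
  # members of the final merge cover all four nodes
  expect_length(f$events$members[[3]], 4)
  # all-ones matrix: empty filtration
  f0 <- filtrate(bipartite_dist(matrix(1, 3, 3)))
  expect_equal(nrow(f0$events), 0)
  expect_equal(betti_at(partition_betti_curve(f0, "cue_alpha"), 0.5), 3)
})

test_that("event count equals node count minus final component count", {
  set.seed(101)
  for (rep in 1:30) {
    p <- sample(2:6, 1)
    D <- random_bipartite_D(p, runif(1, 0.2, 0.8))
    f <- filtrate(bipartite_dist(D))
    final <- oracle_beta0(D, 1, "all")
    expect_equal(nrow(f$events), 2 * p - final)
  }
})

test_that("partition Betti curves match the fixture and flood-fill recounts", {
  f <- filtrate(fixture_D())
  ca <- partition_betti_curve(f, "cue_alpha")
  expect_equal(betti_at(ca, c(0, 0.5, 0.89, 0.9, 1)), c(2, 2, 2, 1, 1))
  ig <- partition_betti_curve(f, "item_gamma")
  # the 0.4 merge joins y2 with the singleton x2, so both projected
  # item-gamma classes persist until the 0.9 merge
  expect_equal(betti_at(ig, c(0, 0.3, 0.4, 0.9)), c(2, 2, 2, 1))
  expect_error(partition_betti_curve(f, "bogus"), class = "xfnet_error_partition")

  set.seed(202)
  for (rep in 1:20) {
    p <- sample(2:5, 1)
    D <- random_bipartite_D(p, runif(1, 0.3, 0.9))
    f <- filtrate(bipartite_dist(D))
    eps_grid <- c(0, sort(unique(D[D < 1])), 0.999)
    for (part in c("cue_alpha", "item_gamma", "all")) {
      curve <- partition_betti_curve(f, part)
      expect_equal(betti_at(curve, eps_grid),
                   vapply(eps_grid, oracle_beta0, 0L, D = D, partition = part),
                   ignore_attr = TRUE)
      expect_true(all(diff(curve$counts) <= 0))
    }
  }
})

test_that("barcode has one bar per partition node and is consistent with the curve", {
  f <- filtrate(fixture_D())
  bc <- barcode(f, "cue_alpha")
  expect_equal(bc$bars$death, c(0.9, 1))
  expect_equal(bc$bars$censored, c(FALSE, TRUE))

  set.seed(303)
  for (rep in 1:15) {
    p <- sample(2:6, 1)
    D <- random_bipartite_D(p, runif(1, 0.2, 0.8))
    f <- filtrate(bipartite_dist(D))
    for (part in c("cue_alpha", "item_gamma")) {
      bc <- barcode(f, part)
      curve <- partition_betti_curve(f, part)
      expect_equal(nrow(bc$bars), p)
      # deaths (uncensored) are exactly the curve's drop points with multiplicity
      expect_equal(sort(bc$bars$death[!bc$bars$censored]), curve$deaths)
      # beta0 recoverable from the barcode: bars alive strictly past eps
      for (eps in c(0, curve$breakpoints))
        expect_equal(sum(bc$bars$death > eps) + 0, betti_at(curve, eps))
    }
  }
})

test_that("single-linkage matrix equals the fixture and respects its bounds", {
  f <- filtrate(fixture_D())
  expect_equal(unname(single_linkage_matrix(f)),
               matrix(c(0.2, 0.9, 0.9, 0.4), 2, 2))
  set.seed(404)
  for (rep in 1:25) {
    p <- sample(2:6, 1)
    D <- random_bipartite_D(p, runif(1, 0.2, 0.6))
    slm <- single_linkage_matrix(filtrate(bipartite_dist(D)))
    expect_true(all(slm <= D + 1e-12))
    # lower bound: the cheapest edge incident to either endpoint
    for (i in seq_len(p)) for (j in seq_len(p)) {
      lb <- min(c(D[i, ], D[, j]))
      if (slm[i, j] < 1) expect_gte(slm[i, j], lb)
    }
  }
})

test_that("projected ultrametrics are exact ultrametrics consistent with dendrograms", {
  f <- filtrate(fixture_D())
  u <- projected_ultrametric(f, "cue_alpha")
  expect_equal(unname(u), matrix(c(0, 0.9, 0.9, 0), 2, 2))
  hc <- sl_dendrogram(u)
  expect_equal(hc$height, 0.9)
  expect_equal(unname(as.matrix(stats::cophenetic(hc))), unname(u))

  # singleton partition
  f1 <- filtrate(bipartite_dist(matrix(0.3, 1, 1)))
  expect_equal(unname(projected_ultrametric(f1, "cue_alpha")), matrix(0, 1, 1))

  set.seed(505)
  for (rep in 1:15) {
    p <- sample(2:6, 1)
    D <- random_bipartite_D(p, runif(1, 0.3, 0.8))
    f <- filtrate(bipartite_dist(D))
    for (part in c("cue_alpha", "item_gamma")) {
      u <- projected_ultrametric(f, part)
      expect_equal(u, t(u))
      expect_true(all(diag(u) == 0))
      # exact ultrametric inequality
      for (k in seq_len(p))
        expect_true(all(u <= outer(u[, k], u[k, ], pmax) + 1e-12))
      # dendrogram merge heights reproduce the partition barcode deaths
      hc <- sl_dendrogram(u)
      deaths <- barcode(f, part)$bars$death
      expect_equal(sort(hc$height), sort(deaths[-length(deaths)]))
    }
  }
})

test_that("combined first-connection matrix is ultrametric over all 2p nodes", {
  set.seed(606)
  for (rep in 1:10) {
    p <- sample(2:5, 1)
    D <- random_bipartite_D(p, runif(1, 0.3, 0.7))
    f <- filtrate(bipartite_dist(D))
    M <- rbind(cbind(projected_ultrametric(f, "cue_alpha"), single_linkage_matrix(f)),
               cbind(t(single_linkage_matrix(f)), projected_ultrametric(f, "item_gamma")))
    for (k in seq_len(2 * p))
      expect_true(all(M <= outer(M[, k], M[k, ], pmax) + 1e-12))
  }
})

test_that("sl_dendrogram rejects non-ultrametric input", {
  bad <- matrix(c(0, 0.2, 0.9, 0.2, 0, 0.3, 0.9, 0.3, 0), 3, 3)
  expect_error(sl_dendrogram(bad), class = "xfnet_error_ultrametric")
})

test_that("symmetric filtration reduces to textbook single-linkage clustering", {
  set.seed(707)
  for (rep in 1:10) {
    p <- sample(3:8, 1)
    pts <- matrix(rnorm(2 * p), p)
    D0 <- as.matrix(dist(pts))
    D0 <- D0 / (1.1 * max(D0))
    sd_ <- symmetric_dist(D0)
    f <- filtrate(sd_)
    hc_ref <- stats::hclust(as.dist(D0), method = "single")
    expect_equal(sort(f$events$epsilon), sort(hc_ref$height))
    U <- projected_ultrametric(f, "all")
    expect_equal(unname(U), unname(as.matrix(stats::cophenetic(hc_ref))))
    # cophenetic round trip through our own tree builder
    expect_equal(unname(as.matrix(stats::cophenetic(sl_dendrogram(U)))),
                 unname(U))
  }
})

test_that("nestedness: component partitions refine as epsilon grows", {
  set.seed(808)
  D <- random_bipartite_D(5, 0.5)
  f <- filtrate(bipartite_dist(D))
  eps <- sort(unique(D[D < 1]))
  for (k in seq_along(eps)[-1]) {
    b_small <- oracle_beta0(D, eps[k - 1], "all")
    b_big <- oracle_beta0(D, eps[k], "all")
    expect_lte(b_big, b_small)
  }
})
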
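# Independent brute-force oracles. These deliberately share no code with the
# package: minimax distances come from exhaustive simple-path enumeration,
# component counts from flood fill on explicitly thresholded graphs.

# random bipartite distance matrix; density kept low for larger p so the
# path enumeration stays exhaustive yet fast
random_bipartite_D <- function(p, edge_prob) {
  D <- matrix(1, p, p)
  e <- matrix(stats::runif(p * p) < edge_prob, p, p)
  D[e] <- round(stats::runif(sum(e), 0.01, 0.95), 3)
  D
}

# all-simple-paths minimax over the 2p-node bipartite graph; entries are 1
# when no path below 1 exists
oracle_minimax <- function(D) {
  p <- nrow(D); n <- 2L * p
  W <- matrix(Inf, n, n)
  for (i in seq_len(p)) for (j in seq_len(p))
    if (D[i, j] < 1) W[i, p + j] <- W[p + j, i] <- D[i, j]
  adj <- lapply(seq_len(n), function(v) which(is.finite(W[v, ])))
  best <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    visited <- logical(n); visited[src] <- TRUE
    dfs <- function(v, mx) {
      for (u in adj[[v]]) if (!visited[u]) {
        m2 <- max(mx, W[v, u])
        if (m2 < best[src, u]) best[src, u] <<- m2
        visited[u] <<- TRUE
        dfs(u, m2)
        visited[u] <<- FALSE
      }
    }
    dfs(src, 0)
  }
  out <- best[seq_len(p), p + seq_len(p), drop = FALSE]
  out[!is.finite(out)] <- 1
  out
}

# flood-fill component labels of a logical adjacency matrix
oracle_components <- function(A) {
  n <- nrow(A); comp <- integer(n); cc <- 0L
  for (v in seq_len(n)) if (comp[v] == 0L) {
    cc <- cc + 1L
    stack <- v; comp[v] <- cc
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      nb <- which(A[x, ] & comp == 0L)
      comp[nb] <- cc
      stack <- c(stack, nb)
    }
  }
  comp
}

# partition-projected Betti-0 of a bipartite matrix at threshold eps
# (edge iff d <= eps and d < 1)
oracle_beta0 <- function(D, eps, partition) {
  p <- nrow(D); n <- 2L * p
  A <- matrix(FALSE, n, n)
  for (i in seq_len(p)) for (j in seq_len(p))
    if (D[i, j] < 1 && D[i, j] <= eps) A[i, p + j] <- A[p + j, i] <- TRUE
  comp <- oracle_components(A)
  idx <- switch(partition,
                cue_alpha = seq_len(p),
                item_gamma = p + seq_len(p),
                all = seq_len(n))
  length(unique(comp[idx]))
}

# small helper cohort for engine tests
tiny_cohort <- function(n_subjects = 6, n_rois = 5, trials = c(R = 24, NR = 28),
                        coupling_R = -0.7, coupling_NR = -0.1, seed = 42) {
  cfg <- simulation_config(
    n_subjects = n_subjects, n_rois = n_rois, trials_per_condition = trials,
    planted_pairs = data.frame(cue_roi = "Frontal_Sup.L", item_roi = "Precentral.R",
                               coupling_R = coupling_R, coupling_NR = coupling_NR,
                               stringsAsFactors = FALSE),
    seed = seed)
  generate_cohort(cfg)
}
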
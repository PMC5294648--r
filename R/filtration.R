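#' Graph filtration of a distance matrix
#'
#' Sweeps the distance threshold epsilon upward from 0 over a weighted graph:
#' two nodes are linked at epsilon iff their distance d satisfies d <= epsilon
#' (closed threshold). Distance 1 is the non-edge sentinel — it marks
#' non-negative or undefined couplings — so the filtration domain is `[0, 1)`
#' and weight-1 entries are never processed. Every merge of two connected
#' components is recorded with its filtration value; equal edge weights are
#' processed in a fixed row-major order (ties cannot change component counts
#' or single-linkage values, only event bookkeeping).
#'
#' For a `bipartite_dist` the graph has `2p` nodes (cue-alpha partition plus
#' item-gamma partition, edges only between partitions); for a
#' `symmetric_dist` it has `p` nodes.
#'
#' @param D A `bipartite_dist` or `symmetric_dist` object.
#' @return An object of class `xf_filtration` holding the merge events
#'   (`$events`: data frame with `epsilon`, the edge node labels, and a
#'   list-column `members` with the partition-tagged node ids of the merged
#'   component) plus the derived invariants consumed by [partition_betti_curve()],
#'   [barcode()], [single_linkage_matrix()] and [projected_ultrametric()].
#' @examples
#' D <- bipartite_dist(matrix(c(0.2, 0.9, 1, 0.4), 2, 2))
#' f <- filtrate(D)
#' f$events$epsilon
#' @export
filtrate <- function(D) UseMethod("filtrate")

#' @export
filtrate.bipartite_dist <- function(D) {
  k <- .filt_core_cpp(D$D, TRUE)
  p <- nrow(D$D)
  tags <- c(paste0("cue_alpha:", D$row_labels),
            paste0("item_gamma:", D$col_labels))
  .new_filtration(k, type = "bipartite", p = p, n_nodes = 2L * p,
                  node_tags = tags,
                  row_labels = D$row_labels, col_labels = D$col_labels,
                  D = D$D)
}

#' @export
filtrate.symmetric_dist <- function(D) {
  k <- .filt_core_cpp(D$D, FALSE)
  p <- nrow(D$D)
  .new_filtration(k, type = "symmetric", p = p, n_nodes = p,
                  node_tags = paste0("all:", D$labels),
                  row_labels = D$labels, col_labels = D$labels,
                  D = D$D)
}

# assemble the filtration object; replay unions in R to attach member lists
.new_filtration <- function(k, type, p, n_nodes, node_tags, row_labels,
                            col_labels, D) {
  m <- length(k$eps)
  members <- vector("list", m)
  if (m > 0) {
    parent <- seq_len(n_nodes)
    mem <- as.list(seq_len(n_nodes))
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    for (i in seq_len(m)) {
      ra <- find(k$node_a[i]); rb <- find(k$node_b[i])
      parent[rb] <- ra
      mem[[ra]] <- c(mem[[ra]], mem[[rb]])
      members[[i]] <- node_tags[sort(mem[[ra]])]
    }
  }
  events <- data.frame(epsilon = as.numeric(k$eps),
                       node_a = node_tags[k$node_a],
                       node_b = node_tags[k$node_b],
                       stringsAsFactors = FALSE)
  events$members <- members
  out <- list(type = type, p = p, n_nodes = n_nodes,
              events = events,
              deaths_x = as.numeric(k$deaths_x),
              deaths_y = if (type == "bipartite") as.numeric(k$deaths_y) else NULL,
              slm = if (type == "bipartite") k$slm else NULL,
              ux = k$ux,
              uy = if (type == "bipartite") k$uy else NULL,
              row_labels = row_labels, col_labels = col_labels, D = D)
  class(out) <- "xf_filtration"
  out
}

#' @export
print.xf_filtration <- function(x, ...) {
  cat(sprintf("%s graph filtration: %d nodes, %d merge events, %d final components\n",
              x$type, x$n_nodes, nrow(x$events), x$n_nodes - nrow(x$events)))
  invisible(x)
}

.match_partition <- function(filt, partition) {
  partition <- as.character(partition)[1]
  if (filt$type == "symmetric") {
    if (partition != "all")
      .xfnet_error(sprintf("unknown partition '%s' for a symmetric filtration",
                           partition), "xfnet_error_partition")
    return(list(deaths = filt$deaths_x, n0 = filt$p, labels = filt$row_labels))
  }
  switch(partition,
    cue_alpha  = list(deaths = filt$deaths_x, n0 = filt$p, labels = filt$row_labels),
    item_gamma = list(deaths = filt$deaths_y, n0 = filt$p, labels = filt$col_labels),
    all        = list(deaths = filt$events$epsilon, n0 = filt$n_nodes,
                      labels = c(filt$row_labels, filt$col_labels)),
    .xfnet_error(sprintf("unknown partition '%s'", partition),
                 "xfnet_error_partition"))
}

#' Per-partition Betti-0 curve
#'
#' The number of connected components of the full graph at threshold epsilon,
#' counted over one node partition: components containing at least one node
#' of the partition, projected onto that partition. The curve starts at the
#' partition size, is non-increasing and right-continuous, and drops by one
#' at each epsilon where two partition-projected classes merge.
#'
#' @param filt An `xf_filtration` from [filtrate()].
#' @param partition `"cue_alpha"`, `"item_gamma"`, or `"all"` (the only valid
#'   choice for a symmetric filtration).
#' @return A `betti_curve` object with `breakpoints`, `counts` (component
#'   count on `[breakpoint_k, breakpoint_{k+1})`), `deaths`, `n0`, `partition`.
#' @export
partition_betti_curve <- function(filt, partition = c("cue_alpha", "item_gamma", "all")) {
  if (length(partition) > 1) partition <- partition[1]
  pr <- .match_partition(filt, partition)
  .new_betti_curve(pr$deaths, pr$n0, partition)
}

.new_betti_curve <- function(deaths, n0, partition) {
  deaths <- sort(as.numeric(deaths))
  bp <- unique(deaths)
  counts <- n0 - findInterval(bp, deaths)
  structure(list(breakpoints = bp, counts = counts, deaths = deaths,
                 n0 = n0, partition = partition),
            class = "betti_curve")
}

#' Evaluate a Betti-0 curve at filtration values
#'
#' @param curve A `betti_curve`.
#' @param eps Numeric vector of filtration values.
#' @return Integer vector of component counts (right-continuous convention:
#'   a merge at epsilon already counts at epsilon).
#' @export
betti_at <- function(curve, eps) {
  curve$n0 - findInterval(eps, curve$deaths)
}

#' @export
print.betti_curve <- function(x, ...) {
  cat(sprintf("Betti-0 curve (partition %s): starts at %d, %d drops, ends at %d\n",
              x$partition, x$n0, length(x$deaths), x$n0 - length(x$deaths)))
  invisible(x)
}

#' Per-partition barcode
#'
#' One bar per node of the partition, all born at epsilon = 0. A bar dies at
#' each epsilon where two partition-projected components merge; components
#' surviving the whole filtration are censored at death = 1 (the non-edge
#' sentinel).
#'
#' @inheritParams partition_betti_curve
#' @return An `xf_barcode` object: data frame `bars` with `birth`, `death`,
#'   `censored`, plus `partition` and `n0`.
#' @export
barcode <- function(filt, partition = c("cue_alpha", "item_gamma", "all")) {
  if (length(partition) > 1) partition <- partition[1]
  pr <- .match_partition(filt, partition)
  deaths <- sort(as.numeric(pr$deaths))
  n_cens <- pr$n0 - length(deaths)
  bars <- data.frame(birth = 0,
                     death = c(deaths, rep(1, n_cens)),
                     censored = c(rep(FALSE, length(deaths)), rep(TRUE, n_cens)))
  structure(list(bars = bars, partition = partition, n0 = pr$n0),
            class = "xf_barcode")
}

#' @export
print.xf_barcode <- function(x, ...) {
  cat(sprintf("barcode (partition %s): %d bars, %d censored at 1\n",
              x$partition, nrow(x$bars), sum(x$bars$censored)))
  invisible(x)
}

#' Single-linkage matrix (first-connection filtration values)
#'
#' Entry (i, j) is the smallest epsilon at which cue-alpha node i and
#' item-gamma node j belong to one connected component — equivalently the
#' minimax (bottleneck) path distance over the bipartite graph. Pairs never
#' connected below 1 take the sentinel value 1. Shorter single-linkage
#' distance means tighter negative coupling.
#'
#' @param filt An `xf_filtration` from [filtrate()] of a `bipartite_dist`
#'   (for a symmetric filtration the within-set first-connection matrix is
#'   returned, which equals the single-linkage ultrametric).
#' @return A labeled `p x p` numeric matrix.
#' @export
single_linkage_matrix <- function(filt) {
  m <- if (filt$type == "bipartite") filt$slm else filt$ux
  dimnames(m) <- list(filt$row_labels, filt$col_labels)
  m
}

#' Projected ultrametric within one partition
#'
#' Entry (i, k) is the first epsilon at which same-partition nodes i and k
#' share a connected component of the full graph. The result is symmetric,
#' has a zero diagonal, satisfies the ultrametric inequality exactly, and is
#' the substrate of the per-partition dendrogram.
#'
#' @inheritParams partition_betti_curve
#' @return A labeled symmetric matrix.
#' @export
projected_ultrametric <- function(filt, partition = c("cue_alpha", "item_gamma", "all")) {
  if (length(partition) > 1) partition <- partition[1]
  if (filt$type == "symmetric") {
    if (partition != "all")
      .xfnet_error("symmetric filtrations only have partition 'all'",
                   "xfnet_error_partition")
    u <- filt$ux
    dimnames(u) <- list(filt$row_labels, filt$col_labels)
    return(u)
  }
  u <- switch(partition,
    cue_alpha = { m <- filt$ux; dimnames(m) <- list(filt$row_labels, filt$row_labels); m },
    item_gamma = { m <- filt$uy; dimnames(m) <- list(filt$col_labels, filt$col_labels); m },
    .xfnet_error("partition must be 'cue_alpha' or 'item_gamma' for a bipartite filtration",
                 "xfnet_error_partition"))
  u
}

.is_ultrametric <- function(U, tol = 1e-8) {
  p <- nrow(U)
  if (any(abs(diag(U)) > tol) || any(abs(U - t(U)) > tol)) return(FALSE)
  for (j in seq_len(p)) {
    # d(i,k) <= max(d(i,j), d(j,k)) for all i, k given intermediate j
    bound <- outer(U[, j], U[j, ], pmax)
    if (any(U > bound + tol)) return(FALSE)
  }
  TRUE
}

#' Single-linkage dendrogram of an ultrametric
#'
#' Builds the merge tree whose cophenetic matrix equals the input ultrametric
#' exactly: nodes are fixed along one axis (unlike the barcode, where bars are
#' sorted by death) and merge heights are the filtration values at which
#' clusters join. The tree is returned as a standard `hclust` object
#' (method `"single"`) built by an internal agglomeration replay, so
#' `stats::cophenetic()` round-trips the input.
#'
#' @param U A symmetric matrix with zero diagonal satisfying the ultrametric
#'   inequality, e.g. from [projected_ultrametric()].
#' @return An `hclust` object.
#' @export
sl_dendrogram <- function(U) {
  U <- as.matrix(U)
  p <- nrow(U)
  if (p != ncol(U) || !.is_ultrametric(U))
    .xfnet_error("input is not an ultrametric", "xfnet_error_ultrametric")
  labels <- rownames(U)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (p == 1) {
    hc <- list(merge = matrix(integer(0), 0, 2), height = numeric(0),
               order = 1L, labels = labels, method = "single",
               call = match.call(), dist.method = "filtration")
    class(hc) <- "hclust"
    return(hc)
  }
  # agglomerate at successive minimum heights; under an ultrametric the
  # single-linkage update is just the elementwise minimum of merged rows
  active <- seq_len(p)            # cluster ids: negative = singleton later
  id <- -seq_len(p)               # hclust coding
  M <- U
  diag(M) <- Inf
  merge <- matrix(0L, p - 1, 2)
  height <- numeric(p - 1)
  members <- as.list(seq_len(p))
  for (s in seq_len(p - 1)) {
    idx <- which(M == min(M), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    height[s] <- M[i, j]
    merge[s, ] <- sort(c(id[i], id[j]))
    id[i] <- s
    members[[i]] <- c(members[[i]], members[[j]])
    newrow <- pmin(M[i, ], M[j, ])
    M[i, ] <- newrow; M[, i] <- newrow
    M[i, i] <- Inf
    M <- M[-j, -j, drop = FALSE]
    id <- id[-j]
    members <- members[-j]
  }
  order <- .dendro_order(merge, p)
  hc <- list(merge = merge, height = height, order = order,
             labels = labels, method = "single", call = match.call(),
             dist.method = "filtration")
  class(hc) <- "hclust"
  hc
}

# leaf order by left-to-right traversal of the merge tree (no crossings)
.dendro_order <- function(merge, p) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  as.integer(walk(p - 1))
}
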
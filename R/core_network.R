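#' Equalize trial counts between two conditions
#'
#' Pearson correlations are biased comparisons when computed on different
#' numbers of observations, so before any between-condition contrast the
#' larger table is subsampled (uniformly, without replacement, reproducibly
#' under `seed`) down to the smaller table's trial count. The smaller table is
#' returned unchanged and trial order is preserved within the kept subset.
#'
#' @param table_a,table_b `trial_power_table` objects sharing `roi_labels`.
#' @param seed Integer seed for the subsample draw.
#' @return A list with elements `a` and `b`, both with
#'   `min(n_a, n_b)` trials.
#' @export
equalize_trials <- function(table_a, table_b, seed) {
  if (!identical(table_a$roi_labels, table_b$roi_labels))
    .xfnet_error("tables have mismatched roi_labels", "xfnet_error_labels")
  na <- nrow(table_a$values); nb <- nrow(table_b$values)
  n <- min(na, nb)
  if (n < 3)
    .xfnet_error("fewer than 3 trials after equalization", "xfnet_error_trials")
  if (na == nb) return(list(a = table_a, b = table_b))
  set.seed(as.integer(seed))
  if (na > nb) {
    keep <- sort(sample.int(na, n))
    table_a$values <- table_a$values[keep, , drop = FALSE]
  } else {
    keep <- sort(sample.int(nb, n))
    table_b$values <- table_b$values[keep, , drop = FALSE]
  }
  list(a = table_a, b = table_b)
}

# kept-trial index draw used inside permutation engines (one draw covers both
# band-epoch tables of a condition, which share trial rows)
.equalize_idx <- function(n_from, n_to) {
  if (n_from == n_to) seq_len(n_from) else sort(sample.int(n_from, n_to))
}

#' Across-trial Pearson correlation matrix
#'
#' Entry (i, j) is the Pearson correlation across trials between column i of
#' `x` and column j of `y`. For the time-delayed cross-frequency network, `x`
#' holds cue-alpha and `y` item-gamma powers of the same trials; rows and
#' columns of the result then index different node sets, so the matrix is
#' generally asymmetric. Zero-variance columns make affected entries
#' undefined: they are returned as `NA` and reported via the `"undefined"`
#' attribute (row/column index pairs) plus a warning — no silent substitution.
#'
#' @param x,y `trial_power_table` objects (or bare matrices) with equal trial
#'   counts (use [equalize_trials()] first) and at least 3 trials.
#' @return A `p_x x p_y` correlation matrix with dimnames, attribute
#'   `"n_trials"`, and attribute `"undefined"` when applicable.
#' @export
pearson_matrix <- function(x, y) {
  xv <- .tpt_values(x); yv <- .tpt_values(y)
  if (nrow(xv) != nrow(yv))
    .xfnet_error("x and y must have equal trial counts (equalize first)",
                 "xfnet_error_trials")
  if (nrow(xv) < 3)
    .xfnet_error("need at least 3 trials", "xfnet_error_trials")
  r <- suppressWarnings(stats::cor(xv, yv))
  dimnames(r) <- list(.tpt_labels(x), .tpt_labels(y))
  attr(r, "n_trials") <- nrow(xv)
  if (anyNA(r)) {
    und <- which(is.na(r), arr.ind = TRUE)
    attr(r, "undefined") <- und
    warning(sprintf("%d correlation entries undefined (zero-variance column)",
                    nrow(und)), call. = FALSE)
  }
  r
}

#' Negative-coupling distance transform
#'
#' Converts a correlation matrix into the distance used by the filtration:
#' only the negative branch carries coupling evidence, so `d = 1 - |r|` when
#' `r < 0` and `d = 1` (the maximum distance, i.e. a non-edge) when `r >= 0`.
#' Undefined entries (`NA`) map to 1 under the default policy
#' `"max_distance"` — a flat power trace carries no negative-coupling
#' evidence — or raise an error under `"strict"`.
#'
#' @param r Correlation matrix with entries in `[-1, 1]` or `NA`.
#' @param undefined_policy `"max_distance"` (default) or `"strict"`.
#' @return A `bipartite_dist` object: list with `D` (entries in `[0, 1]`),
#'   `row_labels` (cue-alpha ROIs), `col_labels` (item-gamma ROIs) and
#'   `n_trials_used`. Diagonal entries (intra-regional coupling) are ordinary
#'   entries and are retained.
#' @export
negative_distance <- function(r, undefined_policy = c("max_distance", "strict")) {
  undefined_policy <- match.arg(undefined_policy)
  r <- as.matrix(r)
  if (anyNA(r) && undefined_policy == "strict")
    .xfnet_error("undefined correlation entries under policy 'strict'",
                 "xfnet_error_undefined")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    .xfnet_error("correlations must lie in [-1, 1]", "xfnet_error_range")
  d <- .negdist(r)
  dimnames(d) <- dimnames(r)
  bipartite_dist(d,
                 row_labels = rownames(r), col_labels = colnames(r),
                 n_trials_used = attr(r, "n_trials"))
}

# vectorized transform: d = 1 - |r| = 1 + r on the negative branch, else 1
.negdist <- function(r) {
  d <- 1 + r
  d[!is.na(r) & r >= 0] <- 1
  d[is.na(r)] <- 1
  d
}

#' Bipartite distance matrix constructor
#'
#' Wraps a `p x p` matrix of negative-coupling distances whose rows index one
#' node partition (cue-alpha ROIs) and columns the other (item-gamma ROIs).
#'
#' @param D Square numeric matrix with entries in `[0, 1]`; 1 is the non-edge
#'   sentinel.
#' @param row_labels,col_labels ROI labels for the two partitions.
#' @param n_trials_used Optional count of trials behind each correlation.
#' @export
bipartite_dist <- function(D, row_labels = rownames(D),
                           col_labels = colnames(D), n_trials_used = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D))
    .xfnet_error("bipartite distance matrix must be p x p", "xfnet_error_shape")
  if (any(D < 0 | D > 1))
    .xfnet_error("distances must lie in [0, 1]", "xfnet_error_range")
  p <- nrow(D)
  if (is.null(row_labels)) row_labels <- paste0("X", seq_len(p))
  if (is.null(col_labels)) col_labels <- paste0("Y", seq_len(p))
  dimnames(D) <- list(row_labels, col_labels)
  structure(list(D = D, row_labels = row_labels, col_labels = col_labels,
                 n_trials_used = n_trials_used),
            class = "bipartite_dist")
}

#' @export
print.bipartite_dist <- function(x, ...) {
  cat(sprintf("bipartite distance matrix: %d x %d, %d edges (d < 1)\n",
              nrow(x$D), ncol(x$D), sum(x$D < 1)))
  invisible(x)
}

#' Symmetric (within-frequency) distance matrix constructor
#'
#' @param D Symmetric numeric matrix with entries in `[0, 1]`; self-distances
#'   are fixed at 1 (self-correlation is +1 by construction, hence a
#'   non-edge).
#' @param labels ROI labels.
#' @export
symmetric_dist <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    .xfnet_error("matrix must be symmetric", "xfnet_error_shape")
  if (any(D < 0 | D > 1))
    .xfnet_error("distances must lie in [0, 1]", "xfnet_error_range")
  diag(D) <- 1
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  structure(list(D = D, labels = labels), class = "symmetric_dist")
}

#' @export
print.symmetric_dist <- function(x, ...) {
  cat(sprintf("symmetric distance matrix: %d nodes, %d edges (d < 1)\n",
              nrow(x$D), sum(x$D[upper.tri(x$D)] < 1)))
  invisible(x)
}

#' Time-delayed cross-frequency bipartite network
#'
#' Convenience composition: [pearson_matrix()] of the cue-alpha table against
#' the item-gamma table, then [negative_distance()].
#'
#' @inheritParams pearson_matrix
#' @inheritParams negative_distance
#' @export
bipartite_distance <- function(x, y,
                               undefined_policy = c("max_distance", "strict")) {
  negative_distance(pearson_matrix(x, y), undefined_policy)
}

#' Non-time-delayed within-frequency network
#'
#' Negative-only distance transform of the symmetric Pearson matrix of one
#' band-epoch table against itself (cue-alpha-to-cue-alpha or
#' item-gamma-to-item-gamma), with the diagonal forced to 1.
#'
#' @inheritParams pearson_matrix
#' @inheritParams negative_distance
#' @return A `symmetric_dist` object.
#' @export
within_frequency_distance <- function(x, undefined_policy = c("max_distance", "strict")) {
  undefined_policy <- match.arg(undefined_policy)
  r <- pearson_matrix(x, x)
  if (!is.null(attr(r, "undefined")) && undefined_policy == "strict")
    .xfnet_error("undefined correlation entries under policy 'strict'",
                 "xfnet_error_undefined")
  d <- .negdist(unclass(r))
  diag(d) <- 1
  symmetric_dist(d, labels = .tpt_labels(x))
}
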
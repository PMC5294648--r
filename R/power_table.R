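#' Trial-level ROI power table
#'
#' Container for one subject/condition/band-epoch block of normalized source
#' power: a trials x ROI matrix (power expressed as a dimensionless ratio
#' against the inter-trial-interval baseline). These tables are the raw input
#' of the whole pipeline; the across-trial Pearson correlation between the
#' cue-alpha table and the item-gamma table of the same condition defines the
#' time-delayed cross-frequency network.
#'
#' @param values Numeric matrix, `n_trials x p`, no missing entries,
#'   `n_trials >= 3`.
#' @param roi_labels Character vector of length `p`; unique ROI names.
#' @param subject_id Subject identifier.
#' @param condition `"R"` (Remember) or `"NR"` (No-Remember).
#' @param band_epoch `"cue_alpha"` (alpha power during cue presentation) or
#'   `"item_gamma"` (gamma power during item presentation).
#' @return An object of class `trial_power_table`.
#' @examples
#' tpt <- trial_power_table(matrix(rnorm(30, 1, 0.2), 10, 3),
#'                          c("A.L", "B.L", "C.R"), "S01", "R", "cue_alpha")
#' dim(tpt$values)
#' @export
trial_power_table <- function(values, roi_labels, subject_id = "S01",
                              condition = c("R", "NR"),
                              band_epoch = c("cue_alpha", "item_gamma")) {
  condition <- match.arg(condition)
  band_epoch <- match.arg(band_epoch)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values))
    .xfnet_error("power table has missing entries", "xfnet_error_table")
  if (nrow(values) < 3)
    .xfnet_error("a power table needs at least 3 trials", "xfnet_error_table")
  if (ncol(values) != length(roi_labels))
    .xfnet_error("ncol(values) must equal length(roi_labels)",
                 "xfnet_error_table")
  if (anyDuplicated(roi_labels))
    .xfnet_error("roi_labels must be unique", "xfnet_error_table")
  colnames(values) <- roi_labels
  structure(list(subject_id = subject_id, condition = condition,
                 band_epoch = band_epoch,
                 roi_labels = as.character(roi_labels), values = values),
            class = "trial_power_table")
}

#' @export
print.trial_power_table <- function(x, ...) {
  cat(sprintf("trial power table: subject %s, condition %s, %s; %d trials x %d ROIs\n",
              x$subject_id, x$condition, x$band_epoch,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept either a trial_power_table or a bare matrix in computational ops.
.tpt_values <- function(x) {
  if (inherits(x, "trial_power_table")) return(x$values)
  if (is.matrix(x)) return(x)
  .xfnet_error("expected a trial_power_table or a matrix", "xfnet_error_table")
}

.tpt_labels <- function(x) {
  if (inherits(x, "trial_power_table")) return(x$roi_labels)
  cn <- colnames(x)
  if (is.null(cn)) paste0("V", seq_len(ncol(x))) else cn
}
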
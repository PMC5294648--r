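#' Cerebral-cortex ROI node set
#'
#' Loads the packaged cortical region-of-interest list derived from the AAL
#' parcellation with subcortical and cerebellar regions excluded: 38 regions
#' per hemisphere, 76 labels in total. Labels follow the `<name>.L` /
#' `<name>.R` hemisphere-suffix convention and interleave left/right per
#' region.
#'
#' @param path Optional path to an alternative plain-text node list (one label
#'   per line, `#` comment lines ignored). Defaults to the packaged list.
#' @return An object of class `roi_node_set`: a list with `labels` (character
#'   vector) and `hemisphere` (factor with levels `L`, `R`).
#' @examples
#' rois <- roi_node_set()
#' table(rois$hemisphere)
#' @export
roi_node_set <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal_cortex_rois.txt", package = "xfnet")
  lines <- readLines(path)
  labels <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  labels <- trimws(labels)
  if (anyDuplicated(labels))
    .xfnet_error("ROI labels must be unique", "xfnet_error_roi")
  hemi <- sub("^.*\\.", "", labels)
  if (!all(hemi %in% c("L", "R")))
    .xfnet_error("every ROI label needs a .L or .R hemisphere suffix",
                 "xfnet_error_roi")
  structure(list(labels = labels, hemisphere = factor(hemi, c("L", "R"))),
            class = "roi_node_set")
}

#' @export
print.roi_node_set <- function(x, ...) {
  cat("ROI node set:", length(x$labels), "labels (",
      sum(x$hemisphere == "L"), "L /", sum(x$hemisphere == "R"), "R )\n")
  invisible(x)
}
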
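#' @title Readers and writers
#' @description Trial power tables travel as tab-separated text with an ROI
#' header plus a key-value sidecar (`<file>.meta`) carrying subject,
#' condition, band-epoch and seed provenance. Distance and single-linkage
#' matrices are labeled TSV printed with 12 significant digits for round-trip
#' stability; structured results (barcodes, test records, manifests) are
#' JSON.
#' @name io
NULL

#' Write / read a trial power table
#'
#' @param tpt A `trial_power_table`.
#' @param path Output TSV path; a `<path>.meta` sidecar is written next to it.
#' @param provenance Optional named list merged into the sidecar.
#' @return `write_power_table` returns `path` invisibly; `read_power_table`
#'   returns a `trial_power_table`.
#' @export
write_power_table <- function(tpt, path, provenance = list()) {
  df <- as.data.frame(tpt$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  meta <- c(list(subject_id = tpt$subject_id, condition = tpt$condition,
                 band_epoch = tpt$band_epoch), provenance)
  writeLines(paste0(names(meta), ": ", vapply(meta, as.character, "")),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_power_table
#' @export
read_power_table <- function(path) {
  vals <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                               check.names = FALSE))
  meta_path <- paste0(path, ".meta")
  meta <- list(subject_id = "S01", condition = "R", band_epoch = "cue_alpha")
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), ": ", fixed = TRUE)
    got <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    for (f in c("subject_id", "condition", "band_epoch"))
      if (f %in% names(got)) meta[[f]] <- unname(got[[f]])
  }
  trial_power_table(vals, colnames(vals), meta$subject_id, meta$condition,
                    meta$band_epoch)
}

#' Write / read a labeled distance or single-linkage matrix
#'
#' @param m Numeric matrix with dimnames (or a `bipartite_dist` /
#'   `symmetric_dist`, whose `$D` is written).
#' @param path TSV path.
#' @export
write_distance_matrix <- function(m, path) {
  if (inherits(m, c("bipartite_dist", "symmetric_dist"))) m <- m$D
  df <- data.frame(roi = rownames(m),
                   format(m, digits = 12, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialize a barcode / Betti curve / filtration result to JSON
#'
#' @param x An `xf_barcode`, `betti_curve` or `permutation_result`.
#' @param path Output path.
#' @export
write_record_json <- function(x, path) {
  rec <- if (inherits(x, "xf_barcode")) {
    list(kind = "barcode", partition = x$partition, n0 = x$n0,
         birth = x$bars$birth, death = x$bars$death, censored = x$bars$censored)
  } else if (inherits(x, "betti_curve")) {
    list(kind = "betti_curve", partition = x$partition, n0 = x$n0,
         breakpoints = x$breakpoints, counts = x$counts)
  } else if (inherits(x, "permutation_result")) {
    list(kind = "permutation_result", partition = x$partition,
         observed_stat = x$observed_stat, p_value = x$p_value,
         n_perm = x$n_perm, seed = x$seed, sidedness = x$sidedness,
         null_stats = x$null_stats)
  } else {
    unclass(x)
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits, per subject, four power-table TSVs (`<id>_<cond>_<band>.tsv` with
#' sidecars), plus `behavior.tsv` and `manifest.json`. The write is atomic:
#' files land in a staging directory that is renamed into place, so a failed
#' run leaves no partial outputs.
#'
#' @param cohort An `xf_cohort`.
#' @param dir Output directory (created; must not already contain a cohort).
#' @export
write_cohort <- function(cohort, dir) {
  stage <- paste0(dir, ".staging")
  if (dir.exists(stage)) unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)
  bands <- c(ca = "cue_alpha", ig = "item_gamma")
  for (sub in cohort$subjects) {
    for (cond in c("R", "NR")) for (b in names(bands)) {
      m <- sub[[paste0(b, "_", cond)]]
      tpt <- trial_power_table(m, colnames(m), sub$subject_id, cond, bands[[b]])
      write_power_table(tpt,
        file.path(stage, sprintf("%s_%s_%s.tsv", sub$subject_id, cond, bands[[b]])),
        provenance = list(seed = cohort$config$seed))
    }
  }
  write.table(cohort$behavior, file.path(stage, "behavior.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$manifest$seed,
         planted_pairs = cohort$manifest$planted_pairs,
         gamma_R = cohort$manifest$gamma_R,
         gamma_NR = cohort$manifest$gamma_NR,
         latent_memory = cohort$manifest$latent_memory,
         latent_compliance = cohort$manifest$latent_compliance,
         designated_good = cohort$manifest$designated_good),
    file.path(stage, "manifest.json"), digits = NA, pretty = TRUE)
  if (dir.exists(dir)) unlink(dir, recursive = TRUE)
  file.rename(stage, dir)
  ok <- TRUE
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `xf_cohort` (without the simulation config; the manifest is
#'   reloaded when present). Errors name the subject if a band-epoch file is
#'   missing.
#' @export
read_cohort <- function(dir) {
  beh_path <- file.path(dir, "behavior.tsv")
  if (!file.exists(beh_path))
    .xfnet_error(sprintf("no behavior.tsv in %s", dir), "xfnet_error_io")
  behavior <- read.table(beh_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  subjects <- list()
  for (sid in behavior$subject_id) {
    sub <- list(subject_id = sid)
    for (cond in c("R", "NR")) for (band in c("cue_alpha", "item_gamma")) {
      f <- file.path(dir, sprintf("%s_%s_%s.tsv", sid, cond, band))
      if (!file.exists(f))
        .xfnet_error(sprintf("subject %s: missing %s table for condition %s",
                             sid, band, cond), "xfnet_error_io")
      key <- paste0(if (band == "cue_alpha") "ca" else "ig", "_", cond)
      sub[[key]] <- read_power_table(f)$values
    }
    subjects[[sid]] <- sub
  }
  manifest <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  structure(list(subjects = subjects, behavior = behavior,
                 manifest = manifest, config = NULL),
            class = "xf_cohort")
}
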
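# Plain-text interchange: tab-separated variant and segment tables,
# Newick trees (via ape) and YAML truth sidecars for simulated patients.

#' Write / read a variant table
#'
#' Tab-separated with columns `patient`, `sample`, `chrom`, `pos`, `ref`,
#' `alt`, `ref_reads`, `alt_reads` (extra columns are preserved).
#'
#' @param variants data.frame (e.g. from [emit_read_counts()]).
#' @param path file path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a SEG-like segment table
#'
#' Tab-separated with columns `sample`, `chrom`, `start`, `end`, `total`,
#' `major`, `minor`; 1-based inclusive coordinates.
#'
#' @param segments data.frame (e.g. from [emit_cna_profiles()]).
#' @param path file path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a truth bundle sidecar
#'
#' Serializes the planted ground truth (tree as Newick, SNV/CNA
#' assignments, CCFs, cross-seeding) as YAML next to the emitted tables.
#'
#' @param truth a `truth_bundle`.
#' @param path output YAML path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_bundle"))
  obj <- list(
    patient_id = truth$patient_id,
    tree = ape::write.tree(truth$tree),
    sample_ccf = as.list(truth$sample_ccf),
    snv_assignments = lapply(seq_len(nrow(truth$snv_assignments)), function(i)
      as.list(truth$snv_assignments[i, ])),
    cna_assignments = if (is.null(truth$cna_assignments)) list() else
      lapply(seq_len(nrow(truth$cna_assignments)), function(i)
        as.list(truth$cna_assignments[i, ])),
    cross_seed = truth$cross_seed)
  yaml::write_yaml(obj, path)
}

#' Write a tier matrix as a tab-separated table
#'
#' Cells are `1` (present), `0` (absent) or `NA` (missing); a comment
#' header carries the per-sample tier levels.
#'
#' @param tm a `tier_matrix`.
#' @param path file path.
#' @export
write_tier_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "tier_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tier\t", paste(names(tm$sample_tier),
                                      tm$sample_tier, sep = "=",
                                      collapse = "\t")), con)
  utils::write.table(data.frame(sample = rownames(tm$calls), tm$calls,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}
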
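#!/usr/bin/env Rscript
# Per-patient phylogenies: Dollo branch-and-bound trees from the tier
# matrices (ties broken by the copy-number tree), minimum-event CNA trees
# with diploid or WGD-aware rooting and resampling support, ACCTRAN
# ancestral states, and reversion verification against the segment
# profiles.  Reads results/cohort + results/tiers, writes results/trees/.

suppressMessages(library(phyloseed))

cohort <- "results/cohort"
dir.create("results/trees", showWarnings = FALSE, recursive = TRUE)

patients <- sub("_variants.tsv$", "",
                basename(Sys.glob(file.path(cohort, "*_variants.tsv"))))
meta <- read.table(file.path(cohort, "metadata.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
rev_rows <- list()
for (pid in patients) {
  rc <- read_variants(file.path(cohort, paste0(pid, "_variants.tsv")))
  prof <- read_segments(file.path(cohort, paste0(pid, "_segments.tsv")))
  tm <- apply_tier3_filters(rc)
  if (tm$empty || nrow(tm$calls) < 3L) next

  is_wgd <- meta$wgd[meta$patient == pid]
  masked <- mask_high_copy(prof, high_ploidy = is_wgd)
  cna <- build_cna_tree(masked)
  if (is_wgd) {
    wr <- suppressWarnings(wgd_root(masked, cna))
    cna <- wr$tree
    cat(sprintf("%s: WGD rooting selected ancestor %s\n", pid, wr$selected))
  }
  pm <- phyloseed:::.profiles_to_matrices(masked)
  D <- phyloseed:::.dissimilarity_matrix(pm)
  cna_sup <- resampling_support(D, cna, n_resamples = 100, noise_sd = 1,
                                seed = 42)
  ape::write.tree(cna, file.path("results/trees", paste0(pid, "_cna.nwk")))
  ape::write.tree(cna_sup,
                  file.path("results/trees", paste0(pid, "_cna_support.nwk")))

  ds <- dollo_search(tm$calls)
  snv_tree <- break_ties_with_cna(ds$trees, cna)
  rec <- acctran_reconstruct(snv_tree, tm$calls)
  ape::write.tree(rec$tree,
                  file.path("results/trees", paste0(pid, "_snv.nwk")))

  # per-character event table
  ev <- data.frame(
    snv = names(rec$gain_node),
    gain_samples = vapply(rec$gain_node, function(v)
      if (is.na(v)) NA_character_ else
        paste(sort(setdiff(rec$tree$tip.label[
          phyloseed:::.phylo_clades(rec$tree)[[v]]], "outgroup")),
          collapse = ","), character(1L)),
    n_losses = rec$losses_per_char)
  write.table(ev, file.path("results/trees", paste0(pid, "_events.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # reversion report
  alpha <- read.table(file.path("results/ccf", paste0(pid, "_alpha.tsv")),
                      header = TRUE, sep = "\t")
  ccf <- setNames(alpha$global_ccf, alpha$sample)
  info <- unique(rc[, c("snv", "chrom", "pos")])
  depths <- matrix(NA_real_, nrow(tm$calls), ncol(tm$calls),
                   dimnames = dimnames(tm$calls))
  keep <- rc$sample %in% rownames(depths) & rc$snv %in% colnames(depths)
  depths[cbind(rc$sample[keep], rc$snv[keep])] <- rc$depth[keep]
  rv <- verify_reversions(rec, info, prof, ccf, depths)
  if (nrow(rv)) rv <- cbind(patient = pid, rv)
  rev_rows[[pid]] <- rv
  cat(sprintf("%s: Dollo score %d (%d co-optimal), %d reversion calls\n",
              pid, ds$score, length(ds$trees), nrow(rv)))
}
revs <- do.call(rbind, rev_rows)
write.table(revs, "results/trees/reversions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("reversion status counts:\n")
print(table(revs$status))
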
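#!/usr/bin/env Rscript
# Progression metrics over the inferred trees: normalized branch lengths
# and their correlation with overall survival, early/late substitution
# spectra, pairwise clonal-frequency configurations, cross-seeding calls
# and per-patient dissemination modes.  Writes results/progression/.

suppressMessages(library(phyloseed))

cohort <- "results/cohort"
dir.create("results/progression", showWarnings = FALSE, recursive = TRUE)
meta <- read.table(file.path(cohort, "metadata.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
patients <- meta$patient

nbl_rows <- list(); spec_rows <- list(); mode_rows <- list()
seed_rows <- list()
for (pid in patients) {
  snv_file <- file.path("results/trees", paste0(pid, "_snv.nwk"))
  if (!file.exists(snv_file)) next
  snv_tree <- ape::read.tree(snv_file)
  cna_tree <- ape::read.tree(file.path("results/trees",
                                       paste0(pid, "_cna.nwk")))
  rc <- read_variants(file.path(cohort, paste0(pid, "_variants.tsv")))
  tm <- apply_tier3_filters(rc)

  nb_snv <- normalized_branch_lengths(snv_tree)
  # a tree without truncal events has no defined ratio
  nb_cna <- tryCatch(normalized_branch_lengths(cna_tree),
                     error = function(e) {
                       cat(pid, ": CNA ratios undefined (", conditionMessage(e),
                           ")\n")
                       list(per_leaf = setNames(rep(NA_real_,
                                                    length(nb_snv$per_leaf)),
                                                names(nb_snv$per_leaf)),
                            mean = NA_real_)
                     })
  nbl_rows[[pid]] <- data.frame(
    patient = pid, sample = names(nb_snv$per_leaf),
    snv_ratio = round(nb_snv$per_leaf, 3),
    cna_ratio = round(nb_cna$per_leaf[names(nb_snv$per_leaf)], 3))

  # early/late phase from the reconstruction: trunk gains are early
  rec <- acctran_reconstruct(snv_tree, tm$calls)
  mrca <- ape::getMRCA(rec$tree,
                       match(setdiff(rec$tree$tip.label, "outgroup"),
                             rec$tree$tip.label))
  phase <- ifelse(rec$gain_node == mrca, "early", "late")
  info <- unique(rc[, c("snv", "ref", "alt", "context")])
  info <- info[match(names(phase), info$snv), ]
  info$phase <- phase
  sp <- substitution_spectrum(info[!is.na(info$phase), ])
  sp <- cbind(patient = pid, sp,
              npcpg_early = attr(sp, "npcpg")[["early"]],
              npcpg_late = attr(sp, "npcpg")[["late"]])
  spec_rows[[pid]] <- sp

  mode_rows[[pid]] <- data.frame(
    patient = pid,
    mode_snv = infer_dissemination_mode(snv_tree),
    mode_cna = infer_dissemination_mode(cna_tree),
    mean_snv_ratio = round(nb_snv$mean, 3),
    mean_cna_ratio = round(nb_cna$mean, 3))

  # cross-seeding from clonal frequencies + the CNA tree
  cf_file <- file.path("results/ccf", paste0(pid, "_clonal.tsv"))
  if (file.exists(cf_file)) {
    cfl <- read.table(cf_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    cf <- matrix(NA_real_, nrow(tm$calls), ncol(tm$calls),
                 dimnames = dimnames(tm$calls))
    keep <- cfl$sample %in% rownames(cf) & cfl$snv %in% colnames(cf)
    cf[cbind(cfl$sample[keep], cfl$snv[keep])] <- cfl$clonal_frequency[keep]
    res <- classify_pairwise(cf, tm$calls == 1L, cna_tree)
    if (nrow(res$calls)) {
      seed_rows[[pid]] <- cbind(patient = pid, res$calls)
    }
  }
}

nbl <- do.call(rbind, nbl_rows)
write.table(nbl, "results/progression/branch_lengths.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
modes <- do.call(rbind, mode_rows)
write.table(modes, "results/progression/modes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
spec <- do.call(rbind, spec_rows)
write.table(spec, "results/progression/spectra.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
seeds <- if (length(seed_rows)) do.call(rbind, seed_rows) else
  data.frame(patient = character(0))
write.table(seeds, "results/progression/cross_seeding.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

os <- setNames(meta$overall_survival_days, meta$patient)
for (col in c("mean_snv_ratio", "mean_cna_ratio")) {
  m <- setNames(modes[[col]], modes$patient)
  m <- m[!is.na(m)]
  sc <- survival_correlation(m, os[names(m)])
  cat(sprintf("Spearman rho (%s vs overall survival): %.2f (p = %.3g, n = %d)\n",
              col, sc$rho, sc$p_value, sc$n))
}
cat("dissemination modes:\n")
print(table(modes$mode_snv))
if (nrow(seeds)) {
  cat("cross-seeding calls:\n")
  print(seeds[, c("patient", "donor", "recipient", "n_support")])
}
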
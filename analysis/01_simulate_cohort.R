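#!/usr/bin/env Rscript
# Build the synthetic cohort the downstream analyses run on: ten patients
# with multi-region sampling, mixed dissemination regimes (short- and
# long-history patients, one WGD patient, one cross-seeded patient), and
# per-patient overall survival drawn to track the late mutational burden.
# Writes variant tables, segment tables and truth sidecars under
# results/cohort/.

suppressMessages(library(phyloseed))

outdir <- "results/cohort"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
set.seed(20160901)

cohort <- list(
  # advanced, de-novo metastatic: most change on the trunk, the primary
  # interleaved with the metastases (multiple seeding), short survival
  PT01 = sim_config(n_samples = 5, n_truncal_snvs = 40, n_branch_snvs = 3,
                    cna_branch_mean = 1, seed = 101),
  PT02 = sim_config(n_samples = 4, n_truncal_snvs = 45, n_branch_snvs = 3,
                    cna_branch_mean = 1, cross_seed = TRUE, seed = 102),
  PT03 = sim_config(n_samples = 4, n_truncal_snvs = 35, n_branch_snvs = 4,
                    cna_branch_mean = 1, seed = 103),
  # early-stage patients: metastases descend from a common precursor
  PT04 = sim_config(n_samples = 5, n_truncal_snvs = 30, n_branch_snvs = 8,
                    cna_branch_mean = 2, primary_basal = TRUE, seed = 104),
  PT05 = sim_config(n_samples = 4, n_truncal_snvs = 30, n_branch_snvs = 8,
                    cna_branch_mean = 2, wgd = TRUE, primary_basal = TRUE,
                    seed = 105),
  PT06 = sim_config(n_samples = 5, n_truncal_snvs = 28, n_branch_snvs = 9,
                    cna_branch_mean = 3, primary_basal = TRUE, seed = 106),
  PT07 = sim_config(n_samples = 6, n_truncal_snvs = 30, n_branch_snvs = 10,
                    cna_branch_mean = 3, primary_basal = TRUE, seed = 107),
  # long disease history: late, APOBEC-flavoured mutational burden
  PT08 = sim_config(n_samples = 5, n_truncal_snvs = 25, n_branch_snvs = 16,
                    cna_branch_mean = 5, apobec_late = TRUE,
                    primary_basal = TRUE, seed = 108),
  PT09 = sim_config(n_samples = 4, n_truncal_snvs = 25, n_branch_snvs = 14,
                    cna_branch_mean = 4, primary_basal = TRUE, seed = 109),
  PT10 = sim_config(n_samples = 5, n_truncal_snvs = 22, n_branch_snvs = 18,
                    cna_branch_mean = 5, apobec_late = TRUE,
                    primary_basal = TRUE, seed = 110))

meta <- list()
for (pid in names(cohort)) {
  cfg <- cohort[[pid]]
  tb <- simulate_patient(cfg, patient_id = pid)
  rc <- emit_read_counts(tb)
  prof <- emit_cna_profiles(tb)
  write_variants(rc, file.path(outdir, paste0(pid, "_variants.tsv")))
  write_segments(prof, file.path(outdir, paste0(pid, "_segments.tsv")))
  write_truth(tb, file.path(outdir, paste0(pid, "_truth.yaml")))
  ape::write.tree(tb$tree, file.path(outdir, paste0(pid, "_truth.nwk")))
  # survival tracks the planted late burden plus noise
  late <- mean(tb$snv_assignments$phase == "late")
  os <- round(120 + 2200 * late + rnorm(1, sd = 120))
  meta[[pid]] <- data.frame(patient = pid, n_samples = cfg$n_samples,
                            wgd = cfg$wgd, cross_seed = cfg$cross_seed,
                            overall_survival_days = max(os, 30),
                            late_fraction = round(late, 3))
  cat(sprintf("%s: %d samples, %d SNVs, %d CNA events, OS %d days\n",
              pid, length(tb$samples), nrow(tb$snv_assignments),
              nrow(tb$cna_assignments), max(os, 30)))
}
meta <- do.call(rbind, meta)
write.table(meta, file.path(outdir, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("cohort written to", outdir, "\n")
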
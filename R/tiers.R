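# Tiered filtering of ultra-deep targeted sequencing SNV calls.
#
# Tier 0-2 (exome indexing, somatic calling, orthogonal validation) enter
# as provenance flags; this module recomputes the sequencing-driven levels:
# background-noise estimation from flanking positions, presence calling at
# a VAF cutoff (default 3%), tier-3 coverage/missingness filters and
# tier-4 promotion of samples with array-confirmed CCF >= 30%.

.SUB_CLASSES <- c("AT>CG", "AT>GC", "AT>TA", "CG>AT", "CG>GC", "CG>TA")

#' Collapse a ref>alt substitution to one of the six pooled classes
#'
#' @param ref,alt single reference / alternate bases.
#' @return factor levels among `AT>CG`, `AT>GC`, `AT>TA`, `CG>AT`,
#'   `CG>GC`, `CG>TA`.
#' @export
substitution_class <- function(ref, alt) {
  key <- paste0(toupper(ref), toupper(alt))
  map <- c(AC = "AT>CG", TG = "AT>CG",
           AG = "AT>GC", TC = "AT>GC",
           AT = "AT>TA", TA = "AT>TA",
           CA = "CG>AT", GT = "CG>AT",
           CG = "CG>GC", GC = "CG>GC",
           CT = "CG>TA", GA = "CG>TA")
  out <- unname(map[key])
  if (anyNA(out)) stop("invalid substitution: ref == alt or non-ACGT base")
  out
}

#' Estimate per-class background noise from flanking positions
#'
#' Pools the non-reference read fractions of positions flanking validated
#' SNVs (25 bp up/downstream in the original design).  Positions with more
#' than `max_nonref` total non-reference reads are excluded as likely
#' SNPs/SNVs; the remaining per-substitution fractions are pooled by the
#' six substitution classes.
#'
#' @param flanks data.frame with columns `position_id`, `ref`, `alt`,
#'   `alt_reads`, `depth` (one row per non-reference base per position).
#' @param max_nonref exclusion cutoff on a position's total non-reference
#'   fraction.
#' @return data.frame: one row per class with `mean_background`,
#'   `sd_background`, `max_observed`, `n_positions` (`NA` means the class
#'   had no usable positions, reported as absent rather than zero);
#'   attribute `max_class_mean` is the maximum mean across classes.
#' @export
estimate_background_noise <- function(flanks, max_nonref = 0.10) {
  stopifnot(all(c("position_id", "ref", "alt", "alt_reads", "depth") %in%
                  names(flanks)))
  if (any(flanks$depth <= 0)) stop("all flank positions must have depth > 0")
  tot <- tapply(flanks$alt_reads / flanks$depth, flanks$position_id, sum)
  keep_pos <- names(tot)[tot <= max_nonref]
  fl <- flanks[flanks$position_id %in% keep_pos, , drop = FALSE]
  fl$class <- substitution_class(fl$ref, fl$alt)
  fl$frac <- fl$alt_reads / fl$depth
  out <- data.frame(substitution_class = .SUB_CLASSES,
                    mean_background = NA_real_, sd_background = NA_real_,
                    max_observed = NA_real_, n_positions = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(.SUB_CLASSES)) {
    x <- fl$frac[fl$class == .SUB_CLASSES[i]]
    if (length(x)) {
      out$mean_background[i] <- mean(x)
      out$sd_background[i] <- if (length(x) > 1L) stats::sd(x) else 0
      out$max_observed[i] <- max(x)
      out$n_positions[i] <- length(x)
    }
  }
  attr(out, "max_class_mean") <- if (all(is.na(out$mean_background))) NA_real_
    else max(out$mean_background, na.rm = TRUE)
  out
}

#' Call a mutation present from its VAF
#'
#' Present iff `vaf >= threshold` (the cutoff itself calls present); the
#' default 3% is deliberately conservative relative to typical FFPE
#' background noise.
#'
#' @param vaf variant allele frequency in `[0, 1]` (vectorized).
#' @param threshold presence cutoff.
#' @return logical vector.
#' @export
call_presence <- function(vaf, threshold = 0.03) {
  stopifnot(all(vaf >= 0 & vaf <= 1, na.rm = TRUE))
  vaf >= threshold
}

#' Tier-3 coverage and missingness filters
#'
#' Builds the binary presence/absence character matrix of one patient,
#' applying in order: (1) cells at depth `<= min_depth` become missing
#' (coverage must be strictly above 1,500x); (2) samples with less
#' than `min_sample_nonmissing` non-missing cells are dropped; (3) SNVs
#' with more than `max_snv_missing` missing cells across the retained
#' samples are dropped; (4) SNVs called absent (VAF below
#' `present_threshold`) in every retained sample are dropped; (5) samples
#' in which the fraction of retained SNVs called present is
#' `<= min_sample_present` are dropped (low-CCF guard).
#'
#' @param obs data.frame of one patient's observations: `sample`, `snv`
#'   (locus id), `alt_reads`, `depth` (columns `chrom`, `pos`, `ref`,
#'   `alt` are carried through if present).
#' @param min_depth coverage cutoff (cells at depth `<= min_depth` are
#'   missing).
#' @param min_sample_nonmissing minimum non-missing fraction per sample.
#' @param max_snv_missing maximum missing cells per SNV.
#' @param min_sample_present minimum fraction of SNVs present per sample
#'   (strict inequality).
#' @param present_threshold VAF presence cutoff.
#' @return object of class `tier_matrix`: list with `calls` (samples x
#'   SNVs matrix of 1/0/NA), `tier = 3`, `dropped_samples`,
#'   `dropped_snvs`, `snv_info`, `empty` flag.
#' @export
apply_tier3_filters <- function(obs, min_depth = 1500,
                                min_sample_nonmissing = 0.75,
                                max_snv_missing = 1,
                                min_sample_present = 0.20,
                                present_threshold = 0.03) {
  stopifnot(all(c("sample", "snv", "alt_reads", "depth") %in% names(obs)))
  samples <- unique(obs$sample)
  snvs <- unique(obs$snv)
  depth <- matrix(NA_real_, length(samples), length(snvs),
                  dimnames = list(samples, snvs))
  vafm <- depth
  ij <- cbind(match(obs$sample, samples), match(obs$snv, snvs))
  depth[ij] <- obs$depth
  vafm[ij] <- obs$alt_reads / obs$depth
  depth[is.na(depth)] <- 0

  # (1) low-coverage cells are missing
  vafm[depth <= min_depth] <- NA

  dropped_samples <- character(0)
  dropped_snvs <- character(0)

  # (2) samples with too many missing cells
  nm_frac <- rowMeans(!is.na(vafm))
  drop_s <- rownames(vafm)[nm_frac < min_sample_nonmissing]
  dropped_samples <- c(dropped_samples, drop_s)
  vafm <- vafm[setdiff(rownames(vafm), drop_s), , drop = FALSE]

  # (3) SNVs with more than max_snv_missing missing cells
  if (nrow(vafm)) {
    miss <- colSums(is.na(vafm))
    drop_m <- colnames(vafm)[miss > max_snv_missing]
    dropped_snvs <- c(dropped_snvs, drop_m)
    vafm <- vafm[, setdiff(colnames(vafm), drop_m), drop = FALSE]
  }

  # (4) SNVs absent everywhere
  if (nrow(vafm) && ncol(vafm)) {
    pres <- call_presence(vafm, present_threshold)
    any_pres <- colSums(pres, na.rm = TRUE) > 0
    dropped_snvs <- c(dropped_snvs, colnames(vafm)[!any_pres])
    vafm <- vafm[, any_pres, drop = FALSE]
  }

  # (5) samples with too few present calls
  if (nrow(vafm) && ncol(vafm)) {
    pres <- call_presence(vafm, present_threshold)
    frac_pres <- rowSums(pres, na.rm = TRUE) / rowSums(!is.na(pres))
    drop_p <- rownames(vafm)[frac_pres <= min_sample_present]
    dropped_samples <- c(dropped_samples, drop_p)
    vafm <- vafm[setdiff(rownames(vafm), drop_p), , drop = FALSE]
  }

  empty <- nrow(vafm) == 0L || ncol(vafm) == 0L
  if (empty) message("tier-3 filtering left no samples or no SNVs")
  calls <- call_presence(vafm, present_threshold) + 0L
  info_cols <- intersect(c("snv", "chrom", "pos", "ref", "alt", "context"),
                         names(obs))
  snv_info <- unique(obs[obs$snv %in% colnames(vafm), info_cols, drop = FALSE])
  depth_sub <- depth[rownames(vafm), colnames(vafm), drop = FALSE]
  structure(list(calls = calls, vaf = vafm, depth = depth_sub, tier = 3L,
                 sample_tier = stats::setNames(rep(3L, nrow(vafm)), rownames(vafm)),
                 dropped_samples = dropped_samples,
                 dropped_snvs = dropped_snvs, snv_info = snv_info,
                 present_threshold = present_threshold, empty = empty),
            class = "tier_matrix")
}

#' @export
print.tier_matrix <- function(x, ...) {
  cat(sprintf("tier-%d matrix: %d samples x %d SNVs (%d samples, %d SNVs dropped)\n",
              x$tier, nrow(x$calls), ncol(x$calls),
              length(x$dropped_samples), length(x$dropped_snvs)))
  if (any(x$sample_tier == 4L)) {
    cat("tier-4 samples:", paste(names(x$sample_tier)[x$sample_tier == 4L],
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Promote samples with array-confirmed CCF to tier 4
#'
#' Samples with a matched SNP array whose cancer cell fraction reaches
#' `min_ccf` are flagged tier-4; samples without a CCF estimate stay
#' tier-3 with a warning.
#'
#' @param tm a `tier_matrix` from [apply_tier3_filters()].
#' @param sample_ccf named numeric vector of per-sample CCFs (samples with
#'   no matched array omitted or `NA`).
#' @param min_ccf promotion cutoff (inclusive).
#' @return the `tier_matrix` with `sample_tier` updated.
#' @export
promote_tier4 <- function(tm, sample_ccf, min_ccf = 0.30) {
  stopifnot(inherits(tm, "tier_matrix"))
  samples <- rownames(tm$calls)
  ccf <- sample_ccf[samples]
  missing_ccf <- samples[is.na(ccf)]
  if (length(missing_ccf)) {
    warning("no CCF for sample(s) ", paste(missing_ccf, collapse = ", "),
            "; kept at tier-3")
  }
  tier <- ifelse(!is.na(ccf) & ccf >= min_ccf, 4L, 3L)
  tm$sample_tier <- stats::setNames(as.integer(tier), samples)
  tm$tier <- if (any(tier == 4L)) 4L else 3L
  tm
}
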
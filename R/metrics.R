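# Progression metrics over per-patient phylogenies: normalized branch
# lengths and their survival correlation, early/late substitution spectra,
# and pairwise clonal-frequency configurations with cross-seeding calls.

#' Normalized phylogenetic branch lengths
#'
#' For each lesion, the ratio of the path length from the cancer-clade
#' most recent common ancestor (the first metastasizing divergence) to the
#' leaf, relative to the trunk (root-to-MRCA path).  Large ratios indicate
#' that most genomic change accumulated after dissemination started.
#'
#' @param tree rooted `phylo` with event-count branch lengths and an
#'   outgroup tip.
#' @param outgroup outgroup tip label.
#' @return list: `per_leaf` (named ratios), `mean`, `trunk_length`.
#' @export
normalized_branch_lengths <- function(tree, outgroup = "outgroup") {
  stopifnot(outgroup %in% tree$tip.label)
  cancer <- setdiff(tree$tip.label, outgroup)
  if (length(cancer) < 2L) stop("need at least 2 cancer leaves")
  tips <- match(cancer, tree$tip.label)
  mrca <- ape::getMRCA(tree, tips)
  pp <- .phylo_parent(tree)
  elen <- rep(NA_real_, length(pp$parent))
  elen[tree$edge[, 2L]] <- tree$edge.length
  pathlen <- function(from_anc, to) {
    v <- to; tot <- 0
    while (v != from_anc) { tot <- tot + elen[v]; v <- pp$parent[v] }
    tot
  }
  trunk <- pathlen(pp$root, mrca)
  if (!is.finite(trunk) || trunk <= 0) stop("undefined ratio: trunk length is 0")
  per_leaf <- vapply(tips, function(tp) pathlen(mrca, tp), numeric(1L))
  names(per_leaf) <- cancer
  per_leaf <- per_leaf / trunk
  list(per_leaf = per_leaf, mean = mean(per_leaf), trunk_length = trunk)
}

#' Correlation of mean normalized branch lengths with overall survival
#'
#' @param patient_means named per-patient mean normalized branch lengths.
#' @param survival named overall survival times (same patients).
#' @return list: `rho` (Spearman), `p_value`, `n`, `degenerate` flag (all
#'   tied input).
#' @export
survival_correlation <- function(patient_means, survival) {
  common <- intersect(names(patient_means), names(survival))
  if (length(common) < 4L) stop("need at least 4 patients")
  x <- patient_means[common]; y <- survival[common]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("degenerate input: all values tied")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(common),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(common),
       degenerate = FALSE)
}

#' Early/late substitution spectra
#'
#' Pyrimidine-strand-normalized counts over the six substitution classes,
#' split by phase (early = trunk, late = below the cancer MRCA), plus the
#' fraction of C>T substitutions occurring at NpCpG trinucleotides (the
#' APOBEC-associated pattern).
#'
#' @param snvs data.frame with `ref`, `alt`, `phase` (`"early"`/`"late"`)
#'   and optionally `context` (pyrimidine-strand trinucleotide).
#' @return data.frame: one row per (phase, class) with counts and
#'   within-phase frequencies; attribute `npcpg` gives the per-phase
#'   NpCpG C>T fraction.
#' @export
substitution_spectrum <- function(snvs) {
  stopifnot(all(c("ref", "alt", "phase") %in% names(snvs)))
  cls <- substitution_class(snvs$ref, snvs$alt)
  phases <- c("early", "late")
  out <- expand.grid(phase = phases, class = .SUB_CLASSES,
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(p, cl) sum(snvs$phase == p & cls == cl),
                      out$phase, out$class)
  tot <- tapply(out$count, out$phase, sum)[out$phase]
  out$frequency <- ifelse(tot > 0, out$count / tot, NA_real_)
  npcpg <- vapply(phases, function(p) {
    i <- snvs$phase == p & cls == "CG>TA"
    if (!any(i)) return(NA_real_)
    if (is.null(snvs$context)) return(NA_real_)
    ctx <- toupper(snvs$context[i])
    known <- nchar(ctx) == 3L & substr(ctx, 2L, 2L) == "C"
    if (!any(known)) return(NA_real_)
    mean(substr(ctx[known], 3L, 3L) == "G")
  }, numeric(1L))
  attr(out, "npcpg") <- npcpg
  out
}

#' Pairwise clonal-frequency configurations and cross-seeding calls
#'
#' For every SNV and ordered sample pair, assigns one of the seven
#' configurations of a two-sample clonal-frequency plot: (i) clonal in
#' both (ancestral); (ii)/(iii) private clonal; (iv)/(v) private
#' subclonal; (vi)/(vii) clonal in one sample but subclonal in the other
#' — configurations incompatible with a strict tree and suggestive of
#' horizontal seeding.  A cross-seeding call donor -> recipient is emitted
#' when at least `k_min` SNVs private-clonal to the donor's clade appear
#' subclonal in the recipient.
#'
#' @param cf samples x SNVs matrix of clonal frequencies (`NA` where the
#'   SNV is absent or unmeasured).
#' @param present samples x SNVs logical/0-1 matrix of presence calls.
#' @param tree rooted `phylo` over the samples (outgroup tolerated); used
#'   to delimit the donor clade.
#' @param clonal_cutoff clonal frequency at or above which an SNV counts
#'   as fully clonal.
#' @param k_min minimum supporting SNVs for a cross-seeding call.
#' @param outgroup outgroup tip label.
#' @return list: `configurations` (long data.frame snv x ordered pair),
#'   `calls` (data.frame donor, recipient, n_support, snvs).
#' @export
classify_pairwise <- function(cf, present, tree, clonal_cutoff = 0.8,
                              k_min = 5L, outgroup = "outgroup") {
  samples <- rownames(cf)
  stopifnot(!is.null(samples), identical(dim(cf), dim(present)))
  if (outgroup %in% tree$tip.label) tree <- ape::drop.tip(tree, outgroup)
  stopifnot(all(samples %in% tree$tip.label))
  pres <- present > 0 & !is.na(present)
  status <- matrix("absent", nrow(cf), ncol(cf), dimnames = dimnames(cf))
  status[pres & !is.na(cf) & cf >= clonal_cutoff] <- "clonal"
  status[pres & !is.na(cf) & cf < clonal_cutoff] <- "subclonal"
  status[pres & is.na(cf)] <- "subclonal"   # present but unquantified

  class_of <- function(s1, s2) {
    if (s1 == "clonal" && s2 == "clonal") return("i")
    if (s1 == "clonal" && s2 == "absent") return("ii")
    if (s1 == "absent" && s2 == "clonal") return("iii")
    if (s1 == "subclonal" && s2 == "absent") return("iv")
    if (s1 == "absent" && s2 == "subclonal") return("v")
    if (s1 == "clonal" && s2 == "subclonal") return("vi")
    if (s1 == "subclonal" && s2 == "clonal") return("vii")
    if (s1 == "subclonal" && s2 == "subclonal") return("both_subclonal")
    NA_character_   # absent in both: not a shared or private mutation
  }

  pairs <- expand.grid(sample1 = samples, sample2 = samples,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$sample1 != pairs$sample2, , drop = FALSE]
  cfg <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(pi) {
    s1 <- pairs$sample1[pi]; s2 <- pairs$sample2[pi]
    cl <- vapply(seq_len(ncol(cf)), function(j)
      class_of(status[s1, j], status[s2, j]), character(1L))
    data.frame(sample1 = s1, sample2 = s2, snv = colnames(cf),
               configuration = cl, stringsAsFactors = FALSE)
  }))
  cfg <- cfg[!is.na(cfg$configuration), , drop = FALSE]

  # donor clade = leaves of the subtree on the donor's side of
  # MRCA(donor, recipient)
  clades <- .phylo_clades(tree)
  pp <- .phylo_parent(tree)
  donor_clade <- function(d, r) {
    di <- match(d, tree$tip.label); ri <- match(r, tree$tip.label)
    mrca <- ape::getMRCA(tree, c(di, ri))
    v <- di
    while (pp$parent[v] != mrca) v <- pp$parent[v]
    tree$tip.label[clades[[v]]]
  }

  calls <- list()
  for (pi in seq_len(nrow(pairs))) {
    d <- pairs$sample1[pi]; r <- pairs$sample2[pi]
    C <- intersect(donor_clade(d, r), samples)
    outside <- setdiff(samples, c(C, r))
    support <- character(0)
    for (j in seq_len(ncol(cf))) {
      if (status[d, j] != "clonal" || status[r, j] != "subclonal") next
      if (any(status[setdiff(C, d), j] == "subclonal")) next
      if (length(outside) && any(status[outside, j] != "absent")) next
      if (!length(setdiff(C, d)) && !length(outside)) next
      # must be private to the donor clade, i.e. absent somewhere
      if (all(status[setdiff(samples, r), j] == "clonal")) next
      support <- c(support, colnames(cf)[j])
    }
    if (length(support) >= k_min) {
      calls[[length(calls) + 1L]] <- data.frame(
        donor = d, recipient = r, n_support = length(support),
        snvs = paste(support, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(donor = character(0), recipient = character(0),
               n_support = integer(0), snvs = character(0),
               stringsAsFactors = FALSE)
  list(configurations = cfg, calls = calls)
}

#' Infer the dissemination mode of a patient
#'
#' `"metastatic_precursor"` when every metastasis descends from a common
#' ancestor that excludes the primary lesion (monoclonal seeding followed
#' by metastasis-to-metastasis spread); `"multiple_seeding"` otherwise
#' (the primary is interleaved with the metastases).
#'
#' @param tree rooted `phylo` with an outgroup tip.
#' @param primary label of the primary lesion.
#' @param outgroup outgroup tip label.
#' @return character mode.
#' @export
infer_dissemination_mode <- function(tree, primary = "P",
                                     outgroup = "outgroup") {
  if (outgroup %in% tree$tip.label) tree <- ape::drop.tip(tree, outgroup)
  stopifnot(primary %in% tree$tip.label)
  mets <- setdiff(tree$tip.label, primary)
  if (length(mets) < 2L) return("metastatic_precursor")
  mrca <- ape::getMRCA(tree, match(mets, tree$tip.label))
  clades <- .phylo_clades(tree)
  below <- tree$tip.label[clades[[mrca]]]
  if (primary %in% below) "multiple_seeding" else "metastatic_precursor"
}
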
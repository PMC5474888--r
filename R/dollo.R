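# Dollo-parsimony phylogenies from binary SNV presence/absence matrices.
#
# Under the Dollo criterion each mutation is gained exactly once (at the
# most recent common ancestor of the samples carrying it) and may only be
# lost afterwards; the score of a tree is the total number of losses
# (reversions) over all characters.  Trees are rooted with an all-absent
# germline outgroup.  Missing cells carry no presence information and
# contribute no cost.

# Vectorized Dollo score of one (possibly partial) tree.
# parent/root: internal tree representation; leaves: leaf ids present;
# X: length(leaves) x n_char matrix of 1/0/NA aligned to `leaves`.
# anc: optional precomputed ancestor matrix.
.dollo_score_fast <- function(parent, root, leaves, X, anc = NULL,
                              post = NULL, per_char = FALSE) {
  n <- length(parent)
  m <- ncol(X)
  if (is.null(post)) post <- .tree_postorder(parent, root)
  if (is.null(anc)) anc <- .tree_anc(parent, root)
  kids <- .tree_children(parent)

  P <- matrix(FALSE, n, m)   # any present leaf below
  A <- matrix(FALSE, n, m)   # any absent leaf below
  CP <- matrix(0L, n, m)     # count of present leaves below
  sizes <- integer(n)
  P[leaves, ] <- !is.na(X) & X == 1L
  A[leaves, ] <- !is.na(X) & X == 0L
  CP[leaves, ] <- P[leaves, , drop = FALSE] + 0L
  sizes[leaves] <- 1L
  for (v in post) {
    kv <- kids[[v]]
    if (length(kv)) {
      P[v, ] <- P[kv[1L], ] | P[kv[2L], ]
      A[v, ] <- A[kv[1L], ] | A[kv[2L], ]
      CP[v, ] <- CP[kv[1L], ] + CP[kv[2L], ]
      sizes[v] <- sizes[kv[1L]] + sizes[kv[2L]]
    }
  }
  np <- CP[root, ]                       # present leaves per character
  # gain node g = smallest subtree containing all present leaves
  bad <- CP != matrix(np, n, m, byrow = TRUE)
  M <- matrix(sizes, n, m) + 1e9 * bad
  g <- max.col(-t(M), ties.method = "first")
  # state 1 exactly at nodes below-or-equal g that contain a present leaf
  state1 <- P & t(anc[g, , drop = FALSE])
  vs <- setdiff(which(!is.na(parent)), root)
  lossmat <- state1[parent[vs], , drop = FALSE] &
    !P[vs, , drop = FALSE] & A[vs, , drop = FALSE]
  losses <- colSums(lossmat)
  losses[np == 0L] <- 0L
  if (per_char) list(score = sum(losses), losses = losses, gain = g) else sum(losses)
}

# Slow per-character reference scorer used as an independent check of the
# vectorized scorer: places the single gain on every feasible node and takes
# the cheapest loss assignment by recursion.
.dollo_score_naive <- function(parent, root, leaves, X) {
  kids <- .tree_children(parent)
  total <- 0
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    pres <- leaves[!is.na(x) & x == 1L]
    if (!length(pres)) next
    anyp <- function(v) {
      if (v %in% leaves) return(v %in% pres)
      any(vapply(kids[[v]], anyp, logical(1L)))
    }
    d1 <- function(v) {  # min losses in subtree(v) given incoming state 1
      if (v %in% leaves) {
        xv <- x[match(v, leaves)]
        if (is.na(xv) || xv == 1L) return(0)
        return(1)
      }
      keep <- sum(vapply(kids[[v]], d1, numeric(1L)))
      drop <- if (anyp(v)) Inf else 1
      min(keep, drop)
    }
    best <- Inf
    for (gg in which(!is.na(parent))) {
      ok <- all(vapply(pres, function(p) gg == p || isTRUE(.is_anc(parent, gg, p)), logical(1L)))
      if (!ok) next
      cost <- if (gg %in% leaves) 0 else sum(vapply(kids[[gg]], d1, numeric(1L)))
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

.is_anc <- function(parent, a, v) {
  u <- v
  while (!is.na(u) && u > 0L) {
    if (u == a) return(TRUE)
    u <- parent[u]
  }
  FALSE
}

#' Dollo score of a fixed tree
#'
#' Number of loss events (reversions) required to explain a binary
#' presence/absence matrix on a given rooted topology under Dollo parsimony,
#' with each character gained once at the MRCA of the samples carrying it.
#' Missing cells (`NA`) are uninformative and never generate cost.
#'
#' @param tree an `ape::phylo` whose tip labels include the row names of
#'   `calls`; an outgroup tip (default label `"outgroup"`) is ignored.
#' @param calls samples x SNVs matrix of 1 (present), 0 (absent), `NA`
#'   (missing).
#' @param outgroup tip label of the germline outgroup, dropped before
#'   scoring.
#' @return integer Dollo score (total losses over characters).
#' @export
dollo_score <- function(tree, calls, outgroup = "outgroup") {
  if (outgroup %in% tree$tip.label) {
    tree <- ape::drop.tip(tree, outgroup)
  }
  stopifnot(all(tree$tip.label %in% rownames(calls)))
  pp <- .phylo_parent(tree)
  X <- calls[pp$labels, , drop = FALSE]
  .dollo_score_fast(pp$parent, pp$root, seq_len(pp$ntip), X)
}

#' Infer minimum-reversion phylogenies by branch-and-bound
#'
#' Searches rooted binary topologies over the cancer samples for the
#' phylogenies minimizing the Dollo score (number of reversions), rooting
#' with an all-absent germline outgroup.  The search is exhaustive: leaves
#' are added stepwise and a partial topology is abandoned as soon as its
#' score (a lower bound for any completion) exceeds the best complete score
#' found.  All co-optimal topologies are returned.
#'
#' @param calls samples x SNVs matrix of 1/0/`NA` (e.g. the calls of a
#'   tier-3 matrix from [apply_tier3_filters()]).
#' @param method `"auto"` (exhaustive up to 9 leaves, else heuristic),
#'   `"exhaustive"`, or `"heuristic"` (neighbour joining on Manhattan
#'   distances; result flagged).
#' @param outgroup label for the germline outgroup tip.
#' @return list with `trees` (list of `phylo`, each with ACCTRAN branch
#'   lengths), `score`, and `heuristic` flag.
#' @export
dollo_search <- function(calls, method = c("auto", "exhaustive", "heuristic"),
                         outgroup = "outgroup") {
  method <- match.arg(method)
  k <- nrow(calls)
  if (k < 3L) stop("need at least 3 cancer samples")
  if (method == "auto") method <- if (k <= 9L) "exhaustive" else "heuristic"
  if (method == "exhaustive" && k > 9L) {
    stop("exhaustive search is limited to 9 leaves; use method = \"heuristic\"")
  }
  labels <- rownames(calls)
  X <- calls
  storage.mode(X) <- "integer"

  if (method == "heuristic") {
    D <- stats::dist(ifelse(is.na(X), 0.5, X), method = "manhattan")
    phy <- ape::nj(D)
    phy <- ape::unroot(phy)
    # root on the edge giving the smallest Dollo score
    best <- NULL
    for (tip in phy$tip.label) {
      cand <- ape::root(phy, outgroup = tip, resolve.root = TRUE)
      sc <- dollo_score(cand, X, outgroup = outgroup)
      if (is.null(best) || sc < best$score) best <- list(tree = cand, score = sc)
    }
    tr <- .attach_outgroup(best$tree, outgroup)
    tr <- .acctran_lengths(tr, X, outgroup)
    out <- list(trees = list(tr), score = best$score, heuristic = TRUE)
    return(out)
  }

  nslot <- 2L * k - 1L
  start <- rep(NA_integer_, nslot)
  start[1:2] <- k + 1L
  start[k + 1L] <- 0L

  best <- Inf
  ties <- list()
  recurse <- function(parent, root, nxt, added) {
    sc <- .dollo_score_fast(parent, root, seq_len(added),
                            X[seq_len(added), , drop = FALSE])
    if (sc > best) return(invisible())
    if (added == k) {
      if (sc < best) {
        best <<- sc
        ties <<- list(list(parent = parent, root = root))
      } else {
        ties[[length(ties) + 1L]] <<- list(parent = parent, root = root)
      }
      return(invisible())
    }
    j <- added + 1L
    for (cc in which(!is.na(parent))) {
      p2 <- parent
      w <- nxt
      r2 <- root
      if (cc == root) {
        p2[w] <- 0L
        r2 <- w
      } else {
        p2[w] <- p2[cc]
      }
      p2[cc] <- w
      p2[j] <- w
      recurse(p2, r2, w + 1L, j)
    }
    invisible()
  }
  recurse(start, k + 1L, k + 2L, 2L)

  trees <- lapply(ties, function(tr) {
    phy <- .ptree_to_phylo(tr$parent, tr$root, labels, outgroup)
    .acctran_lengths(phy, X, outgroup)
  })
  list(trees = trees, score = best, heuristic = FALSE)
}

.attach_outgroup <- function(phy, outgroup = "outgroup") {
  nwk <- ape::write.tree(phy)
  ape::read.tree(text = paste0("(", outgroup, ",", sub(";$", "", nwk), ");"))
}

.acctran_lengths <- function(phy, calls, outgroup = "outgroup") {
  rec <- acctran_reconstruct(phy, calls, outgroup = outgroup)
  rec$tree
}

#' Break ties between co-optimal SNV trees with the CNA tree
#'
#' Among equally parsimonious Dollo trees, returns the one closest to the
#' copy-number phylogeny of the same patient by unrooted Robinson-Foulds
#' distance; residual ties are broken deterministically by lexicographic
#' Newick order.
#'
#' @param trees list of `phylo` (e.g. `dollo_search()$trees`).
#' @param cna_tree `phylo` over the same (or a subset of the) leaves.
#' @return single `phylo`.
#' @export
break_ties_with_cna <- function(trees, cna_tree) {
  stopifnot(length(trees) >= 1L)
  if (length(trees) == 1L) return(trees[[1L]])
  shared <- Reduce(intersect, c(lapply(trees, function(t) t$tip.label),
                                list(cna_tree$tip.label)))
  if (length(shared) < 3L) stop("leaf sets of SNV and CNA trees are disjoint or too small")
  ref <- ape::unroot(ape::keep.tip(cna_tree, shared))
  d <- vapply(trees, function(t) {
    tt <- ape::unroot(ape::keep.tip(t, shared))
    as.numeric(phangorn::RF.dist(tt, ref))
  }, numeric(1L))
  cand <- which(d == min(d))
  if (length(cand) > 1L) {
    nwk <- vapply(trees[cand], function(t)
      ape::write.tree(ape::ladderize(t)), character(1L))
    cand <- cand[order(nwk)[1L]]
  }
  trees[[cand[1L]]]
}

#' Ancestral state reconstruction under accelerated transformation
#'
#' Places, for each SNV, the single Dollo gain as early as compatible with
#' the minimum-loss reconstruction (the branch into the MRCA of the carrying
#' samples) and losses as high as possible below it.  Branch lengths of the
#' returned tree are the number of state changes (gains + losses) assigned
#' to each branch.
#'
#' @param tree rooted `phylo` including the outgroup tip.
#' @param calls samples x SNVs matrix of 1/0/`NA`.
#' @param outgroup outgroup tip label.
#' @return object of class `dollo_reconstruction`: list with `tree` (branch
#'   lengths = event counts), `states` (node x SNV 0/1 matrix, ape node
#'   numbering), `gain_node` (named vector: node whose parent branch carries
#'   the gain), `loss_nodes` (list of nodes whose parent branch carries a
#'   loss), `excluded` (characters absent everywhere).
#' @export
acctran_reconstruct <- function(tree, calls, outgroup = "outgroup") {
  if (!outgroup %in% tree$tip.label) tree <- .attach_outgroup(tree, outgroup)
  pp <- .phylo_parent(tree)
  n <- length(pp$parent)
  samp <- setdiff(pp$labels, outgroup)
  stopifnot(all(samp %in% rownames(calls)))
  m <- ncol(calls)
  X <- matrix(NA_integer_, pp$ntip, m, dimnames = list(pp$labels, colnames(calls)))
  X[samp, ] <- as.integer(calls[samp, , drop = FALSE])
  X[outgroup, ] <- 0L

  post <- .tree_postorder(pp$parent, pp$root)
  anc <- .tree_anc(pp$parent, pp$root)
  kids <- .tree_children(pp$parent)

  P <- matrix(FALSE, n, m); A <- matrix(FALSE, n, m)
  CP <- matrix(0L, n, m); NM <- matrix(TRUE, n, m)  # NM: subtree all-missing
  sizes <- integer(n)
  tipids <- seq_len(pp$ntip)
  P[tipids, ] <- !is.na(X) & X == 1L
  A[tipids, ] <- !is.na(X) & X == 0L
  NM[tipids, ] <- is.na(X)
  CP[tipids, ] <- P[tipids, , drop = FALSE] + 0L
  sizes[tipids] <- 1L
  for (v in post) {
    kv <- kids[[v]]
    if (length(kv)) {
      P[v, ] <- Reduce(`|`, lapply(kv, function(x) P[x, ]))
      A[v, ] <- Reduce(`|`, lapply(kv, function(x) A[x, ]))
      NM[v, ] <- Reduce(`&`, lapply(kv, function(x) NM[x, ]))
      CP[v, ] <- Reduce(`+`, lapply(kv, function(x) CP[x, ]))
      sizes[v] <- sum(sizes[kv])
    }
  }
  np <- CP[pp$root, ]
  excluded <- which(np == 0L)
  bad <- CP != matrix(np, n, m, byrow = TRUE)
  M <- matrix(sizes, n, m) + 1e9 * bad
  g <- max.col(-t(M), ties.method = "first")
  belowEq <- t(anc[g, , drop = FALSE])
  # accelerated states: 1 below g wherever a present leaf remains or the
  # subtree is entirely missing (no loss is then postulated)
  states <- belowEq & (P | NM)
  states[, excluded] <- FALSE

  vs <- setdiff(which(!is.na(pp$parent)), pp$root)
  par_vs <- pp$parent[vs]
  lossmat <- states[par_vs, , drop = FALSE] & !states[vs, , drop = FALSE] &
    belowEq[vs, , drop = FALSE]
  if (length(excluded)) lossmat[, excluded] <- FALSE

  gain_node <- g
  gain_node[excluded] <- NA_integer_
  names(gain_node) <- colnames(calls)
  loss_nodes <- lapply(seq_len(m), function(j) vs[lossmat[, j]])
  names(loss_nodes) <- colnames(calls)

  # per-branch event counts; branch of node v = edge (parent[v] -> v)
  tab <- table(factor(gain_node[!is.na(gain_node)], levels = seq_len(n)))
  events <- as.integer(tab)
  lcounts <- integer(n)
  lv <- unlist(loss_nodes, use.names = FALSE)
  if (length(lv)) {
    tl <- table(factor(lv, levels = seq_len(n)))
    lcounts <- as.integer(tl)
  }
  events <- events + lcounts
  tree$edge.length <- events[tree$edge[, 2L]]

  if (length(excluded)) {
    warning(sprintf("%d character(s) absent in every sample were excluded", length(excluded)))
  }
  structure(list(tree = tree, states = states + 0L, gain_node = gain_node,
                 loss_nodes = loss_nodes,
                 excluded = colnames(calls)[excluded],
                 losses_per_char = vapply(loss_nodes, length, integer(1L)),
                 outgroup = outgroup),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("Dollo/ACCTRAN reconstruction:", ncol(x$states), "characters,",
      sum(x$losses_per_char), "losses\n")
  invisible(x)
}

#' Verify predicted reversions against copy-number losses
#'
#' Each loss predicted by the ancestral reconstruction (an SNV present in an
#' ancestor but undetected in descendant samples) is checked against the
#' allele-specific copy-number profiles: a reversion is supported when the
#' affected samples show a loss (drop in total, major or minor copies
#' relative to every sample still carrying the SNV) at the mutated segment.
#' Predicted reversions whose detection power falls below
#' `power_threshold` in an affected sample are flagged possible false
#' negatives rather than asserted.
#'
#' @param rec a `dollo_reconstruction`.
#' @param snv_info data.frame with columns `snv`, `chrom`, `pos`.
#' @param profiles segment data.frame (`sample`, `chrom`, `start`, `end`,
#'   `total`, `major`, `minor`) with shared boundaries across samples.
#' @param sample_ccf named vector of per-sample cancer cell fractions.
#' @param depths samples x SNVs matrix of sequencing depths.
#' @param e sequencing error rate.
#' @param power_threshold minimum detection power to assert a reversion.
#' @param present_threshold VAF presence cutoff used for the power
#'   computation.
#' @return data.frame, one row per (SNV, affected sample): loss branch,
#'   power, copy-state annotation and `status` in
#'   `reversion_cna_supported` / `unexplained` / `possible_false_negative` /
#'   `unannotated` (SNV outside all segments).
#' @export
verify_reversions <- function(rec, snv_info, profiles, sample_ccf, depths,
                              e = 0.01, power_threshold = 0.95,
                              present_threshold = 0.03) {
  tree <- rec$tree
  clades <- .phylo_clades(tree)
  labs <- tree$tip.label
  out <- list()
  seg <- profiles
  for (j in seq_along(rec$loss_nodes)) {
    ln <- rec$loss_nodes[[j]]
    if (!length(ln)) next
    snv <- names(rec$loss_nodes)[j]
    info <- snv_info[snv_info$snv == snv, , drop = FALSE]
    carriers_nodes <- which(rec$states[seq_along(labs), j] == 1L)
    carriers <- labs[carriers_nodes]
    for (v in ln) {
      affected <- labs[clades[[v]]]
      affected <- setdiff(affected, rec$outgroup)
      ref_samples <- setdiff(carriers, affected)
      for (s in affected) {
        srow <- .locate_segment(seg, s, info$chrom[1L], info$pos[1L])
        ann <- list(segment_chrom = NA, segment_start = NA, segment_end = NA,
                    loss_total = NA, loss_major = NA, loss_minor = NA)
        supported <- FALSE
        unannotated <- FALSE
        qt_s <- 2L
        if (is.null(srow)) {
          unannotated <- TRUE
        } else {
          qt_s <- srow$total
          refrows <- do.call(rbind, lapply(ref_samples, function(r)
            .locate_segment(seg, r, info$chrom[1L], info$pos[1L])))
          if (!is.null(refrows) && nrow(refrows)) {
            ann$segment_chrom <- srow$chrom
            ann$segment_start <- srow$start
            ann$segment_end <- srow$end
            ann$loss_total <- srow$total < min(refrows$total)
            ann$loss_major <- srow$major < min(refrows$major)
            ann$loss_minor <- srow$minor < min(refrows$minor)
            supported <- isTRUE(ann$loss_total) || isTRUE(ann$loss_major) ||
              isTRUE(ann$loss_minor)
          }
        }
        alpha <- unname(sample_ccf[s])
        nd <- depths[s, snv]
        f <- expected_vaf(1L, max(qt_s, 1L), alpha)
        pw <- detection_power(nd, f, e = e, threshold = present_threshold)
        status <- if (pw < power_threshold) {
          "possible_false_negative"
        } else if (unannotated) {
          "unannotated"
        } else if (supported) {
          "reversion_cna_supported"
        } else {
          "unexplained"
        }
        out[[length(out) + 1L]] <- data.frame(
          snv = snv, loss_node = v, sample = s, power = pw, status = status,
          loss_total = ann$loss_total, loss_major = ann$loss_major,
          loss_minor = ann$loss_minor, segment_chrom = ann$segment_chrom,
          segment_start = ann$segment_start, segment_end = ann$segment_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(snv = character(0), loss_node = integer(0),
                      sample = character(0), power = numeric(0),
                      status = character(0), loss_total = logical(0),
                      loss_major = logical(0), loss_minor = logical(0),
                      segment_chrom = character(0), segment_start = numeric(0),
                      segment_end = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.locate_segment <- function(seg, sample, chrom, pos) {
  hit <- seg[seg$sample == sample & seg$chrom == chrom &
               seg$start <= pos & seg$end >= pos, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  hit[1L, ]
}
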
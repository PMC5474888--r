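# Minimum-event phylogenies from allele-specific integer copy-number
# profiles.
#
# The elementary event adds +1 or -1 to a contiguous run of loci of one
# allele; an event may never raise an allele from 0 (no rescue of a deleted
# allele) and counts stay non-negative.  Near-diploid patients are rooted at
# a uniform 2/1 (total/major) outgroup; tetraploid patients are rooted by
# scoring the four candidate post-duplication ancestral states.

#' Directed segmental event distance between two allele vectors
#'
#' Minimum number of events transforming integer vector `a` into `b`, where
#' one event adds +1 or -1 to a contiguous run of loci, counts must stay
#' non-negative and no event raises an allele from 0.  The minimum equals
#' the sum of positive "ascents" of the required gain and loss profiles;
#' loci fixed at zero split the vector into independent blocks.
#'
#' @param a,b non-negative integer vectors of equal length (single allele).
#' @return number of events, or `Inf` when `b` is unreachable (`b > 0`
#'   where `a == 0`).
#' @export
directed_event_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (!length(a)) return(0)
  if (any(a < 0) || any(b < 0)) stop("copy numbers must be non-negative")
  if (any(a == 0 & b > 0)) return(Inf)
  d <- b - a
  g <- pmax(d, 0)
  l <- pmax(-d, 0)
  sum(pmax(g - c(0, g[-length(g)]), 0)) + sum(pmax(l - c(0, l[-length(l)]), 0))
}

#' Symmetric pairwise dissimilarity between two allele-specific profiles
#'
#' Minimum over common ancestor profiles `c` of
#' `d(c -> p) + d(c -> q)` under the directed segmental event distance,
#' summed over the major and minor alleles.  Because the directed distance
#' decomposes into per-adjacent-locus terms, the minimization over ancestors
#' is exact by dynamic programming over ancestor states at each locus.
#'
#' @param p,q profiles: data.frames/lists with `major` and `minor` integer
#'   vectors over shared segments (optionally `chrom`; events never span
#'   chromosomes).
#' @return total event count (numeric; `Inf` if no feasible ancestor).
#' @export
pairwise_dissimilarity <- function(p, q) {
  stopifnot(length(p$major) == length(q$major),
            length(p$minor) == length(q$minor))
  chrom <- if (!is.null(p$chrom)) p$chrom else rep(1L, length(p$major))
  tot <- 0
  for (ch in unique(chrom)) {
    i <- chrom == ch
    tot <- tot + .ancestor_dp(p$major[i], q$major[i]) +
      .ancestor_dp(p$minor[i], q$minor[i])
  }
  tot
}

# min over ancestor vectors c of d(c->x) + d(c->y) for one allele,
# exploiting that the ascent formula makes the cost pairwise in
# (c[i-1], c[i]).
.ancestor_dp <- function(x, y) {
  L <- length(x)
  K <- max(x, y, 1L)
  states <- 0:K
  S <- length(states)
  step_cost <- function(cprev, gprev_x, lprev_x, gprev_y, lprev_y, i) {
    # vectorized over states at locus i
    gx <- pmax(x[i] - states, 0); lx <- pmax(states - x[i], 0)
    gy <- pmax(y[i] - states, 0); ly <- pmax(states - y[i], 0)
    cost <- pmax(gx - gprev_x, 0) + pmax(lx - lprev_x, 0) +
      pmax(gy - gprev_y, 0) + pmax(ly - lprev_y, 0)
    cost[states == 0L & (x[i] > 0L | y[i] > 0L)] <- Inf
    cost
  }
  # dp[s]: best cost of prefix ending with ancestor state s at locus i
  gx <- pmax(x[1L] - states, 0); lx <- pmax(states - x[1L], 0)
  gy <- pmax(y[1L] - states, 0); ly <- pmax(states - y[1L], 0)
  dp <- gx + lx + gy + ly
  dp[states == 0L & (x[1L] > 0L | y[1L] > 0L)] <- Inf
  if (L >= 2L) {
    for (i in 2:L) {
      ndp <- rep(Inf, S)
      for (sprev in seq_len(S)) {
        if (!is.finite(dp[sprev])) next
        cp <- states[sprev]
        gpx <- max(x[i - 1L] - cp, 0); lpx <- max(cp - x[i - 1L], 0)
        gpy <- max(y[i - 1L] - cp, 0); lpy <- max(cp - y[i - 1L], 0)
        cand <- dp[sprev] + step_cost(cp, gpx, lpx, gpy, lpy, i)
        ndp <- pmin(ndp, cand)
      }
      dp <- ndp
    }
  }
  min(dp)
}

# ---------------------------------------------------------------------------
# Sankoff-style per-locus per-allele parsimony on a fixed topology.
# Transition cost parent u -> child v is |u - v|, infinite for 0 -> v > 0.
# ---------------------------------------------------------------------------

.cn_trans_cost <- function(states) {
  S <- length(states)
  Tm <- abs(outer(states, states, "-"))
  Tm[states == 0L, states > 0L] <- Inf
  Tm
}

# minimal cost of one locus/allele on topology (parent, root) with leaf
# values `vals` (aligned to leaf ids 1..k) and fixed outgroup value r.
.sankoff_locus <- function(parent, root, post, kids, leaves, vals, r,
                           backtrack = FALSE) {
  states <- seq.int(0L, max(vals, r))
  S <- length(states)
  Tm <- .cn_trans_cost(states)
  n <- length(parent)
  cost <- matrix(Inf, n, S)
  for (i in seq_along(leaves)) {
    cost[leaves[i], ] <- ifelse(states == vals[i], 0, Inf)
  }
  choice <- if (backtrack) array(NA_integer_, c(n, S)) else NULL
  for (v in post) {
    kv <- kids[[v]]
    if (!length(kv)) next
    acc <- rep(0, S)
    for (ch in kv) {
      # for each parent state s: min over child state s' of cost + T
      m <- sweep(Tm, 2L, cost[ch, ], "+")     # m[s, s'] = T + cost(child)
      best <- apply(m, 1L, min)
      acc <- acc + best
      if (backtrack) {
        pick <- apply(m, 1L, which.min)
        attr(choice, paste(v, ch)) <- pick
      }
    }
    cost[v, ] <- acc
  }
  ridx <- match(r, states)
  total <- min(cost[root, ] + Tm[ridx, ])
  if (!backtrack) return(total)
  # recover states top-down (smallest optimal state index on ties)
  st <- rep(NA_integer_, n)
  sroot <- which.min(cost[root, ] + Tm[ridx, ])
  st[root] <- states[sroot]
  ord <- rev(post)
  for (v in ord) {
    kv <- kids[[v]]
    for (ch in kv) {
      pick <- attr(choice, paste(v, ch))
      st[ch] <- states[pick[match(st[v], states)]]
    }
  }
  list(total = total, states = st, root_state = r)
}

#' Build a minimum-event copy-number phylogeny
#'
#' Exhaustive search over rooted binary topologies (up to 7 samples)
#' minimizing the total number of copy-number events, with internal-node
#' profiles optimized per locus and per allele by dynamic programming over
#' integer states under the segmental-event cost and the no-0-to-1 rule.
#' Near-diploid patients are rooted at a uniform diploid 2/1 outgroup; for
#' tetraploid patients build the tree in `"diploid"` mode first and then
#' apply [wgd_root()].  Branch lengths are the event counts assigned to each
#' branch.
#'
#' @param profiles data.frame (`sample`, `chrom`, `start`, `end`, `total`,
#'   `major`, `minor`) with identical segment boundaries in all samples.
#' @param root_major,root_minor outgroup allele counts (defaults 1/1, the
#'   diploid 2/1 state).
#' @param outgroup outgroup tip label.
#' @param max_exhaustive maximum number of leaves for exhaustive search;
#'   above it a neighbour-joining topology is refit by the same dynamic
#'   programme and the result is flagged `heuristic`.
#' @return `phylo` with outgroup tip and event-count branch lengths;
#'   attributes `total_events`, `n_tied` (co-optimal topologies) and
#'   `heuristic`.
#' @export
build_cna_tree <- function(profiles, root_major = 1L, root_minor = 1L,
                           outgroup = "outgroup", max_exhaustive = 7L) {
  pm <- .profiles_to_matrices(profiles)
  k <- nrow(pm$major)
  if (k < 3L) stop("need at least 3 samples")
  labels <- rownames(pm$major)

  if (k > max_exhaustive) {
    D <- .dissimilarity_matrix(pm)
    phy <- ape::nj(stats::as.dist(D))
    topo <- .phylo_to_ptree_topo(ape::root(phy, outgroup = labels[1L],
                                           resolve.root = TRUE), labels)
    cand <- list(topo)
    heuristic <- TRUE
  } else {
    cand <- .enumerate_topologies(k)
    heuristic <- FALSE
  }

  scores <- vapply(cand, function(tr) {
    .cn_tree_score(tr, pm, root_major, root_minor)
  }, numeric(1L))
  best <- which(scores == min(scores))
  tr <- cand[[best[1L]]]
  fit <- .cn_tree_fit(tr, pm, root_major, root_minor)
  phy <- .ptree_to_phylo(tr$parent, tr$root, labels, outgroup,
                         lengths = fit$edge_events,
                         trunk_length = fit$trunk_events)
  phy$edge.length[is.na(phy$edge.length)] <- 0
  attr(phy, "total_events") <- min(scores)
  attr(phy, "n_tied") <- length(best)
  attr(phy, "heuristic") <- heuristic
  phy
}

.profiles_to_matrices <- function(profiles) {
  stopifnot(all(c("sample", "chrom", "start", "end", "major", "minor") %in%
                  names(profiles)))
  key <- paste(profiles$chrom, profiles$start, profiles$end, sep = ":")
  segs <- unique(data.frame(chrom = profiles$chrom, start = profiles$start,
                            end = profiles$end, key = key,
                            stringsAsFactors = FALSE))
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  samples <- unique(profiles$sample)
  mk <- function(col) {
    m <- matrix(NA_integer_, length(samples), nrow(segs),
                dimnames = list(samples, segs$key))
    m[cbind(match(profiles$sample, samples), match(key, segs$key))] <-
      as.integer(profiles[[col]])
    if (anyNA(m)) stop("samples do not share identical segment boundaries")
    m
  }
  list(major = mk("major"), minor = mk("minor"), segments = segs)
}

.dissimilarity_matrix <- function(pm) {
  k <- nrow(pm$major)
  D <- matrix(0, k, k, dimnames = list(rownames(pm$major), rownames(pm$major)))
  chrom <- pm$segments$chrom
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      D[i, j] <- D[j, i] <- pairwise_dissimilarity(
        list(major = pm$major[i, ], minor = pm$minor[i, ], chrom = chrom),
        list(major = pm$major[j, ], minor = pm$minor[j, ], chrom = chrom))
    }
  }
  D
}

.cn_tree_score <- function(tr, pm, root_major, root_minor) {
  kids <- .tree_children(tr$parent)
  leaves <- seq_len(nrow(pm$major))
  tot <- 0
  for (allele in c("major", "minor")) {
    vals <- pm[[allele]]
    r <- if (allele == "major") root_major else root_minor
    # dedupe identical locus patterns
    patt <- apply(vals, 2L, paste, collapse = ",")
    up <- !duplicated(patt)
    counts <- table(patt)[patt[up]]
    idx <- which(up)
    for (ii in seq_along(idx)) {
      sc <- .sankoff_locus(tr$parent, tr$root, tr$post, kids, leaves,
                           vals[, idx[ii]], r)
      tot <- tot + sc * as.integer(counts[ii])
    }
  }
  tot
}

.cn_tree_fit <- function(tr, pm, root_major, root_minor) {
  kids <- .tree_children(tr$parent)
  leaves <- seq_len(nrow(pm$major))
  n <- length(tr$parent)
  edge_events <- rep(0, n)   # events on branch above node v
  trunk <- 0                 # events on outgroup -> clade-root branch
  total <- 0
  states <- list(major = NULL, minor = NULL)
  for (allele in c("major", "minor")) {
    vals <- pm[[allele]]
    r <- if (allele == "major") root_major else root_minor
    stmat <- matrix(NA_integer_, n, ncol(vals))
    for (j in seq_len(ncol(vals))) {
      fit <- .sankoff_locus(tr$parent, tr$root, tr$post, kids, leaves,
                            vals[, j], r, backtrack = TRUE)
      total <- total + fit$total
      st <- fit$states
      stmat[, j] <- st
      trunk <- trunk + abs(st[tr$root] - r)
      for (v in which(!is.na(tr$parent))) {
        if (v == tr$root) next
        edge_events[v] <- edge_events[v] + abs(st[v] - st[tr$parent[v]])
      }
    }
    states[[allele]] <- stmat
  }
  list(edge_events = edge_events, trunk_events = trunk, total = total,
       states = states)
}

.phylo_to_ptree_topo <- function(phy, labels) {
  # rooted binary phylo over `labels` -> internal parent-vector topology
  phy <- ape::keep.tip(phy, labels)
  pp <- .phylo_parent(phy)
  k <- length(labels)
  map <- integer(length(pp$parent))
  map[seq_len(pp$ntip)] <- match(pp$labels, labels)
  internals <- setdiff(which(!is.na(pp$parent)), seq_len(pp$ntip))
  map[internals] <- k + seq_along(internals)
  parent <- rep(NA_integer_, 2L * k - 1L)
  for (v in which(!is.na(pp$parent))) {
    parent[map[v]] <- if (pp$parent[v] == 0L) 0L else map[pp$parent[v]]
  }
  root <- map[pp$root]
  list(parent = parent, root = root,
       post = .tree_postorder(parent, root),
       anc = .tree_anc(parent, root))
}

#' Root a tetraploid patient via candidate whole-genome-duplication states
#'
#' Scores the four tetraploid ancestral states 6/4, 4/2, 4/4 and 2/2
#' (total/major) as the root of an intermediate topology: the score of a
#' candidate is the parsimony tree length (summed per locus and allele,
#' internal states optimized under the segmental-event cost with no 0-to-1
#' transitions).  Ties are broken by adding the cost of the events that
#' must precede the duplication, i.e. the event distance from diploid 2/1
#' to the halved counterparts 3/2, 2/1, 2/2 and 1/1 (costs 1, 0, 2 and 1).
#'
#' @param profiles segment data.frame as in [build_cna_tree()].
#' @param intermediate_tree `phylo` giving the topology (branch lengths
#'   ignored), e.g. a diploid-mode [build_cna_tree()] result.
#' @param outgroup outgroup tip label.
#' @return list with `candidates` (data.frame: state, score, pre-WGD cost,
#'   selected flag), `selected` (the chosen "total/major" label), `tree`
#'   (the topology re-rooted at the chosen ancestor with refit event-count
#'   branch lengths) and `excluded_loci`.
#' @export
wgd_root <- function(profiles, intermediate_tree, outgroup = "outgroup") {
  pm <- .profiles_to_matrices(profiles)
  labels <- rownames(pm$major)
  topo <- .phylo_to_ptree_topo(intermediate_tree, labels)
  kids <- .tree_children(topo$parent)
  leaves <- seq_along(labels)

  cand <- data.frame(
    state = c("6/4", "4/2", "4/4", "2/2"),
    major = c(4L, 2L, 4L, 2L),
    minor = c(2L, 2L, 0L, 0L),
    # halved counterparts 3/2, 2/1, 2/2, 1/1 (total/major)
    halved_major = c(2L, 1L, 2L, 1L),
    halved_minor = c(1L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
  cand$pre_wgd_cost <- vapply(seq_len(nrow(cand)), function(i) {
    directed_event_distance(1L, cand$halved_major[i]) +
      directed_event_distance(1L, cand$halved_minor[i])
  }, numeric(1L))

  nl <- ncol(pm$major)
  sc <- matrix(0, nrow(cand), nl)
  for (j in seq_len(nl)) {
    for (i in seq_len(nrow(cand))) {
      sc[i, j] <- .sankoff_locus(topo$parent, topo$root, topo$post, kids,
                                 leaves, pm$major[, j], cand$major[i]) +
        .sankoff_locus(topo$parent, topo$root, topo$post, kids,
                       leaves, pm$minor[, j], cand$minor[i])
    }
  }
  # a locus no candidate can reach is dropped; a candidate that cannot
  # reach a retained locus scores infinity and cannot be selected
  excl <- apply(sc, 2L, function(col) all(!is.finite(col)))
  if (any(excl)) {
    warning(sprintf("%d locus/loci excluded from WGD rooting (no candidate feasible)",
                    sum(excl)))
  }
  cand$score <- rowSums(sc[, !excl, drop = FALSE])
  ord <- order(cand$score, cand$score + cand$pre_wgd_cost)
  sel <- ord[1L]
  cand$selected <- seq_len(nrow(cand)) == sel

  fit <- .cn_tree_fit(topo, pm, cand$major[sel], cand$minor[sel])
  phy <- .ptree_to_phylo(topo$parent, topo$root, labels, outgroup,
                         lengths = fit$edge_events,
                         trunk_length = fit$trunk_events)
  phy$edge.length[is.na(phy$edge.length)] <- 0
  list(candidates = cand, selected = cand$state[sel], tree = phy,
       excluded_loci = which(excl))
}

#' Bipartition support by noisy resampling of the distance matrix
#'
#' Adds i.i.d. Gaussian noise to the off-diagonal entries of the pairwise
#' dissimilarity matrix (symmetrized, floored at 0), rebuilds a tree from
#' each resample, and reports for every internal node of the original tree
#' the fraction of resamples containing the same bipartition.
#'
#' @param D symmetric dissimilarity matrix over the samples.
#' @param tree the original `phylo` (an `outgroup` tip, if present, is
#'   dropped for the comparison).
#' @param n_resamples number of resamples.
#' @param noise_sd standard deviation of the added noise, in events.
#' @param builder function mapping a distance matrix to a `phylo`
#'   (default: neighbour joining).
#' @param outgroup outgroup tip label.
#' @param seed optional seed fixing the resampling.
#' @return the (outgroup-dropped) tree with `node.label` set to support
#'   values in `[0, 1]`.
#' @export
resampling_support <- function(D, tree, n_resamples = 100, noise_sd = 1,
                               builder = NULL, outgroup = "outgroup",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(builder)) builder <- function(d) ape::nj(stats::as.dist(d))
  if (outgroup %in% tree$tip.label) tree <- ape::drop.tip(tree, outgroup)
  D <- as.matrix(D)[tree$tip.label, tree$tip.label]
  k <- nrow(D)
  reps <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    noise <- matrix(stats::rnorm(k * k, sd = noise_sd), k, k)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    Db <- pmax(D + noise, 0)
    dimnames(Db) <- dimnames(D)
    reps[[b]] <- builder(Db)
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- counts / n_resamples
  tree
}
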
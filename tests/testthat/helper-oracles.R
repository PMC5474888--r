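# Independent oracles and shared fixtures.

# Breadth-first search over the copy-number state graph: states are integer
# vectors with values 0..cap, moves add +/-1 to a contiguous run (no +1 on
# a run containing a 0, no negative counts).  Adjacency is precomputed once
# per (length, cap) and cached.
.bfs_env <- new.env(parent = emptyenv())

.bfs_adjacency <- function(L, cap = 4L) {
  key <- paste(L, cap)
  if (!is.null(.bfs_env[[key]])) return(.bfs_env[[key]])
  base <- cap + 1L
  n_states <- base^L
  decode <- function(code) {
    v <- integer(L)
    for (i in seq_len(L)) {
      v[i] <- code %% base
      code <- code %/% base
    }
    v
  }
  pw <- base^(0:(L - 1L))
  adj <- vector("list", n_states)
  for (code in 0:(n_states - 1L)) {
    v <- decode(code)
    nb <- integer(0)
    for (i in seq_len(L)) for (j in i:L) {
      run <- i:j
      if (all(v[run] >= 1L)) {
        if (all(v[run] + 1L <= cap)) nb <- c(nb, code + sum(pw[run]))  # gain
        nb <- c(nb, code - sum(pw[run]))                                # loss
      }
    }
    adj[[code + 1L]] <- nb
  }
  out <- list(adj = adj, pw = pw, base = base)
  .bfs_env[[key]] <- out
  out
}

bfs_event_distance <- function(a, b, cap = 4L) {
  L <- length(a)
  g <- .bfs_adjacency(L, cap)
  enc <- function(v) sum(v * g$pw)
  src <- enc(a)
  dst <- enc(b)
  if (src == dst) return(0)
  dist <- rep(NA_integer_, length(g$adj))
  dist[src + 1L] <- 0L
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (code in frontier) {
      for (w in g$adj[[code + 1L]]) {
        if (is.na(dist[w + 1L])) {
          dist[w + 1L] <- dist[code + 1L] + 1L
          if (w == dst) return(dist[w + 1L])
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

# exhaustive Dollo minimum over all rooted topologies, scored with the
# slow per-character recursive scorer (used at small sizes)
brute_force_dollo_naive <- function(X) {
  k <- nrow(X)
  topos <- phyloseed:::.enumerate_topologies(k)
  min(vapply(topos, function(tr)
    phyloseed:::.dollo_score_naive(tr$parent, tr$root, seq_len(k), X),
    numeric(1L)))
}

# exhaustive Dollo minimum over all rooted topologies (fast scorer); the
# search path is independent of the branch-and-bound
brute_force_dollo <- function(X) {
  k <- nrow(X)
  topos <- phyloseed:::.enumerate_topologies(k)
  min(vapply(topos, function(tr)
    phyloseed:::.dollo_score_fast(tr$parent, tr$root, seq_len(k), X,
                                  anc = tr$anc, post = tr$post),
    numeric(1L)))
}

random_binary_matrix <- function(k, m, p = 0.5) {
  X <- matrix(stats::rbinom(k * m, 1L, p), k, m,
              dimnames = list(paste0("S", seq_len(k)), paste0("c", seq_len(m))))
  X[1L, colSums(X) == 0L] <- 1L   # every character present somewhere
  X
}

# simulate one patient and run the full variant pipeline
run_patient_pipeline <- function(seed, n_samples = 4, depth_mean = 5000,
                                 cross_seed = FALSE, loh_probability = 0.1,
                                 with_ccf = TRUE, ...) {
  cfg <- sim_config(seed = seed, n_samples = n_samples,
                    depth_mean = depth_mean, cross_seed = cross_seed,
                    loh_probability = loh_probability, ...)
  tb <- simulate_patient(cfg)
  rc <- emit_read_counts(tb)
  prof <- emit_cna_profiles(tb)
  tm <- apply_tier3_filters(rc)
  out <- list(truth = tb, obs = rc, profiles = prof, tier = tm)
  if (tm$empty) return(out)
  if (with_ccf) {
    out$ccf <- suppressWarnings(estimate_patient_ccf(rc, prof, tm))
  }
  out$cna_tree <- build_cna_tree(prof)
  ds <- dollo_search(tm$calls)
  out$snv_tree <- break_ties_with_cna(ds$trees, out$cna_tree)
  out$dollo_score <- ds$score
  out$reconstruction <- acctran_reconstruct(out$snv_tree, tm$calls)
  out
}

# leaf labels below a node of a phylo, outgroup removed
leafset <- function(tree, node, outgroup = "outgroup") {
  cl <- phyloseed:::.phylo_clades(tree)
  sort(setdiff(tree$tip.label[cl[[node]]], outgroup))
}

depth_matrix <- function(obs, tm) {
  d <- matrix(NA_real_, nrow(tm$calls), ncol(tm$calls),
              dimnames = dimnames(tm$calls))
  keep <- obs$sample %in% rownames(d) & obs$snv %in% colnames(d)
  o <- obs[keep, ]
  d[cbind(o$sample, o$snv)] <- o$depth
  d
}
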
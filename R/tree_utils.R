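# Internal rooted-tree machinery shared by the SNV and CNA phylogeny code.
#
# Trees over k sample leaves are held as a parent vector indexed by node id:
# leaf ids 1..k, internal ids k+1 .. 2k-1 (partial trees leave unused slots
# NA).  The root has parent 0.  The germline outgroup is attached only when
# converting to an ape "phylo".

.ps_cache <- new.env(parent = emptyenv())

.tree_children <- function(parent) {
  kids <- vector("list", length(parent))
  for (v in seq_along(parent)) {
    p <- parent[v]
    if (!is.na(p) && p > 0L) kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

# reverse preorder: every node appears after all of its descendants
.tree_postorder <- function(parent, root) {
  kids <- .tree_children(parent)
  stack <- root
  out <- integer(0L)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  rev(out)
}

# anc[a, v] TRUE iff a is an ancestor of v or a == v
.tree_anc <- function(parent, root) {
  n <- length(parent)
  anc <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    if (is.na(parent[v])) next
    u <- v
    while (!is.na(u) && u > 0L) {
      anc[u, v] <- TRUE
      u <- parent[u]
    }
  }
  anc
}

# All rooted binary topologies over leaves 1..k ((2k-3)!! of them), built by
# inserting leaf j on every edge (or above the root) of every (j-1)-leaf tree.
.enumerate_topologies <- function(k) {
  key <- paste0("topo", k)
  if (!is.null(.ps_cache[[key]])) return(.ps_cache[[key]])
  stopifnot(k >= 2L)
  p0 <- rep(NA_integer_, 2L * k - 1L)
  p0[1:2] <- k + 1L
  p0[k + 1L] <- 0L
  trees <- list(list(parent = p0, root = k + 1L, nxt = k + 2L))
  if (k >= 3L) {
    for (j in 3L:k) {
      grown <- vector("list", length(trees) * (2L * j - 3L))
      i <- 0L
      for (tr in trees) {
        active <- which(!is.na(tr$parent))
        for (cc in active) {
          nt <- tr
          w <- nt$nxt
          if (cc == nt$root) {
            nt$parent[w] <- 0L
            nt$root <- w
          } else {
            nt$parent[w] <- nt$parent[cc]
          }
          nt$parent[cc] <- w
          nt$parent[j] <- w
          nt$nxt <- w + 1L
          i <- i + 1L
          grown[[i]] <- nt
        }
      }
      trees <- grown
    }
  }
  trees <- lapply(trees, function(tr) {
    tr$post <- .tree_postorder(tr$parent, tr$root)
    tr$anc <- .tree_anc(tr$parent, tr$root)
    tr
  })
  .ps_cache[[key]] <- trees
  trees
}

# Newick serialization of a parent-vector tree; leaf labels by id.
.newick_clade <- function(parent, root, labels, lengths = NULL) {
  kids <- .tree_children(parent)
  build <- function(v) {
    s <- if (v <= length(labels) && !is.null(labels) && length(kids[[v]]) == 0L) {
      labels[v]
    } else {
      paste0("(", paste(vapply(kids[[v]], build, ""), collapse = ","), ")")
    }
    if (!is.null(lengths) && !is.na(lengths[v]) && v != root) {
      s <- paste0(s, ":", format(lengths[v], scientific = FALSE))
    }
    s
  }
  build(root)
}

# Convert an internal tree to an ape phylo, attaching an all-ancestral
# outgroup leaf above the cancer-clade root.
.ptree_to_phylo <- function(parent, root, labels, outgroup = "outgroup",
                            lengths = NULL, trunk_length = NA) {
  clade <- .newick_clade(parent, root, labels, lengths)
  trunk <- if (is.na(trunk_length)) "" else paste0(":", format(trunk_length, scientific = FALSE))
  og <- if (is.null(lengths) && is.na(trunk_length)) outgroup else paste0(outgroup, ":0")
  nwk <- paste0("(", og, ",", clade, trunk, ");")
  ape::read.tree(text = nwk)
}

# phylo -> parent vector over ape node ids (leaves 1..n, internals n+1..)
.phylo_parent <- function(phy) {
  nn <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  parent[root] <- 0L
  list(parent = parent, root = root, ntip = ape::Ntip(phy),
       labels = phy$tip.label)
}

# leaves (tip ids) below each node of a phylo
.phylo_clades <- function(phy) {
  pp <- .phylo_parent(phy)
  post <- .tree_postorder(pp$parent, pp$root)
  kids <- .tree_children(pp$parent)
  clades <- vector("list", length(pp$parent))
  for (v in post) {
    clades[[v]] <- if (v <= pp$ntip) v else unlist(lapply(kids[[v]], function(k) clades[[k]]))
  }
  clades
}
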
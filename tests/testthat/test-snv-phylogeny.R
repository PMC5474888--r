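# Dollo-parsimony search, ancestral reconstruction and reversion
# verification.

test_that("a perfectly nested matrix yields a unique zero-loss tree", {
  X <- rbind(S1 = c(1, 1, 1, 0, 0),
             S2 = c(1, 1, 0, 1, 0),
             S3 = c(1, 0, 0, 0, 1))
  colnames(X) <- paste0("c", 1:5)
  ds <- dollo_search(X)
  expect_equal(ds$score, 0)
  expect_length(ds$trees, 1L)
  expect_false(ds$heuristic)
  tr <- ds$trees[[1L]]
  expect_setequal(leafset(tr, ape::getMRCA(tr, c("S1", "S2"))),
                  c("S1", "S2"))
})

test_that("the scorer agrees with an independent per-character recursion", {
  set.seed(201)
  for (i in 1:60) {
    k <- sample(4:6, 1L)
    X <- random_binary_matrix(k, sample(4:9, 1L))
    if (i %% 3 == 0) X[sample(length(X), 3L)] <- NA   # missing cells
    topos <- phyloseed:::.enumerate_topologies(k)
    tr <- topos[[sample(length(topos), 1L)]]
    fast <- phyloseed:::.dollo_score_fast(tr$parent, tr$root, seq_len(k), X,
                                          anc = tr$anc, post = tr$post)
    naive <- phyloseed:::.dollo_score_naive(tr$parent, tr$root, seq_len(k), X)
    expect_equal(fast, naive)
  }
})

test_that("losses concentrate on the lesion that lost the mutations", {
  # M2 is held inside the metastatic clade by six shared SNVs, yet lacks
  # four SNVs carried by the primary and its sister metastasis: the best
  # tree explains those as reversions on the M2 terminal branch
  X <- rbind(P  = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
             M2 = c(1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
             M3 = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  colnames(X) <- paste0("c", 1:12)
  ds <- dollo_search(X)
  expect_equal(ds$score, 4)
  best <- ds$trees[[1L]]
  expect_setequal(leafset(best, ape::getMRCA(best, c("M2", "M3"))),
                  c("M2", "M3"))
  rec <- acctran_reconstruct(best, X)
  # characters 3..6 were lost once each, on the M2 terminal branch
  for (ch in paste0("c", 3:6)) {
    ln <- rec$loss_nodes[[ch]]
    expect_length(ln, 1L)
    expect_identical(leafset(best, ln), "M2")
  }
})

test_that("ACCTRAN places truncal gains on the trunk and private gains on terminal branches", {
  X <- rbind(S1 = c(1, 1, 0), S2 = c(1, 0, 0), S3 = c(1, 0, 1))
  colnames(X) <- c("truncal", "privS1", "privS3")
  ds <- dollo_search(X)
  rec <- acctran_reconstruct(ds$trees[[1L]], X)
  tr <- rec$tree
  expect_setequal(leafset(tr, rec$gain_node[["truncal"]]),
                  c("S1", "S2", "S3"))
  expect_identical(leafset(tr, rec$gain_node[["privS1"]]), "S1")
  expect_identical(leafset(tr, rec$gain_node[["privS3"]]), "S3")
  expect_warning(acctran_reconstruct(ds$trees[[1L]],
                                     cbind(X, allzero = c(0, 0, 0))),
                 "absent in every sample")
})

test_that("reconstructed gains match planted branches on clean simulations", {
  for (seed in c(301, 302, 303)) {
    pl <- run_patient_pipeline(seed, n_samples = 5, depth_mean = 4000,
                               loh_probability = 0, with_ccf = FALSE,
                               error_rate = 0)
    rec <- pl$reconstruction
    truth <- pl$truth$snv_assignments
    tr <- rec$tree
    ok <- 0; tot <- 0
    for (sv in colnames(pl$tier$calls)) {
      g <- rec$gain_node[[sv]]
      if (is.na(g)) next
      want <- truth$gain_leafset[truth$snv == sv]
      if (want == "trunk") want <- paste(sort(pl$truth$samples), collapse = ",")
      # only loss-free characters pin the gain: an SNV whose carriers were
      # pruned by an incidental copy-number loss is not fully identifiable
      carriers <- paste(sort(pl$truth$samples[
        pl$truth$presence[, sv] == 1L]), collapse = ",")
      if (!identical(carriers, want)) next
      got <- paste(leafset(tr, g), collapse = ",")
      tot <- tot + 1
      ok <- ok + as.integer(identical(got, want))
    }
    expect_gt(tot, 0)
    expect_equal(ok, tot)   # no homoplasy among loss-free characters
  }
})

test_that("re-scoring a tree from its reconstruction reproduces the search score", {
  set.seed(210)
  X <- random_binary_matrix(5, 10, p = 0.4)
  ds <- dollo_search(X)
  for (tr in ds$trees) {
    rec <- acctran_reconstruct(tr, X)
    expect_equal(sum(rec$losses_per_char), ds$score)
    expect_equal(sum(tr$edge.length),
                 ds$score + sum(!is.na(rec$gain_node)))
  }
})

test_that("Newick round-trips preserve topology, labels and branch lengths", {
  pl <- run_patient_pipeline(401, with_ccf = FALSE)
  tr <- pl$snv_tree
  rt <- ape::read.tree(text = ape::write.tree(tr))
  expect_true(ape::all.equal.phylo(tr, rt, use.edge.length = TRUE))
  expect_setequal(rt$tip.label, tr$tip.label)
})

test_that("CNA trees break ties deterministically", {
  # two samples sharing nothing: both resolutions of the cherry are tied
  X <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1))
  colnames(X) <- paste0("c", 1:3)
  ds <- dollo_search(X)
  expect_gt(length(ds$trees), 1L)
  cna <- ape::read.tree(text = "(outgroup,(C,(A,B)));")
  pick <- break_ties_with_cna(ds$trees, cna)
  expect_setequal(leafset(pick, ape::getMRCA(pick, c("A", "B"))),
                  c("A", "B"))
  expect_identical(break_ties_with_cna(ds$trees[1], cna), ds$trees[[1L]])
  bad <- ape::read.tree(text = "(X,(Y,Z));")
  expect_error(break_ties_with_cna(ds$trees, bad), "disjoint")
  # deterministic under repetition
  expect_identical(ape::write.tree(break_ties_with_cna(ds$trees, cna)),
                   ape::write.tree(break_ties_with_cna(ds$trees, cna)))
})

test_that("heuristic mode engages above the exhaustive limit and is flagged", {
  set.seed(220)
  X <- random_binary_matrix(11, 20, p = 0.4)
  expect_error(dollo_search(X, method = "exhaustive"), "9 leaves")
  ds <- dollo_search(X)
  expect_true(ds$heuristic)
  expect_gte(ds$score, 0)
})

test_that("predicted reversions are annotated with the planted allele loss", {
  # high LOH rate stresses the annotation; whenever a planted reversion is
  # predicted on the right lesion, the supporting loss must name the
  # mutated segment (recall under default conditions is checked
  # separately, end to end)
  checked <- 0L
  for (seed in c(42, 43)) {
    pl <- run_patient_pipeline(seed = seed, n_samples = 5, depth_mean = 3000,
                               loh_probability = 0.4, with_ccf = FALSE)
    tb <- pl$truth
    rv <- verify_reversions(pl$reconstruction,
                            tb$snv_assignments[, c("snv", "chrom", "pos")],
                            pl$profiles, tb$sample_ccf,
                            depth_matrix(pl$obs, pl$tier))
    planted <- tb$snv_assignments[!is.na(tb$snv_assignments$loss_leafset), ]
    expect_gt(nrow(planted), 0)
    for (i in seq_len(nrow(planted))) {
      hit <- rv[rv$snv == planted$snv[i] &
                  rv$sample %in% strsplit(planted$loss_leafset[i], ",")[[1L]], ]
      if (!nrow(hit)) next    # tree ambiguity can hide the prediction
      checked <- checked + 1L
      expect_true(all(hit$status == "reversion_cna_supported"))
      seg <- tb$segments[tb$segments$segment == planted$segment[i], ]
      expect_true(all(hit$segment_chrom == seg$chrom &
                        hit$segment_start == seg$start))
    }
    # nothing asserted as a reversion below the power threshold
    expect_true(all(rv$power[rv$status == "reversion_cna_supported"] >= 0.95))
  }
  expect_gt(checked, 0L)
})

test_that("underpowered absences are flagged, not asserted as reversions", {
  # M1 is pinned inside a cherry with M2 by three shared SNVs but lacks
  # r1, which every other sample carries: one predicted reversion on M1
  X <- rbind(P  = c(1, 1, 0, 0, 0, 1),
             M1 = c(1, 1, 1, 1, 1, 0),
             M2 = c(1, 1, 1, 1, 1, 1),
             M3 = c(1, 1, 0, 0, 0, 1))
  colnames(X) <- c("t1", "t2", "p1", "p2", "p3", "r1")
  ds <- dollo_search(X)
  rec <- acctran_reconstruct(ds$trees[[1L]], X)
  expect_identical(leafset(rec$tree, rec$loss_nodes[["r1"]][1L]), "M1")
  samples <- rownames(X)
  prof <- data.frame(sample = samples, chrom = 1L, start = 1,
                     end = 1e6, total = 2L, major = 1L, minor = 1L)
  depths <- matrix(2000, 4, 6, dimnames = dimnames(X))
  info <- data.frame(snv = colnames(X), chrom = 1L, pos = 100 * 1:6)
  ccf <- c(P = 1, M1 = 1, M2 = 1, M3 = 1)
  rv <- verify_reversions(rec, info, prof, ccf, depths)
  rv1 <- rv[rv$snv == "r1" & rv$sample == "M1", ]
  # copy state unchanged and power ~1: unexplained (negative control)
  expect_identical(rv1$status, "unexplained")
  expect_gt(rv1$power, 0.99)

  # shallow depth in a low-CCF lesion: expected VAF 5%, ~2 reads needed
  depths["M1", ] <- 40
  ccf["M1"] <- 0.1
  rv2 <- verify_reversions(rec, info, prof, ccf, depths)
  rv2 <- rv2[rv2$snv == "r1" & rv2$sample == "M1", ]
  expect_lt(rv2$power, 0.95)
  expect_identical(rv2$status, "possible_false_negative")
})
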
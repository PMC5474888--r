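# Segmental event distances, minimum-event trees, WGD rooting and
# resampling support.

test_that("directed event distance matches hand-worked cases and the BFS oracle", {
  expect_equal(directed_event_distance(c(2, 1), c(2, 1)), 0)
  expect_equal(directed_event_distance(c(1, 1, 1), c(2, 2, 1)), 1)
  expect_equal(directed_event_distance(c(2, 2), c(0, 2)), 2)
  expect_true(is.infinite(directed_event_distance(c(0, 2), c(1, 2))))
  expect_equal(directed_event_distance(c(2, 1, 2), c(0, 0, 0)), 3)
  expect_error(directed_event_distance(c(1, 1), c(1, 1, 1)), "length")

  set.seed(501)
  for (i in 1:60) {
    L <- sample(2:4, 1L)
    a <- sample(0:4, L, replace = TRUE)
    b <- sample(0:4, L, replace = TRUE)
    expect_equal(directed_event_distance(a, b), bfs_event_distance(a, b),
                 info = paste("a =", paste(a, collapse = ","),
                              "b =", paste(b, collapse = ",")))
  }
})

test_that("pairwise dissimilarity is symmetric, zero on identity, and ancestor-minimal", {
  prof <- function(ma, mi) list(major = ma, minor = mi)
  p <- prof(c(2, 2, 2), c(1, 1, 1))
  expect_equal(pairwise_dissimilarity(p, p), 0)
  q <- prof(c(3, 3, 2), c(1, 1, 1))
  expect_equal(pairwise_dissimilarity(p, q), 1)   # ancestor = p

  set.seed(502)
  for (i in 1:200) {
    L <- sample(2:4, 1L)
    a <- prof(sample(1:4, L, TRUE), sample(0:2, L, TRUE))
    b <- prof(sample(1:4, L, TRUE), sample(0:2, L, TRUE))
    a$minor <- pmin(a$minor, a$major); b$minor <- pmin(b$minor, b$major)
    expect_equal(pairwise_dissimilarity(a, b), pairwise_dissimilarity(b, a))
  }

  # exhaustive ancestor search oracle on small vectors
  set.seed(503)
  for (i in 1:25) {
    L <- 3L
    x <- sample(0:3, L, TRUE); y <- sample(0:3, L, TRUE)
    grid <- expand.grid(rep(list(0:4), L))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      cc <- as.integer(grid[r, ])
      best <- min(best, directed_event_distance(cc, x) +
                    directed_event_distance(cc, y))
    }
    got <- phyloseed:::.ancestor_dp(x, y)
    expect_equal(got, best,
                 info = paste(paste(x, collapse = ","), "|",
                              paste(y, collapse = ",")))
  }
})

make_profiles <- function(major, minor) {
  # major/minor: samples x segments matrices with rownames
  k <- nrow(major); L <- ncol(major)
  do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(sample = rownames(major)[i], chrom = 1L,
               start = (seq_len(L) - 1) * 100 + 1, end = seq_len(L) * 100,
               total = major[i, ] + minor[i, ], major = major[i, ],
               minor = minor[i, ], stringsAsFactors = FALSE)))
}

test_that("private gains produce a star-like tree with one event per sample", {
  maj <- rbind(A = c(2, 1, 1), B = c(1, 2, 1), C = c(1, 1, 2))
  mi <- matrix(1L, 3, 3, dimnames = dimnames(maj))
  tr <- build_cna_tree(make_profiles(maj, mi))
  expect_equal(attr(tr, "total_events"), 3)
  expect_false(attr(tr, "heuristic"))
  # each terminal branch carries exactly its private event; trunk empty
  term <- tr$edge.length[tr$edge[, 2L] <= ape::Ntip(tr)]
  expect_setequal(term[term > 0], c(1, 1, 1))
})

test_that("shared truncal events land on the trunk and clades are recovered", {
  # truncal gain on segments 1-2 in all samples, private events below
  maj <- rbind(P  = c(2, 2, 1, 1, 1),
               M1 = c(2, 2, 2, 2, 1),
               M2 = c(2, 2, 2, 2, 2))
  mi <- matrix(1L, 3, 5, dimnames = dimnames(maj))
  tr <- build_cna_tree(make_profiles(maj, mi))
  # trunk (outgroup -> cancer MRCA) carries the shared segmental gain
  og <- match("outgroup", tr$tip.label)
  pp <- phyloseed:::.phylo_parent(tr)
  mrca <- ape::getMRCA(tr, match(c("P", "M1", "M2"), tr$tip.label))
  trunk_len <- tr$edge.length[tr$edge[, 2L] == mrca]
  expect_gte(trunk_len, 1)
  expect_setequal(leafset(tr, ape::getMRCA(tr, c("M1", "M2"))),
                  c("M1", "M2"))
})

test_that("planted topologies are recovered from emitted profiles", {
  hits <- 0; n <- 30
  for (seed in seq_len(n)) {
    # >= 5 events per branch over a segment grid wide enough that
    # independent branches rarely hit the same allele slot
    cfg <- sim_config(seed = 600 + seed, n_samples = 5, n_segments = 60,
                      n_chrom = 20, cna_truncal_mean = 5,
                      cna_branch_mean = 5, cna_branch_min = 5,
                      loh_probability = 0)
    tb <- simulate_patient(cfg)
    tr <- build_cna_tree(emit_cna_profiles(tb))
    rf <- phangorn::RF.dist(ape::unroot(ape::drop.tip(tr, "outgroup")),
                            ape::unroot(ape::drop.tip(tb$tree, "outgroup")))
    if (rf == 0) hits <- hits + 1
  }
  expect_gte(hits / n, 0.9)
})

test_that("tree score is invariant under leaf input order", {
  cfg <- sim_config(seed = 640, n_samples = 4, cna_branch_mean = 4)
  prof <- emit_cna_profiles(simulate_patient(cfg))
  t1 <- build_cna_tree(prof)
  prof2 <- prof[order(rev(prof$sample)), , drop = FALSE]
  t2 <- build_cna_tree(prof2)
  expect_equal(attr(t1, "total_events"), attr(t2, "total_events"))
})

test_that("WGD rooting scores the four tetraploid states with the stated tie-breaks", {
  mk <- function(major, minor, k = 3L, L = 4L) {
    maj <- matrix(major, k, L, dimnames = list(c("P", "M1", "M2"), NULL))
    make_profiles(maj, matrix(minor, k, L, dimnames = dimnames(maj)))
  }
  topo <- ape::read.tree(text = "(outgroup,(P,(M1,M2)));")

  wr <- wgd_root(mk(2L, 2L), topo)     # all samples 4/2
  expect_identical(wr$selected, "4/2")
  expect_equal(wr$candidates$score[wr$candidates$state == "4/2"], 0)
  expect_equal(wr$candidates$pre_wgd_cost, c(1, 0, 2, 1))

  wr2 <- wgd_root(mk(4L, 0L), topo)    # all samples 4/4
  expect_identical(wr2$selected, "4/4")
  expect_equal(wr2$candidates$pre_wgd_cost[wr2$candidates$state == "4/4"], 2)
})

test_that("the planted pre-duplication state is recovered across WGD simulations", {
  hits <- 0; n <- 10
  for (seed in seq_len(n)) {
    cfg <- sim_config(seed = 700 + seed, wgd = TRUE, n_samples = 4,
                      loh_probability = 0)
    tb <- simulate_patient(cfg)
    prof <- emit_cna_profiles(tb)
    wr <- suppressWarnings(wgd_root(prof, build_cna_tree(prof)))
    # genome-wide pre-WGD baseline is diploid 2/1, doubled to 4/2
    if (wr$selected == "4/2") hits <- hits + 1
  }
  expect_gte(hits / n, 0.9)
})

test_that("the chosen WGD ancestor never scores worse than the alternatives", {
  cfg <- sim_config(seed = 711, wgd = TRUE, n_samples = 4)
  prof <- emit_cna_profiles(simulate_patient(cfg))
  wr <- suppressWarnings(wgd_root(prof, build_cna_tree(prof)))
  sel <- wr$candidates[wr$candidates$selected, ]
  oth <- wr$candidates[!wr$candidates$selected, ]
  expect_true(all(sel$score + sel$pre_wgd_cost <=
                    oth$score + oth$pre_wgd_cost))
  expect_true(all(sel$score <= oth$score))
})

test_that("resampling support is 1 without noise, bounded, and reproducible", {
  cfg <- sim_config(seed = 720, n_samples = 5, cna_branch_mean = 6,
                    loh_probability = 0)
  prof <- emit_cna_profiles(simulate_patient(cfg))
  pm <- phyloseed:::.profiles_to_matrices(prof)
  D <- phyloseed:::.dissimilarity_matrix(pm)
  base <- ape::nj(stats::as.dist(D))
  s0 <- resampling_support(D, base, n_resamples = 20, noise_sd = 0, seed = 1)
  expect_true(all(s0$node.label == 1))
  tr <- build_cna_tree(prof)
  s1 <- resampling_support(D, tr, n_resamples = 30, noise_sd = 1, seed = 2)
  expect_true(all(s1$node.label >= 0 & s1$node.label <= 1))
  s2 <- resampling_support(D, tr, n_resamples = 30, noise_sd = 1, seed = 2)
  expect_identical(s1$node.label, s2$node.label)
})
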
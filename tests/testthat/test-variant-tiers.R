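# Tiered SNV filtering: background-noise pooling, the 3% presence cutoff,
# and the ordered tier-3 / tier-4 filters.

make_flanks <- function(n_pos, frac_by_class, depth = 10000) {
  # three non-reference bases per position, error shared equally
  refs <- c("A", "C")
  rows <- list()
  for (i in seq_len(n_pos)) {
    ref <- refs[(i %% 2) + 1L]
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    for (alt in alts) {
      cls <- substitution_class(ref, alt)
      f <- frac_by_class[[cls]]
      if (is.null(f)) f <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        position_id = paste0("p", i), ref = ref, alt = alt,
        alt_reads = round(f * depth), depth = depth,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("background noise is zero on clean flanks and SNP-like positions are excluded", {
  fl <- make_flanks(20, list())
  ne <- estimate_background_noise(fl)
  expect_true(all(ne$mean_background[ne$n_positions > 0] == 0))

  # one position with 12% non-reference reads is removed, means unchanged
  spike <- data.frame(position_id = "pX", ref = "A", alt = "G",
                      alt_reads = 1200, depth = 10000)
  ne2 <- estimate_background_noise(rbind(fl, spike))
  expect_identical(ne2$mean_background, ne$mean_background)
  expect_error(estimate_background_noise(transform(fl, depth = 0)), "depth")
})

test_that("planted per-class error rates are recovered from pooled flanks", {
  set.seed(41)
  depth <- 10000
  planted <- c("CG>TA" = 0.005, "AT>GC" = 0.005)
  rows <- list()
  for (i in 1:5000) {
    ref <- c("A", "C")[(i %% 2) + 1L]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cls <- substitution_class(ref, alt)
      f <- if (cls %in% names(planted)) planted[[cls]] else 0.001
      rows[[length(rows) + 1L]] <- data.frame(
        position_id = paste0("p", i), ref = ref, alt = alt,
        alt_reads = rbinom(1, depth, f), depth = depth)
    }
  }
  ne <- estimate_background_noise(do.call(rbind, rows))
  got <- ne$mean_background[ne$substitution_class == "CG>TA"]
  expect_lt(abs(got - 0.005), 0.001)
  expect_lt(abs(attr(ne, "max_class_mean") - 0.005), 0.001)
})

test_that("presence is called at the inclusive 3% boundary", {
  expect_false(call_presence(0.029))
  expect_true(call_presence(0.031))
  expect_true(call_presence(0.03))      # boundary convention: inclusive
  expect_false(call_presence(0))
  expect_error(call_presence(1.2))
})

make_obs <- function(vaf, depth) {
  # vaf, depth: samples x snvs matrices with dimnames
  idx <- expand.grid(sample = rownames(vaf), snv = colnames(vaf),
                     stringsAsFactors = FALSE)
  data.frame(sample = idx$sample, snv = idx$snv,
             chrom = 1L, pos = match(idx$snv, colnames(vaf)) * 100,
             depth = depth[cbind(idx$sample, idx$snv)],
             alt_reads = round(vaf[cbind(idx$sample, idx$snv)] *
                                 depth[cbind(idx$sample, idx$snv)]),
             stringsAsFactors = FALSE)
}

test_that("tier-3 filters apply in the documented order with the documented boundaries", {
  samples <- paste0("S", 1:4)
  snvs <- paste0("v", 1:10)
  vaf <- matrix(0.5, 4, 10, dimnames = list(samples, snvs))
  depth <- matrix(5000, 4, 10, dimnames = list(samples, snvs))

  # clean input: nothing dropped
  tm <- apply_tier3_filters(make_obs(vaf, depth))
  expect_equal(dim(tm$calls), c(4L, 10L))
  expect_length(tm$dropped_samples, 0)

  # depth boundary: exactly 1500 is missing, 1501 is kept
  d2 <- depth; d2["S1", "v1"] <- 1500; d2["S1", "v2"] <- 1501
  tm2 <- apply_tier3_filters(make_obs(vaf, d2))
  expect_true(is.na(tm2$calls["S1", "v1"]))
  expect_identical(tm2$calls["S1", "v2"], 1L)

  # a sample with 60% of cells below coverage is dropped at step (2)
  d3 <- depth; d3["S2", 1:6] <- 1000
  tm3 <- apply_tier3_filters(make_obs(vaf, d3))
  expect_false("S2" %in% rownames(tm3$calls))
  expect_true("S2" %in% tm3$dropped_samples)

  # an SNV with 2 missing cells (after sample drops) is dropped at step (3)
  d4 <- depth; d4[c("S1", "S2"), "v3"] <- 1200
  tm4 <- apply_tier3_filters(make_obs(vaf, d4))
  expect_false("v3" %in% colnames(tm4$calls))
  # one missing cell is tolerated
  d5 <- depth; d5["S1", "v4"] <- 1200
  tm5 <- apply_tier3_filters(make_obs(vaf, d5))
  expect_true("v4" %in% colnames(tm5$calls))
  expect_true(is.na(tm5$calls["S1", "v4"]))

  # SNVs absent everywhere (below 3%) are dropped at step (4)
  v6 <- vaf; v6[, "v5"] <- 0.02
  tm6 <- apply_tier3_filters(make_obs(v6, depth))
  expect_false("v5" %in% colnames(tm6$calls))

  # samples with <= 20% of SNVs present are dropped at step (5)
  v7 <- vaf; v7["S4", 1:8] <- 0.001            # 2/10 = 20% present: dropped
  tm7 <- apply_tier3_filters(make_obs(v7, depth))
  expect_false("S4" %in% rownames(tm7$calls))
  v8 <- vaf; v8["S4", 1:7] <- 0.001            # 3/10 = 30% present: kept
  tm8 <- apply_tier3_filters(make_obs(v8, depth))
  expect_true("S4" %in% rownames(tm8$calls))

  # everything filtered away -> explicit empty status
  v9 <- vaf; v9[] <- 0.001
  expect_message(tm9 <- apply_tier3_filters(make_obs(v9, depth)), "no samples")
  expect_true(tm9$empty)
})

test_that("tier-3 filtering is idempotent and monotone in the depth cutoff", {
  set.seed(55)
  tb <- simulate_patient(sim_config(seed = 55, depth_mean = 3000))
  rc <- emit_read_counts(tb)
  tm <- apply_tier3_filters(rc)

  # re-apply to its own output (reconstructed observation table)
  obs2 <- data.frame(sample = rownames(tm$calls)[row(tm$vaf)],
                     snv = colnames(tm$calls)[col(tm$vaf)],
                     depth = as.vector(tm$depth),
                     alt_reads = round(as.vector(tm$vaf) *
                                         as.vector(tm$depth)))
  obs2$alt_reads[is.na(obs2$alt_reads)] <- 0
  tm2 <- apply_tier3_filters(obs2)
  expect_identical(sort(rownames(tm2$calls)), sort(rownames(tm$calls)))
  expect_identical(sort(colnames(tm2$calls)), sort(colnames(tm$calls)))
  expect_identical(tm2$calls[rownames(tm$calls), colnames(tm$calls)],
                   tm$calls)

  # raising min_depth never increases what is retained
  for (md in c(2000, 2500, 3000)) {
    tmd <- apply_tier3_filters(rc, min_depth = md)
    expect_lte(nrow(tmd$calls), nrow(tm$calls))
    expect_lte(ncol(tmd$calls), ncol(tm$calls))
    tm <- tmd
  }
})

test_that("noise-free deep-coverage runs reproduce the planted truth exactly", {
  tb <- simulate_patient(sim_config(seed = 77, error_rate = 0,
                                    depth_mean = 5000))
  rc <- emit_read_counts(tb)
  tm <- apply_tier3_filters(rc)
  expect_identical(sort(rownames(tm$calls)), sort(tb$samples))
  truth <- tb$presence[rownames(tm$calls), colnames(tm$calls)]
  expect_identical(unname(tm$calls), unname(truth))
})

test_that("tier-4 promotion follows the inclusive 30% CCF boundary", {
  vaf <- matrix(0.5, 3, 6, dimnames = list(paste0("S", 1:3), paste0("v", 1:6)))
  depth <- matrix(5000, 3, 6, dimnames = dimnames(vaf))
  tm <- apply_tier3_filters(make_obs(vaf, depth))
  tm <- promote_tier4(tm, c(S1 = 0.29, S2 = 0.31, S3 = 0.30))
  expect_identical(unname(tm$sample_tier[c("S1", "S2", "S3")]),
                   c(3L, 4L, 4L))
  expect_warning(promote_tier4(tm, c(S1 = 1, S2 = 1)), "no CCF")
  tm2 <- promote_tier4(tm, c(S1 = 1, S2 = 1, S3 = 1))
  expect_true(all(tm2$sample_tier == 4L))
})
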
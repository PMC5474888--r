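# Synthetic multi-sample tumour data with known evolutionary history.
#
# One patient = a random rooted binary clone tree over the sampled lesions
# (primary "P" plus metastases "M1", "M2", ...), rooted by a germline
# outgroup.  Truncal and branch SNVs and segmental copy-number events are
# planted on the tree; optional extras emulate the phenomena the pipeline
# must detect: LOH events deleting a mutated allele (reversions), a
# whole-genome duplication on the trunk, and horizontal cross-seeding of
# one lesion by another.  Read counts are then drawn per SNV and sample
# from a binomial at the error-adjusted expected VAF given the sample's
# CCF, local copy state and mutation multiplicity.

#' Simulation configuration
#'
#' @param n_samples number of sampled lesions (>= 2).
#' @param n_truncal_snvs SNVs on the trunk (fixed count).
#' @param n_branch_snvs mean SNVs per branch below the trunk (Poisson).
#' @param depth_mean mean sequencing depth (Poisson, floored at 100);
#'   default mirrors the ultra-deep targeted regime (~9,000x).
#' @param error_rate per-base sequencing error; a misread hits the
#'   specific alternate base with probability `error_rate / 3`.
#' @param ccf_range interval for per-sample cancer cell fractions.
#' @param loh_probability per truncal SNV, probability of planting an LOH
#'   event that deletes the mutated allele in one lesion (a reversion).
#' @param wgd plant a whole-genome duplication on the trunk.
#' @param cross_seed plant a donor -> recipient cross-seeding event.
#' @param cross_seed_fraction clonal fraction of donor-private SNVs in the
#'   recipient.
#' @param n_segments,n_chrom shared segment grid.
#' @param cna_truncal_mean,cna_branch_mean mean copy-number events on the
#'   trunk / per branch (Poisson).
#' @param cna_branch_min floor on the per-branch copy-number event count
#'   (for regimes defined by a minimum number of events per branch).
#' @param apobec_late enrich late SNVs for C>T at NpCpG trinucleotides.
#' @param primary_basal force the primary lesion to branch off first, so
#'   all metastases descend from a common metastatic precursor
#'   (otherwise the topology is uniformly random and the primary usually
#'   sits among the metastases).
#' @param seed integer fixing all randomness end-to-end.
#' @return validated configuration list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 5L, n_truncal_snvs = 30L,
                       n_branch_snvs = 8, depth_mean = 9000,
                       error_rate = 0.01, ccf_range = c(0.5, 1),
                       loh_probability = 0.1, wgd = FALSE,
                       cross_seed = FALSE, cross_seed_fraction = 0.3,
                       n_segments = 20L, n_chrom = 10L,
                       cna_truncal_mean = 4, cna_branch_mean = 2,
                       cna_branch_min = 0L, apobec_late = FALSE,
                       primary_basal = FALSE, seed = NULL) {
  if (n_samples < 2L) stop("configuration error: n_samples must be >= 2")
  stopifnot(n_truncal_snvs >= 0, n_branch_snvs >= 0, depth_mean > 0,
            error_rate >= 0, error_rate < 1,
            length(ccf_range) == 2L, all(ccf_range > 0), all(ccf_range <= 1),
            ccf_range[1] <= ccf_range[2],
            loh_probability >= 0, loh_probability <= 1,
            cross_seed_fraction > 0, cross_seed_fraction <= 1,
            n_segments >= 1, n_chrom >= 1, n_chrom <= n_segments)
  structure(as.list(environment()), class = "sim_config")
}

.SUB_PROBS <- c("AT>CG" = 0.08, "AT>GC" = 0.20, "AT>TA" = 0.07,
                "CG>AT" = 0.15, "CG>GC" = 0.10, "CG>TA" = 0.40)

.class_to_refalt <- function(cls) {
  # pyrimidine-strand representative of each pooled class
  map <- list("AT>CG" = c("T", "G"), "AT>GC" = c("T", "C"),
              "AT>TA" = c("T", "A"), "CG>AT" = c("C", "A"),
              "CG>GC" = c("C", "G"), "CG>TA" = c("C", "T"))
  map[[cls]]
}

#' Simulate one patient's ground truth
#'
#' @param config a [sim_config()].
#' @param patient_id label.
#' @return object of class `truth_bundle`: the clone tree (`phylo` with a
#'   germline `outgroup` tip; branch lengths = planted SNV counts), SNV
#'   and CNA assignments (branches identified by the set of samples below
#'   them), the true presence and multiplicity matrices, per-leaf
#'   allele-specific profiles, per-sample CCFs, and the cross-seeding
#'   event if planted.
#' @export
simulate_patient <- function(config, patient_id = "PT1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$n_samples
  samples <- c("P", if (k > 1L) paste0("M", seq_len(k - 1L)))

  ## random rooted binary topology over the lesions; with primary_basal
  ## the primary (leaf 1) joins last, above the metastatic clade
  nslot <- 2L * k - 1L
  parent <- rep(NA_integer_, nslot)
  first2 <- if (config$primary_basal && k >= 3L) c(2L, 3L) else 1:2
  if (k == 2L) {
    parent[1:2] <- 3L; parent[3L] <- 0L
    root <- 3L; nxt <- 4L
  } else {
    parent[first2] <- k + 1L; parent[k + 1L] <- 0L
    root <- k + 1L; nxt <- k + 2L
    rest <- setdiff(seq_len(k), first2)
    if (config$primary_basal) rest <- c(setdiff(rest, 1L), 1L)
    for (j in rest) {
      cands <- which(!is.na(parent))
      cc <- if (config$primary_basal && j == 1L) root else
        sample(cands, 1L)
      w <- nxt
      if (cc == root) { parent[w] <- 0L; root <- w } else parent[w] <- parent[cc]
      parent[cc] <- w; parent[j] <- w
      nxt <- w + 1L
    }
  }
  kids <- .tree_children(parent)
  post <- .tree_postorder(parent, root)
  anc <- .tree_anc(parent, root)
  clade_leaves <- lapply(seq_len(nslot), function(v)
    if (is.na(parent[v])) NULL else which(anc[v, seq_len(k)]))

  ## segment grid
  per_chrom <- ceiling(config$n_segments / config$n_chrom)
  seg_chrom <- rep(seq_len(config$n_chrom), each = per_chrom)[seq_len(config$n_segments)]
  seg_idx <- stats::ave(seq_along(seg_chrom), seg_chrom, FUN = seq_along)
  segments <- data.frame(segment = seq_len(config$n_segments),
                         chrom = seg_chrom,
                         start = (seg_idx - 1) * 1e7 + 1,
                         end = seg_idx * 1e7)

  ## branches in preorder: trunk (0) first, then non-root nodes
  pre <- rev(post)
  branch_nodes <- c(0L, setdiff(pre, root))

  ## ----- copy-number events (drawn branch by branch, validated locally)
  ns <- config$n_segments
  germline <- list(a = rep(1L, ns), b = rep(1L, ns))
  node_state <- vector("list", nslot + 1L)   # slot nslot+1 = cancer root inflow
  events <- list()
  draw_events <- function(state, n_events, branch, wgd_here = FALSE) {
    evs <- list()
    if (wgd_here) {
      # pre-duplication events create the 3/2, 2/2 and 1/1 states
      npre <- stats::rpois(1L, max(1, config$cna_truncal_mean / 2))
      for (i in seq_len(npre)) {
        seg <- sample.int(ns, 1L)
        type <- sample(c("gain_a", "loss_b"), 1L)
        if (type == "gain_a" && state$a[seg] >= 1L) {
          state$a[seg] <- state$a[seg] + 1L
          evs[[length(evs) + 1L]] <- list(seg = seg, allele = "a", delta = 1L)
        } else if (type == "loss_b" && state$b[seg] >= 1L &&
                   state$a[seg] >= state$b[seg] - 1L + 1L) {
          state$b[seg] <- state$b[seg] - 1L
          evs[[length(evs) + 1L]] <- list(seg = seg, allele = "b", delta = -1L)
        }
      }
      state$a <- state$a * 2L
      state$b <- state$b * 2L
      evs[[length(evs) + 1L]] <- list(seg = NA_integer_, allele = NA_character_,
                                      delta = NA_integer_, wgd = TRUE)
    }
    for (i in seq_len(n_events)) {
      for (try in 1:50) {
        seg <- sample.int(ns, 1L)
        allele <- sample(c("a", "b"), 1L)
        delta <- sample(c(1L, -1L), 1L)
        cur <- state[[allele]][seg]
        if (cur < 1L) next                       # no event on a lost allele
        new <- cur + delta
        a2 <- if (allele == "a") new else state$a[seg]
        b2 <- if (allele == "b") new else state$b[seg]
        # background losses keep one copy of each allele: allele-deleting
        # LOH is planted only through the dedicated reversion events (and
        # pre-WGD states), so the reversions in the data are the planted ones
        if (new < 1L || a2 < b2) next            # keep phased major >= minor
        state[[allele]][seg] <- new
        evs[[length(evs) + 1L]] <- list(seg = seg, allele = allele, delta = delta)
        break
      }
    }
    list(state = state, events = evs)
  }

  branch_events <- vector("list", length(branch_nodes))
  names(branch_events) <- as.character(branch_nodes)
  state_at <- vector("list", nslot)
  trunk_n <- stats::rpois(1L, config$cna_truncal_mean)
  res <- draw_events(germline, trunk_n, 0L, wgd_here = config$wgd)
  branch_events[["0"]] <- res$events
  state_at_root <- res$state
  state_at[[root]] <- state_at_root
  for (v in setdiff(pre, root)) {
    nb <- max(stats::rpois(1L, config$cna_branch_mean),
              config$cna_branch_min)
    res <- draw_events(state_at[[parent[v]]], nb, v)
    branch_events[[as.character(v)]] <- res$events
    state_at[[v]] <- res$state
  }

  ## ----- SNVs
  n_on_branch <- stats::setNames(
    c(config$n_truncal_snvs,
      stats::rpois(length(branch_nodes) - 1L, config$n_branch_snvs)),
    as.character(branch_nodes))
  donor <- recipient <- NA_character_
  if (config$cross_seed) {
    if (k < 3L) stop("configuration error: cross-seeding needs >= 3 samples")
    donor_leaf <- sample.int(k, 1L)
    recipient_leaf <- sample(setdiff(seq_len(k), donor_leaf), 1L)
    donor <- samples[donor_leaf]; recipient <- samples[recipient_leaf]
    n_on_branch[as.character(donor_leaf)] <-
      max(n_on_branch[as.character(donor_leaf)], 8L)
  }

  snv_rows <- list()
  used_pos <- new.env(parent = emptyenv())
  sid <- 0L
  for (bn in branch_nodes) {
    start_state <- if (bn == 0L) germline else state_at[[parent[bn]]]
    for (i in seq_len(n_on_branch[as.character(bn)])) {
      sid <- sid + 1L
      seg <- sample.int(ns, 1L)
      avail <- c("a", "b")[c(start_state$a[seg] >= 1L, start_state$b[seg] >= 1L)]
      if (!length(avail)) { sid <- sid - 1L; next }
      allele <- if (length(avail) == 1L) avail else sample(avail, 1L)
      late <- bn != 0L
      probs <- .SUB_PROBS
      if (config$apobec_late && late) {
        probs["CG>TA"] <- 0.60
        probs <- probs / sum(probs)
      }
      cls <- sample(names(probs), 1L, prob = probs)
      ra <- .class_to_refalt(cls)
      npcpg_boost <- config$apobec_late && late && cls == "CG>TA"
      three <- if (ra[1L] == "C") {
        if (npcpg_boost && stats::runif(1L) < 0.8) "G"
        else sample(c("A", "C", "G", "T"), 1L)
      } else sample(c("A", "C", "G", "T"), 1L)
      five <- sample(c("A", "C", "G", "T"), 1L)
      repeat {
        pos <- segments$start[seg] + sample.int(1e7 - 2L, 1L)
        key <- paste(segments$chrom[seg], pos)
        if (is.null(used_pos[[key]])) { used_pos[[key]] <- TRUE; break }
      }
      snv_rows[[sid]] <- data.frame(
        snv = sprintf("s%03d", sid), branch = bn, segment = seg,
        allele = allele, chrom = segments$chrom[seg], pos = pos,
        ref = ra[1L], alt = ra[2L],
        context = paste0(five, ra[1L], three),
        phase = if (bn == 0L) "early" else "late",
        stringsAsFactors = FALSE)
    }
  }
  snvs <- do.call(rbind, snv_rows)

  ## ----- planted LOH reversions on truncal SNVs
  # eligible loss leaves: terminal branches whose leaf is not a direct
  # child of the cancer-clade root (so that the remaining carriers still
  # span the trunk and the reversion is identifiable)
  eligible_leaves <- setdiff(seq_len(k), kids[[root]])
  snvs$loss_leaf <- NA_character_
  if (config$loh_probability > 0 && length(eligible_leaves) && !is.null(snvs)) {
    planted <- new.env(parent = emptyenv())
    truncal <- which(snvs$branch == 0L)
    for (i in truncal) {
      if (stats::runif(1L) >= config$loh_probability) next
      ok <- Filter(function(lf) {
        st <- state_at[[lf]]
        key <- paste(snvs$segment[i], snvs$allele[i], lf)
        cur <- st[[snvs$allele[i]]][snvs$segment[i]]
        other <- st[[setdiff(c("a", "b"), snvs$allele[i])]][snvs$segment[i]]
        a2 <- if (snvs$allele[i] == "a") cur - 1L else other
        b2 <- if (snvs$allele[i] == "b") cur - 1L else other
        cur == 1L && a2 >= b2 && is.null(planted[[key]])
      }, eligible_leaves)
      if (!length(ok)) next
      lf <- if (length(ok) == 1L) ok[[1L]] else sample(unlist(ok), 1L)
      key <- paste(snvs$segment[i], snvs$allele[i], lf)
      planted[[key]] <- TRUE
      branch_events[[as.character(lf)]] <-
        c(branch_events[[as.character(lf)]],
          list(list(seg = snvs$segment[i], allele = snvs$allele[i],
                    delta = -1L, reversion = snvs$snv[i])))
      st <- state_at[[lf]]
      st[[snvs$allele[i]]][snvs$segment[i]] <-
        st[[snvs$allele[i]]][snvs$segment[i]] - 1L
      state_at[[lf]] <- st
    }
  }

  ## ----- replay: presence + multiplicity per leaf
  # branch sequence along a leaf's root path (trunk = 0), with the events
  # of each branch in planted order
  path_branches <- function(leaf) {
    v <- leaf
    chain <- integer(0)
    while (v != root) { chain <- c(v, chain); v <- parent[v] }
    c(0L, chain)
  }

  presence <- matrix(0L, k, nrow(snvs), dimnames = list(samples, snvs$snv))
  mult <- presence
  for (lf in seq_len(k)) {
    path_bns <- path_branches(lf)
    evs <- list(); evb <- integer(0)
    for (u in path_bns) {
      be <- branch_events[[as.character(u)]]
      evs <- c(evs, be)
      evb <- c(evb, rep(u, length(be)))
    }
    for (i in seq_len(nrow(snvs))) {
      bn <- snvs$branch[i]
      gain_pos <- match(bn, path_bns)
      if (is.na(gain_pos)) next        # SNV's gain branch not on this path
      # mutated-copy count m and allele count cc, walked from the start of
      # the gain branch (SNVs precede their branch's copy-number events;
      # gains after the SNV duplicate it when every copy is mutated,
      # losses remove unmutated copies first unless planted as reversions)
      st <- if (bn == 0L) germline else state_at[[parent[bn]]]
      m <- 1L
      cc <- st[[snvs$allele[i]]][snvs$segment[i]]
      for (j in seq_along(evs)) {
        if (match(evb[j], path_bns) < gain_pos) next
        ev <- evs[[j]]
        if (isTRUE(ev$wgd)) { m <- 2L * m; cc <- 2L * cc; next }
        if (is.na(ev$seg) || ev$seg != snvs$segment[i] ||
            ev$allele != snvs$allele[i]) next
        if (ev$delta == 1L) {
          if (m == cc) m <- m + 1L
          cc <- cc + 1L
        } else {
          if (!is.null(ev$reversion) && ev$reversion == snvs$snv[i]) m <- m - 1L
          cc <- cc - 1L
          m <- min(m, cc)
        }
      }
      if (m > 0L) { presence[lf, i] <- 1L; mult[lf, i] <- m }
    }
  }

  ## ----- per-leaf emitted profiles
  prof_rows <- lapply(seq_len(k), function(lf) {
    st <- state_at[[lf]]
    data.frame(sample = samples[lf], chrom = segments$chrom,
               start = segments$start, end = segments$end,
               total = st$a + st$b, major = st$a, minor = st$b,
               stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, prof_rows)
  rownames(profiles) <- NULL

  sample_ccf <- stats::setNames(
    stats::runif(k, config$ccf_range[1L], config$ccf_range[2L]), samples)

  branch_label <- function(bn) {
    if (bn == 0L) "trunk"
    else paste(sort(samples[clade_leaves[[bn]]]), collapse = ",")
  }
  snvs$gain_leafset <- vapply(snvs$branch, branch_label, character(1L))
  snvs$loss_leafset <- NA_character_
  for (bn in branch_nodes[-1L]) {
    evs <- branch_events[[as.character(bn)]]
    for (ev in evs) {
      if (!is.null(ev$reversion)) {
        snvs$loss_leafset[snvs$snv == ev$reversion] <- branch_label(bn)
      }
    }
  }

  cna_rows <- list()
  for (bn in branch_nodes) {
    for (ev in branch_events[[as.character(bn)]]) {
      cna_rows[[length(cna_rows) + 1L]] <- data.frame(
        branch_leafset = branch_label(bn),
        segment = if (is.null(ev$seg)) NA_integer_ else ev$seg,
        allele = if (is.null(ev$allele)) NA_character_ else ev$allele,
        delta = if (is.null(ev$delta)) NA_integer_ else ev$delta,
        is_wgd = isTRUE(ev$wgd),
        is_reversion = !is.null(ev$reversion),
        snv = if (!is.null(ev$reversion)) ev$reversion else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  cna_assignments <- do.call(rbind, cna_rows)

  # planted tree with SNV-count branch lengths
  snv_per_branch <- table(factor(snvs$branch, levels = branch_nodes))
  lens <- rep(NA_real_, nslot)
  for (bn in branch_nodes[-1L]) lens[bn] <- snv_per_branch[as.character(bn)]
  tree <- .ptree_to_phylo(parent, root, samples, outgroup = "outgroup",
                          lengths = lens,
                          trunk_length = snv_per_branch[["0"]])

  structure(list(patient_id = patient_id, config = config, tree = tree,
                 samples = samples, segments = segments,
                 snv_assignments = snvs, cna_assignments = cna_assignments,
                 presence = presence, multiplicity = mult,
                 profiles = profiles, sample_ccf = sample_ccf,
                 cross_seed = if (config$cross_seed)
                   list(donor = donor, recipient = recipient,
                        fraction = config$cross_seed_fraction) else NULL),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("truth bundle %s: %d samples, %d SNVs, %d CNA events%s%s\n",
              x$patient_id, length(x$samples), nrow(x$snv_assignments),
              if (is.null(x$cna_assignments)) 0L else nrow(x$cna_assignments),
              if (isTRUE(x$config$wgd)) ", WGD" else "",
              if (!is.null(x$cross_seed))
                sprintf(", cross-seed %s->%s", x$cross_seed$donor,
                        x$cross_seed$recipient) else ""))
  invisible(x)
}

#' Emit per-sample allele-specific copy-number profiles
#'
#' @param truth a `truth_bundle`.
#' @return segment data.frame (`sample`, `chrom`, `start`, `end`, `total`,
#'   `major`, `minor`); replaying the planted events along each leaf's
#'   root path reproduces it exactly.
#' @export
emit_cna_profiles <- function(truth) {
  stopifnot(inherits(truth, "truth_bundle"))
  truth$profiles
}

#' Emit binomial read counts for every SNV x sample
#'
#' Variant reads are binomial at the error-adjusted expected VAF given the
#' sample's CCF, the local total copy number, the mutation multiplicity
#' and (for cross-seeded mutations) the planted subclonal fraction; absent
#' SNVs yield error-only counts.  Depth is Poisson around
#' `config$depth_mean`, floored at 100.
#'
#' @param truth a `truth_bundle`.
#' @param config the [sim_config()] used to generate it.
#' @return data.frame: `patient`, `sample`, `snv`, `chrom`, `pos`, `ref`,
#'   `alt`, `ref_reads`, `alt_reads`, `depth`, `vaf`, `context`.
#' @export
emit_read_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_bundle"))
  if (!is.null(config$seed)) set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  snvs <- truth$snv_assignments
  e <- config$error_rate
  rows <- list()
  seg_of <- snvs$segment
  for (s in truth$samples) {
    prof <- truth$profiles[truth$profiles$sample == s, , drop = FALSE]
    qt <- prof$total[seg_of]
    alpha <- truth$sample_ccf[[s]]
    m <- truth$multiplicity[s, ]
    cf <- as.numeric(truth$presence[s, ])
    if (!is.null(truth$cross_seed) && s == truth$cross_seed$recipient) {
      donor_set <- truth$cross_seed$donor
      seeded <- snvs$gain_leafset == donor_set & truth$presence[s, ] == 0L
      cf[seeded] <- truth$cross_seed$fraction
      m[seeded] <- 1L
    }
    f <- ifelse(cf > 0,
                m * cf * alpha / (pmax(qt, 1L) * alpha + 2 * (1 - alpha)),
                0)
    p <- e / 3 + f * (1 - 4 * e / 3)
    depth <- pmax(100L, stats::rpois(nrow(snvs), config$depth_mean))
    X <- stats::rbinom(nrow(snvs), depth, p)
    rows[[s]] <- data.frame(
      patient = truth$patient_id, sample = s, snv = snvs$snv,
      chrom = snvs$chrom, pos = snvs$pos, ref = snvs$ref, alt = snvs$alt,
      ref_reads = depth - X, alt_reads = X, depth = depth, vaf = X / depth,
      context = snvs$context, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
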
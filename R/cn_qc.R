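# Array-level quality control and pre-phylogenetics cleanup of
# allele-specific copy-number profiles.
#
# FFPE-damaged DNA produces noisy, wavy log2 tracks that mimic copy-number
# change.  Two track-level metrics guard against this: MAPD (median
# absolute pairwise deviation of adjacent probes; point noise) and MAC
# (median across chromosomes of the lag-1 autocorrelation; waviness).
# Samples with MAPD > 0.7 or MAC > 0.3 are discarded.

#' Median absolute pairwise deviation of a log2 track
#'
#' Median of `|x[i+1] - x[i]|` over adjacent probes, pooled genome-wide
#' (differences never span a chromosome boundary).
#'
#' @param track data.frame with columns `chrom`, `pos`, `log2` (positions
#'   strictly increasing within each chromosome).
#' @return non-negative MAPD value.
#' @export
compute_mapd <- function(track) {
  .check_track(track)
  d <- unlist(lapply(split(track$log2, track$chrom), diff), use.names = FALSE)
  if (!length(d)) stop("MAPD undefined: fewer than 2 probes")
  stats::median(abs(d))
}

#' Median lag-1 autocorrelation of a log2 track
#'
#' Lag-1 Pearson autocorrelation computed per chromosome; MAC is the
#' median across chromosomes.  Zero-variance chromosomes are excluded
#' with a warning.
#'
#' @inheritParams compute_mapd
#' @return MAC value in `[-1, 1]`.
#' @export
compute_mac <- function(track) {
  .check_track(track)
  acs <- vapply(split(track$log2, track$chrom), function(x) {
    if (length(x) < 3L) return(NA_real_)
    if (stats::sd(x) == 0 || stats::sd(x[-1L]) == 0 || stats::sd(x[-length(x)]) == 0)
      return(NA_real_)
    stats::cor(x[-length(x)], x[-1L])
  }, numeric(1L))
  if (anyNA(acs)) {
    warning(sum(is.na(acs)), " chromosome(s) excluded from MAC (too short or zero variance)")
    acs <- acs[!is.na(acs)]
  }
  if (!length(acs)) stop("MAC undefined: no usable chromosome")
  stats::median(acs)
}

.check_track <- function(track) {
  stopifnot(all(c("chrom", "pos", "log2") %in% names(track)))
  ok <- vapply(split(track$pos, track$chrom),
               function(p) all(diff(p) > 0), logical(1L))
  if (!all(ok)) stop("probe positions must be strictly increasing within a chromosome")
}

#' Array QC verdict
#'
#' @param track probe-level log2 track (see [compute_mapd()]).
#' @param max_mapd,max_mac discard cutoffs; the boundary values themselves
#'   pass.
#' @return list with `mapd`, `mac`, `pass`.
#' @export
qc_metrics <- function(track, max_mapd = 0.7, max_mac = 0.3) {
  mapd <- compute_mapd(track)
  mac <- compute_mac(track)
  list(mapd = mapd, mac = mac, pass = !(mapd > max_mapd || mac > max_mac))
}

#' Merge segments closer than three standard deviations
#'
#' Iteratively merges each segment with its immediate neighbour (leftmost
#' pair first) when the difference of their mean log2 values is below
#' `n_sd` pooled probe standard deviations, recomputing the pooled
#' statistics after each merge, until a fixed point is reached.  Merging
#' never crosses a chromosome boundary and never changes the spanned
#' genome.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `mean`, `sd`, `n_probes` (per-segment probe statistics), ordered by
#'   position within chromosome.
#' @param n_sd merge cutoff in pooled standard deviations.
#' @return merged segment data.frame with recomputed statistics.
#' @export
merge_close_segments <- function(segments, n_sd = 3) {
  stopifnot(all(c("chrom", "start", "end", "mean", "sd", "n_probes") %in%
                  names(segments)))
  out <- lapply(split(segments, segments$chrom), .merge_chrom, n_sd = n_sd)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

.merge_chrom <- function(seg, n_sd) {
  seg <- seg[order(seg$start), , drop = FALSE]
  repeat {
    if (nrow(seg) < 2L) return(seg)
    merged <- FALSE
    for (i in seq_len(nrow(seg) - 1L)) {
      # merge criterion: mean gap against the pooled *within-segment*
      # probe noise (the gap itself must not inflate the reference s.d.)
      s_w <- sqrt(((seg$n_probes[i] - 1) * seg$sd[i]^2 +
                     (seg$n_probes[i + 1L] - 1) * seg$sd[i + 1L]^2) /
                    max(seg$n_probes[i] + seg$n_probes[i + 1L] - 2, 1))
      s <- .pooled_sd(seg$sd[i], seg$n_probes[i], seg$mean[i],
                      seg$sd[i + 1L], seg$n_probes[i + 1L], seg$mean[i + 1L])
      if (abs(seg$mean[i] - seg$mean[i + 1L]) < n_sd * s_w) {
        seg$end[i] <- seg$end[i + 1L]
        seg$mean[i] <- s$mean
        seg$sd[i] <- s$sd
        seg$n_probes[i] <- seg$n_probes[i] + seg$n_probes[i + 1L]
        seg <- seg[-(i + 1L), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(seg)
  }
}

# pooled mean/sd of two probe sets from their sufficient statistics
.pooled_sd <- function(sd1, n1, m1, sd2, n2, m2) {
  n <- n1 + n2
  m <- (n1 * m1 + n2 * m2) / n
  ss <- (n1 - 1) * sd1^2 + (n2 - 1) * sd2^2 + n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  list(mean = m, sd = sqrt(ss / max(n - 1, 1)))
}

#' Mask high-copy loci before phylogenetic reconstruction
#'
#' The integer caller truncates total copy numbers at 8, making high-copy
#' calls unreliable: any segment with total copy number 8 or a major
#' allele count above 4 in any sample is removed from all matched samples
#' of the patient — except for high-ploidy tumours, where the rule would
#' erase most of the genome and is skipped.
#'
#' @param profiles segment data.frame (`sample`, `chrom`, `start`, `end`,
#'   `total`, `major`, `minor`) of one patient, shared boundaries.
#' @param high_ploidy logical flag for the patient.
#' @param max_total,max_major masking cutoffs.
#' @return profiles with masked segments removed; attribute
#'   `masked_segments` lists the removed (chrom, start, end) keys (SNVs at
#'   those loci must also be excluded from CCF estimation).
#' @export
mask_high_copy <- function(profiles, high_ploidy = FALSE, max_total = 8L,
                           max_major = 4L) {
  stopifnot(all(c("sample", "chrom", "start", "end", "total", "major") %in%
                  names(profiles)))
  if (high_ploidy) {
    attr(profiles, "masked_segments") <- character(0)
    return(profiles)
  }
  key <- paste(profiles$chrom, profiles$start, profiles$end, sep = ":")
  bad <- unique(key[profiles$total >= max_total | profiles$major > max_major])
  out <- profiles[!key %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "masked_segments") <- bad
  out
}

#' Flag SNVs falling in masked segments
#'
#' @param snv_info data.frame with `snv`, `chrom`, `pos`.
#' @param masked_segments character keys `"chrom:start:end"` from
#'   [mask_high_copy()].
#' @return logical vector (TRUE = masked) aligned to `snv_info` rows.
#' @export
snvs_in_masked <- function(snv_info, masked_segments) {
  if (!length(masked_segments)) return(rep(FALSE, nrow(snv_info)))
  parts <- do.call(rbind, strsplit(masked_segments, ":", fixed = TRUE))
  segs <- data.frame(chrom = parts[, 1L], start = as.numeric(parts[, 2L]),
                     end = as.numeric(parts[, 3L]), stringsAsFactors = FALSE)
  vapply(seq_len(nrow(snv_info)), function(i) {
    any(segs$chrom == as.character(snv_info$chrom[i]) &
          segs$start <= snv_info$pos[i] & segs$end >= snv_info$pos[i])
  }, logical(1L))
}
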
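# Cancer cell fraction (CCF) estimation from ultra-deep read counts.
#
# For an SNV carried on s_q of the q_2 major-allele copies (s_q in 1..q_2)
# at a locus with total copy number q_t in a sample with CCF alpha, the
# expected variant allele frequency is
#
#     f = s_q * alpha / (q_t * alpha + 2 * (1 - alpha)),
#
# and sequencing error e (misreads hitting the specific alternate base with
# probability e/3) shifts the binomial success probability to
# f * (1 - e) + (1 - f) * e / 3.  The per-sample global CCF maximizes a
# binomial mixture likelihood over all usable SNVs, with mixture weights
# over s_q adjusted iteratively (EM) at each candidate alpha.

#' Expected variant allele frequency
#'
#' @param s_q number of mutated copies (1..q_t).
#' @param q_t total copy number at the locus.
#' @param alpha cancer cell fraction in (0, 1].
#' @param e sequencing error rate; `e > 0` returns the error-adjusted
#'   binomial success probability `f (1 - e) + (1 - f) e/3`.
#' @return expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(s_q, q_t, alpha, e = 0) {
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must be in (0, 1]")
  if (any(s_q < 1) || any(s_q > q_t)) stop("s_q must be in 1..q_t")
  if (any(q_t == 0)) stop("q_t = 0 is undefined for a mutated locus")
  f <- s_q * alpha / (q_t * alpha + 2 * (1 - alpha))
  f * (1 - e) + (1 - f) * e / 3
}

.adjust_error <- function(f, e) e / 3 + f * (1 - 4 * e / 3)
.deadjust_error <- function(p, e) pmin(pmax((p - e / 3) / (1 - 4 * e / 3), 0), 1)

#' Pointwise CCF estimate for a single SNV
#'
#' Posterior over the number of mutated copies `s_q` (uniform prior times
#' binomial likelihood at the error-adjusted expected VAF, with the global
#' CCF as plug-in), and a point CCF obtained by inverting the expected-VAF
#' relation at the posterior-mode multiplicity:
#' `alpha_hat = 2 f / (s_q - f q_t + 2 f)`.
#'
#' @param X variant read count.
#' @param n total read count.
#' @param q_t,q1,q2 total / minor / major copy numbers at the locus.
#' @param alpha plug-in CCF (e.g. from a SNP array or [global_ccf()]).
#' @param e sequencing error rate.
#' @return list: `posterior` (named over s_q), `s_mode`, `alpha_point` in
#'   `[0, 1]`, `saturated` (inversion denominator <= 0; estimate pinned at
#'   1), `near_zero` (no evidence of presence).
#' @export
pointwise_ccf <- function(X, n, q_t, q1, q2, alpha, e = 0.01) {
  stopifnot(q2 >= 1, q1 + q2 == q_t, X >= 0, X <= n)
  s <- seq_len(q2)
  p <- vapply(s, function(si) expected_vaf(si, q_t, alpha, e = e), numeric(1L))
  ll <- stats::dbinom(X, n, p, log = TRUE)
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  names(post) <- s
  s_mode <- s[which.max(post)]
  f_hat <- .deadjust_error(X / n, e)
  den <- s_mode - f_hat * q_t + 2 * f_hat
  a_hat <- if (den <= 0) Inf else 2 * f_hat / den
  saturated <- a_hat > 1   # no CCF in (0,1] explains so high a VAF
  a_hat <- min(max(a_hat, 0), 1)
  list(posterior = post, s_mode = s_mode, alpha_point = a_hat,
       saturated = saturated, near_zero = a_hat < 1e-3)
}

#' Global CCF by maximizing the binomial mixture likelihood
#'
#' For each candidate `alpha` on a grid, mixture weights over the number of
#' mutated copies are shared across SNVs with the same copy state and
#' adjusted by expectation-maximization until the log-likelihood changes by
#' less than `tol` or `max_iter` iterations are reached; the global CCF is
#' the grid value maximizing the converged likelihood.
#'
#' @param snvs data.frame with columns `X`, `n`, `q_t`, `q1`, `q2` (one row
#'   per usable tier-4 SNV present in the sample); rows with a `masked`
#'   column set to `TRUE` are dropped.
#' @param alpha_grid candidate CCF values.
#' @param e sequencing error rate.
#' @param max_iter,tol EM control.
#' @return object of class `ccf_estimate`: `alpha`, `loglik` (per grid
#'   point), `trace` (iterations x grid log-likelihood matrix), `per_snv`
#'   (pointwise estimates at the global alpha), `clonal_frequency`.
#' @export
global_ccf <- function(snvs, alpha_grid = seq(0.02, 1, by = 0.01), e = 0.01,
                       max_iter = 100L, tol = 1e-6) {
  if (!is.null(snvs$masked)) snvs <- snvs[!snvs$masked, , drop = FALSE]
  if (nrow(snvs) == 0L) stop("no usable SNVs: all at masked loci or none supplied")
  if (nrow(snvs) < 5L) stop("need at least 5 usable SNVs")
  A <- length(alpha_grid)
  groups <- split(seq_len(nrow(snvs)), paste(snvs$q_t, snvs$q2))

  glik <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    q_t <- snvs$q_t[rows[1L]]
    q2 <- snvs$q2[rows[1L]]
    s <- seq_len(q2)
    # log lik[i, s, a], kept on log scale throughout
    lik <- array(NA_real_, c(length(rows), length(s), A))
    for (ai in seq_len(A)) {
      p <- expected_vaf(s, rep(q_t, length(s)), alpha_grid[ai], e = e)
      for (si in seq_along(s)) {
        lik[, si, ai] <- stats::dbinom(snvs$X[rows], snvs$n[rows], p[si],
                                       log = TRUE)
      }
    }
    glik[[gi]] <- lik
  }

  W <- lapply(glik, function(lik) {
    S <- dim(lik)[2L]
    matrix(1 / S, S, A)
  })
  trace <- matrix(NA_real_, 0L, A)
  ll_prev <- rep(-Inf, A)
  for (it in seq_len(max_iter)) {
    ll <- rep(0, A)
    Wnew <- W
    for (gi in seq_along(glik)) {
      lik <- glik[[gi]]
      ni <- dim(lik)[1L]; S <- dim(lik)[2L]
      for (ai in seq_len(A)) {
        lw <- sweep(matrix(lik[, , ai], ni, S), 2L,
                    log(W[[gi]][, ai]), "+")
        lw <- pmax(lw, -745)             # floor far-tail underflow
        mx <- apply(lw, 1L, max)
        ew <- exp(lw - mx)
        denom <- rowSums(ew)
        ll[ai] <- ll[ai] + sum(mx + log(denom))
        resp <- ew / denom
        Wnew[[gi]][, ai] <- colSums(resp) / ni
      }
    }
    trace <- rbind(trace, ll)
    if (all(abs(ll - ll_prev) < tol)) { W <- Wnew; break }
    ll_prev <- ll
    W <- Wnew
  }
  ll_final <- trace[nrow(trace), ]
  alpha <- alpha_grid[which.max(ll_final)]

  per <- lapply(seq_len(nrow(snvs)), function(i) {
    pointwise_ccf(snvs$X[i], snvs$n[i], snvs$q_t[i], snvs$q1[i], snvs$q2[i],
                  alpha = alpha, e = e)
  })
  alpha_point <- vapply(per, `[[`, numeric(1L), "alpha_point")
  structure(list(alpha = alpha, alpha_grid = alpha_grid, loglik = ll_final,
                 trace = unname(trace),
                 per_snv = data.frame(
                   X = snvs$X, n = snvs$n, q_t = snvs$q_t, q2 = snvs$q2,
                   s_mode = vapply(per, `[[`, numeric(1L), "s_mode"),
                   alpha_point = alpha_point,
                   clonal_frequency = clonal_frequency(alpha_point, alpha)),
                 weights = W, n_iter = nrow(trace)),
            class = "ccf_estimate")
}

#' @export
print.ccf_estimate <- function(x, ...) {
  cat(sprintf("Global CCF estimate: alpha = %.2f (%d SNVs, %d EM iterations)\n",
              x$alpha, nrow(x$per_snv), x$n_iter))
  invisible(x)
}

#' Clonal frequency of an SNV
#'
#' Ratio of the pointwise CCF to the sample's global CCF, capped at 1:
#' fully clonal mutations have value ~1, mutations confined to a subclone
#' (or acquired by cross-seeding) have proportionally smaller values.
#'
#' @param alpha_point per-SNV pointwise CCF.
#' @param alpha global CCF of the sample.
#' @return fraction in `[0, 1]`.
#' @export
clonal_frequency <- function(alpha_point, alpha) {
  pmin(1, alpha_point / alpha)
}

#' Probability of detecting a mutation at a given depth
#'
#' Probability that a binomial draw at the error-adjusted expected VAF
#' reaches the presence cutoff, used to certify that a predicted reversion
#' is not explainable as a false-negative call.
#'
#' @param n sequencing depth.
#' @param expected_f expected VAF if the mutation were present.
#' @param e sequencing error rate.
#' @param threshold VAF presence cutoff.
#' @return detection probability.
#' @export
detection_power <- function(n, expected_f, e = 0.01, threshold = 0.03) {
  stopifnot(n >= 1)
  p <- .adjust_error(expected_f, e)
  kmin <- ceiling(n * threshold - 1e-9)
  stats::pbinom(kmin - 1, n, p, lower.tail = FALSE)
}

#' Per-patient CCF estimation across samples
#'
#' Convenience wrapper running [global_ccf()] per sample over the SNVs
#' present in the tier matrix, joining read counts with the local
#' allele-specific copy state, and returning per-SNV clonal frequencies.
#' SNVs at loci with no remaining major-allele copy in a sample, or inside
#' `masked_segments`, are excluded from that sample's fit.
#'
#' @param obs variant observations (as from [emit_read_counts()]): columns
#'   `sample`, `snv`, `chrom`, `pos`, `alt_reads`, `depth`.
#' @param profiles segment table with `sample`, `chrom`, `start`, `end`,
#'   `total`, `major`, `minor`.
#' @param tm `tier_matrix` for the patient.
#' @param masked_segments optional `"chrom:start:end"` keys from
#'   [mask_high_copy()].
#' @param e sequencing error rate.
#' @param ... passed to [global_ccf()].
#' @return list: `alpha` (named per-sample global CCF), `clonal_frequency`
#'   and `alpha_point` (samples x SNVs matrices, `NA` where absent or
#'   unusable), `estimates` (per-sample `ccf_estimate` objects).
#' @export
estimate_patient_ccf <- function(obs, profiles, tm, masked_segments = NULL,
                                 e = 0.01, ...) {
  stopifnot(inherits(tm, "tier_matrix"))
  samples <- rownames(tm$calls)
  snvs <- colnames(tm$calls)
  obs <- obs[obs$sample %in% samples & obs$snv %in% snvs, , drop = FALSE]
  masked_by_pos <- if (is.null(masked_segments)) rep(FALSE, length(snvs)) else {
    info <- unique(obs[match(snvs, obs$snv), c("snv", "chrom", "pos")])
    snvs_in_masked(info, masked_segments)
  }
  cf <- ap <- matrix(NA_real_, length(samples), length(snvs),
                     dimnames = list(samples, snvs))
  alphas <- stats::setNames(rep(NA_real_, length(samples)), samples)
  ests <- vector("list", length(samples))
  names(ests) <- samples
  for (s in samples) {
    o <- obs[obs$sample == s, , drop = FALSE]
    o <- o[match(snvs, o$snv), , drop = FALSE]
    prof <- profiles[profiles$sample == s, , drop = FALSE]
    segi <- vapply(seq_len(nrow(o)), function(i) {
      w <- which(prof$chrom == o$chrom[i] & prof$start <= o$pos[i] &
                   prof$end >= o$pos[i])
      if (length(w)) w[1L] else NA_integer_
    }, integer(1L))
    df <- data.frame(snv = snvs, X = o$alt_reads, n = o$depth,
                     q_t = prof$total[segi], q1 = prof$minor[segi],
                     q2 = prof$major[segi], stringsAsFactors = FALSE)
    usable <- !is.na(tm$calls[s, ]) & tm$calls[s, ] == 1L &
      !is.na(df$q2) & df$q2 >= 1L & !masked_by_pos
    if (sum(usable) < 5L) {
      warning("sample ", s, ": fewer than 5 usable SNVs, no global CCF")
      next
    }
    est <- global_ccf(df[usable, , drop = FALSE], e = e, ...)
    ests[[s]] <- est
    alphas[s] <- est$alpha
    ap[s, usable] <- est$per_snv$alpha_point
    cf[s, usable] <- est$per_snv$clonal_frequency
  }
  list(alpha = alphas, clonal_frequency = cf, alpha_point = ap,
       estimates = ests)
}
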
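# Distance-aware 5-state HMM for CNV calling from LRR/BAF, PennCNV-style:
# states are copy numbers 0..4, transitions relax toward a stationary
# distribution with inter-marker distance, emissions combine a Gaussian LRR
# term with a Hardy-Weinberg-weighted BAF cluster mixture.

#' HMM parameters for the CNV caller
#'
#' @param lrr_means named LRR emission means per copy number 0..4.
#' @param lrr_sds named LRR emission sds per copy number (CN0 is wide: with
#'   no DNA present the intensity log-ratio is essentially noise).
#' @param baf_noise_sd sd of the truncated-Gaussian BAF clusters.
#' @param pi_stationary stationary state distribution; heavily favours the
#'   diploid state.
#' @param p_offdiag off-diagonal transition probability at zero distance.
#' @param distance_scale bp constant D: at inter-marker distance d the
#'   transition row is exp(-d/D) times the near-identity base matrix plus
#'   (1 - exp(-d/D)) times the stationary distribution.
#' @return list of class \code{hmm_params}.
#' @export
hmm_params <- function(lrr_means = default_lrr_means(),
                       lrr_sds = c("0" = 1.0, "1" = 0.30, "2" = 0.20, "3" = 0.25, "4" = 0.30),
                       baf_noise_sd = 0.05,
                       pi_stationary = c("0" = 0.0005, "1" = 0.005, "2" = 0.9885,
                                         "3" = 0.005, "4" = 0.001),
                       p_offdiag = 1e-4,
                       distance_scale = 1e5) {
  states <- as.character(0:4)
  stopifnot(all(states %in% names(lrr_means)), all(states %in% names(lrr_sds)))
  if (any(lrr_sds <= 0) || baf_noise_sd <= 0) stop("emission sds must be > 0")
  pi_stationary <- pi_stationary[states] / sum(pi_stationary[states])
  base <- matrix(p_offdiag, 5, 5, dimnames = list(states, states))
  diag(base) <- 1 - 4 * p_offdiag
  structure(list(
    states = 0:4,
    lrr_means = lrr_means[states], lrr_sds = lrr_sds[states],
    baf_noise_sd = baf_noise_sd,
    pi_stationary = pi_stationary,
    transition_base = base,
    distance_scale = distance_scale
  ), class = "hmm_params")
}

#' Distance-dependent transition matrix
#'
#' a(d) = w * A0 + (1 - w) * Pi with w = exp(-d / D), where A0 is the
#' near-identity base matrix and Pi has the stationary distribution in every
#' row.  Rows sum to 1 at every distance; as d grows, markers decouple and
#' the chain forgets its state.
#'
#' @param d inter-marker distance in bp.
#' @param params \code{\link{hmm_params}}.
#' @return 5x5 transition probability matrix.
#' @export
transition_matrix <- function(d, params) {
  w <- exp(-d / params$distance_scale)
  w * params$transition_base +
    (1 - w) * matrix(params$pi_stationary, 5, 5, byrow = TRUE,
                     dimnames = dimnames(params$transition_base))
}

# attainable BAF cluster means and Hardy-Weinberg weights at copy number cn
# and population B-allele frequency pfb; CN0 emits uniform BAF.
baf_mixture <- function(cn, pfb) {
  if (cn == 0L) return(NULL)
  k <- 0:cn
  list(means = k / cn, weights = dbinom(k, cn, pfb))
}

# truncated normal density on [0,1]; recycles over either x or mean
dtnorm01 <- function(x, mean, sd) {
  z <- pnorm(1, mean, sd) - pnorm(0, mean, sd)
  dnorm(x, mean, sd) / z * as.numeric(x >= 0 & x <= 1)
}

#' Joint LRR/BAF emission log-likelihood
#'
#' Log of the product of a Gaussian LRR density and a BAF mixture density.
#' The BAF mixture components sit at the allelic ratios attainable at the
#' copy number (CN2: 0, 1/2, 1; CN3: 0, 1/3, 2/3, 1; ...), each a normal
#' truncated to [0,1], weighted by Hardy--Weinberg genotype probabilities at
#' the marker's PFB.  CN0 has no B-allele signal and emits uniform BAF.
#'
#' @param lrr_value,baf_value observed signals at one marker.
#' @param pfb population B-allele frequency in [0,1].
#' @param state copy number in 0..4.
#' @param params \code{\link{hmm_params}}.
#' @return log-density (finite for interior BAF values).
#' @export
emission_loglik <- function(lrr_value, baf_value, pfb, state, params = hmm_params()) {
  if (!is.finite(lrr_value) || !is.finite(baf_value) || !is.finite(pfb))
    stop("non-finite emission inputs")
  if (pfb < 0 || pfb > 1) stop("pfb outside [0,1]")
  if (!state %in% 0:4) stop("state must be in 0..4")
  s <- as.character(state)
  ll_lrr <- dnorm(lrr_value, params$lrr_means[[s]], params$lrr_sds[[s]], log = TRUE)
  if (state == 0L) {
    dens <- if (baf_value >= 0 && baf_value <= 1) 1 else 0
  } else {
    mix <- baf_mixture(as.integer(state), pfb)
    dens <- sum(mix$weights * dtnorm01(baf_value, mix$means, params$baf_noise_sd))
  }
  ll_lrr + log(dens)
}

# 5 x n matrix of emission log-likelihoods for one chromosome, vectorised
# over markers.
emission_matrix <- function(lrr, baf, pfb, params) {
  n <- length(lrr)
  E <- matrix(NA_real_, 5, n)
  for (s in 0:4) {
    ll <- dnorm(lrr, params$lrr_means[[s + 1L]], params$lrr_sds[[s + 1L]], log = TRUE)
    if (s == 0L) {
      dens <- as.numeric(baf >= 0 & baf <= 1)
    } else {
      dens <- 0
      for (k in 0:s) {
        dens <- dens + dbinom(k, s, pfb) * dtnorm01(baf, k / s, params$baf_noise_sd)
      }
    }
    E[s + 1L, ] <- ll + log(dens)
  }
  E
}

#' Viterbi decoding of the copy-number state path
#'
#' Per-chromosome maximum a posteriori state path under the
#' distance-modulated HMM.  Ties are broken toward the lower copy number
#' (then the earlier state index), making the decode deterministic.
#'
#' @param signal list with \code{lrr} and \code{baf} aligned to \code{map}.
#' @param map marker map (same row order as the signal vectors).
#' @param params \code{\link{hmm_params}}.
#' @return integer vector of copy numbers (0..4), one per marker, in map
#'   order.
#' @export
viterbi_decode <- function(signal, map, params = hmm_params()) {
  if (length(signal$lrr) != nrow(map) || length(signal$baf) != nrow(map))
    stop("signal length must equal map length")
  path <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2L) stop("chromosome ", ch, " has < 2 markers")
    path[idx] <- viterbi_chrom(signal$lrr[idx], signal$baf[idx],
                               map$pfb[idx], map$pos[idx], params)
  }
  path
}

viterbi_chrom <- function(lrr, baf, pfb, pos, params) {
  n <- length(lrr)
  E <- emission_matrix(lrr, baf, pfb, params)
  delta <- matrix(-Inf, 5, n)
  psi <- matrix(0L, 5, n)
  delta[, 1] <- log(params$pi_stationary) + E[, 1]
  for (t in 2:n) {
    logA <- log(transition_matrix(pos[t] - pos[t - 1L], params))
    cand <- delta[, t - 1L] + logA          # cand[i, j]: from state i to j
    best <- apply_colwise_argmax(cand)
    psi[, t] <- best$arg
    delta[, t] <- best$max + E[, t]
  }
  states <- integer(n)
  states[n] <- which.max(delta[, n])        # which.max: first (lowest CN) on ties
  for (t in (n - 1L):1L) if (n > 1L) states[t] <- psi[states[t + 1L], t + 1L]
  states - 1L
}

# column-wise max and first-argmax of a 5x5 matrix (ties -> lowest row
# index, i.e. lowest copy number)
apply_colwise_argmax <- function(m) {
  arg <- max.col(t(m), ties.method = "first")
  list(arg = arg, max = m[cbind(arg, seq_len(ncol(m)))])
}

#' Extract filtered CNV calls from a decoded state path
#'
#' Maximal runs of a constant non-diploid state become candidate calls with
#' boundaries at the outermost marker positions of the run (1-based
#' inclusive).  Candidates with fewer than \code{min_snps} markers or
#' shorter than \code{min_length_bp} are dropped.
#'
#' @param path integer copy-number path from \code{\link{viterbi_decode}}.
#' @param map marker map aligned to the path.
#' @param sample_id sample label for the emitted calls.
#' @param min_snps minimum markers per call (default 3).
#' @param min_length_bp minimum call span in bp (default 1000).
#' @return data.frame of calls: \code{sample_id}, \code{chrom},
#'   \code{start_pos}, \code{end_pos}, \code{state}, \code{cnv_type},
#'   \code{n_snps}, \code{length_bp}; zero rows if nothing survives.
#' @export
extract_calls <- function(path, map, sample_id,
                          min_snps = 3L, min_length_bp = 1000L) {
  stopifnot(length(path) == nrow(map))
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    r <- rle(path[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      st <- r$values[j]
      if (st == 2L) next
      i1 <- idx[starts[j]]; i2 <- idx[ends[j]]
      n_snps <- r$lengths[j]
      len <- map$pos[i2] - map$pos[i1] + 1L
      if (n_snps < min_snps || len < min_length_bp) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = ch,
        start_pos = map$pos[i1], end_pos = map$pos[i2],
        state = st, cnv_type = if (st < 2L) "deletion" else "duplication",
        n_snps = n_snps, length_bp = len, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(map$chrom)), res$start_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @keywords internal
empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_pos = integer(), end_pos = integer(), state = integer(),
             cnv_type = character(), n_snps = integer(), length_bp = integer(),
             stringsAsFactors = FALSE)
}

#' Call CNVs for one sample (decode + extract)
#'
#' @inheritParams viterbi_decode
#' @inheritParams extract_calls
#' @return data.frame of filtered calls.
#' @export
call_cnvs <- function(signal, map, params = hmm_params(),
                      min_snps = 3L, min_length_bp = 1000L) {
  path <- viterbi_decode(signal, map, params)
  extract_calls(path, map, signal$sample_id, min_snps, min_length_bp)
}

#' Compile a PFB table from sample BAFs
#'
#' Per-marker median B allele frequency across a set of samples, the
#' standard way a population-specific PFB file is built when no reference
#' file is available for the array.
#'
#' @param signals list of signals as returned by \code{\link{simulate_signals}}.
#' @param map marker map.
#' @return data.frame \code{marker_id}, \code{chrom}, \code{pos}, \code{pfb}.
#' @export
compile_pfb <- function(signals, map) {
  if (!length(signals)) stop("no signals supplied")
  bafs <- vapply(signals, function(s) s$baf, numeric(nrow(map)))
  data.frame(marker_id = map$marker_id, chrom = map$chrom, pos = map$pos,
             pfb = apply(bafs, 1, median), stringsAsFactors = FALSE)
}
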
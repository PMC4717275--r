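# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive: they re-derive quantities from first principles and
# never call the implementation paths they are used to check.

# --- tiny deterministic marker map -----------------------------------------
toy_map <- function(n = 10, chrom = "chr1", spacing = 2000, pfb = 0.5, gc = 0.5) {
  data.frame(marker_id = sprintf("%s_m%03d", chrom, seq_len(n)),
             chrom = chrom, pos = seq_len(n) * spacing,
             pfb = rep_len(pfb, n), gc = rep_len(gc, n),
             stringsAsFactors = FALSE)
}

# --- exhaustive Viterbi oracle ---------------------------------------------
# Enumerates all 5^n state paths and scores each with the same model
# quantities (initial distribution, distance transitions, emissions),
# computed independently of the DP code.
path_cache <- new.env(parent = emptyenv())

all_paths <- function(n) {
  key <- as.character(n)
  if (is.null(path_cache[[key]])) {
    path_cache[[key]] <- as.matrix(expand.grid(rep(list(1:5), n)))
  }
  path_cache[[key]]
}

enum_best_path <- function(signal, map, params) {
  n <- nrow(map)
  P <- all_paths(n)
  E <- matrix(NA_real_, 5, n)
  for (s in 0:4) for (t in seq_len(n)) {
    E[s + 1, t] <- emission_loglik(signal$lrr[t], signal$baf[t], map$pfb[t], s, params)
  }
  score <- log(params$pi_stationary)[P[, 1]]
  for (t in seq_len(n)) score <- score + E[cbind(P[, t], t)]
  for (t in seq_len(n - 1)) {
    logA <- log(transition_matrix(map$pos[t + 1] - map$pos[t], params))
    score <- score + logA[cbind(P[, t], P[, t + 1])]
  }
  best <- which.max(score)
  list(path = unname(P[best, ]) - 1L, score = max(score))
}

# score an arbitrary path under the model (for monotonicity checks)
score_path <- function(path, signal, map, params) {
  n <- nrow(map)
  sc <- unname(log(params$pi_stationary)[path[1] + 1])
  for (t in seq_len(n)) {
    sc <- sc + emission_loglik(signal$lrr[t], signal$baf[t], map$pfb[t], path[t], params)
  }
  for (t in seq_len(n - 1)) {
    logA <- log(transition_matrix(map$pos[t + 1] - map$pos[t], params))
    sc <- sc + logA[path[t] + 1, path[t + 1] + 1]
  }
  sc
}

# --- brute-force region merge oracle ---------------------------------------
# all-pairs overlap test + repeated transitive closure via matrix powers
oracle_merge <- function(calls, min_frac, n_passing) {
  out <- list()
  for (type in unique(calls$cnv_type)) for (ch in unique(calls$chrom)) {
    cc <- calls[calls$cnv_type == type & calls$chrom == ch, , drop = FALSE]
    n <- nrow(cc)
    if (n == 0) next
    adj <- diag(n) > 0
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        a <- list(chrom = ch, start_pos = cc$start_pos[i], end_pos = cc$end_pos[i])
        b <- list(chrom = ch, start_pos = cc$start_pos[j], end_pos = cc$end_pos[j])
        if (overlap_fraction_shorter(a, b) >= min_frac) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    reach <- adj
    for (k in seq_len(n)) reach <- (reach %*% adj) > 0 | reach   # transitive closure
    comp <- rep(NA_integer_, n)
    g <- 0L
    for (i in seq_len(n)) {
      if (is.na(comp[i])) { g <- g + 1L; comp[which(reach[i, ])] <- g }
    }
    for (gg in unique(comp)) {
      rows <- cc[comp == gg, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_pos = min(rows$start_pos), end_pos = max(rows$end_pos),
        cnv_type = type, n_carriers = length(unique(rows$sample_id)),
        frequency = length(unique(rows$sample_id)) / n_passing,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_pos, res$cnv_type, res$end_pos), , drop = FALSE]
}

random_calls <- function(n, n_samples = 8, chroms = c("chr1", "chr2")) {
  start <- sample.int(5e4, n, replace = TRUE)
  len <- sample.int(2e4, n, replace = TRUE) + 999L
  data.frame(sample_id = sprintf("S%02d", sample.int(n_samples, n, replace = TRUE)),
             chrom = sample(chroms, n, replace = TRUE),
             start_pos = start, end_pos = start + len,
             state = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
             stringsAsFactors = FALSE) -> d
  d$cnv_type <- ifelse(d$state < 2, "deletion", "duplication")
  d$n_snps <- 5L
  d$length_bp <- d$end_pos - d$start_pos + 1L
  d
}

# --- textbook delayed-entry Cox partial log-likelihood ----------------------
# Breslow form (exact equal to Efron when there are no tied event times).
cox_pll <- function(beta, entry, exit, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    t <- exit[i]
    at_risk <- entry < t & exit >= t
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# two-group exponential survival fixture with planted hazard ratio
exp_fixture <- function(n = 40, hr = 2, seed = 1) {
  set.seed(seed)
  x <- rep(0:1, each = n / 2)
  t <- rexp(n, rate = 0.1 * hr^x)
  cens <- rexp(n, rate = 0.02)
  data.frame(entry_age = 0, exit_age = pmax(pmin(t, cens), 1e-6),
             event = as.integer(t <= cens), x = x)
}
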
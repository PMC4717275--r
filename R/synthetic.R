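# Synthetic cohort generator: marker maps, LRR/BAF signals with implanted
# CNVs, and left-truncated Gompertz proportional-hazards survival outcomes.

#' Default LRR emission means by copy number
#'
#' Canonical log R ratio shifts for copy numbers 0--4 on Illumina-style
#' arrays: a homozygous deletion all but abolishes signal (-3.5), a
#' hemizygous deletion gives about -0.66, and one or two extra copies give
#' +0.40 and +0.68.  Used both by the signal generator and as the default
#' emission means of the HMM caller; both accept overrides.
#'
#' @return Named numeric vector, names "0".."4".
#' @export
default_lrr_means <- function() {
  c("0" = -3.5, "1" = -0.66, "2" = 0, "3" = 0.40, "4" = 0.68)
}

#' Simulate an ordered autosomal SNP marker map
#'
#' Generates a marker map emulating a dense genotyping array.  Inter-marker
#' gaps are drawn from a log-normal distribution whose median equals
#' \code{target_median_spacing} and whose mean is
#' \code{target_mean_spacing}, reproducing the heavy right tail of real
#' array spacing (defaults 2.1 kb median, 4.0 kb mean).  Population B-allele
#' frequencies are a mixture of near-monomorphic (near 0 or 1) and uniform
#' components; local GC content is a smooth long-range (Mb-scale) process
#' confined to [0.3, 0.7].
#'
#' @param n_markers total number of markers, allocated to chromosomes
#'   proportionally to \code{chrom_lengths} (at least 2 per chromosome).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names are autosome labels.
#' @param target_median_spacing target median inter-marker gap in bp.
#' @param target_mean_spacing target mean gap in bp; must exceed the median.
#' @param seed integer seed.
#' @return data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos}, \code{pfb}, \code{gc}; positions strictly increasing within
#'   each chromosome.
#' @export
simulate_marker_map <- function(n_markers,
                                chrom_lengths = c(chr1 = 50e6),
                                target_median_spacing = 2100,
                                target_mean_spacing = 4000,
                                seed = 1L) {
  if (length(chrom_lengths) == 0) stop("chrom_lengths must name at least one chromosome")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (!is.finite(target_median_spacing) || target_median_spacing <= 0)
    stop("target_median_spacing must be positive")
  if (target_mean_spacing < target_median_spacing)
    stop("target_mean_spacing must be >= target_median_spacing")
  n_chrom <- length(chrom_lengths)
  if (n_markers < 2 * n_chrom) stop("need at least 2 markers per chromosome")

  set.seed(seed)
  # allocate proportionally, guaranteeing >= 2 per chromosome
  alloc <- pmax(2L, floor(n_markers * chrom_lengths / sum(chrom_lengths)))
  while (sum(alloc) > n_markers) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_markers) alloc[which.max(chrom_lengths)] <- alloc[which.max(chrom_lengths)] + 1L

  # log-normal gaps: median = exp(mu), mean = exp(mu + s^2/2)
  mu <- log(target_median_spacing)
  s  <- sqrt(2 * log(target_mean_spacing / target_median_spacing))

  pieces <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    n <- alloc[i]
    gaps <- exp(rnorm(n, mu, s))
    pos <- as.integer(round(cumsum(pmax(1, gaps))))
    pos <- pos + seq_len(n) - 1L          # enforce strict monotonicity after rounding
    # PFB mixture: 15% near-0 monomorphic, 15% near-1, 70% common variation
    comp <- sample.int(3L, n, replace = TRUE, prob = c(0.15, 0.15, 0.70))
    pfb <- numeric(n)
    pfb[comp == 1L] <- stats::rbeta(sum(comp == 1L), 1, 50)
    pfb[comp == 2L] <- stats::rbeta(sum(comp == 2L), 50, 1)
    pfb[comp == 3L] <- runif(sum(comp == 3L))
    # GC: sum of three Mb-scale sinusoids with random period/phase
    period <- runif(3, 1e6, 5e6)
    phase <- runif(3, 0, 2 * pi)
    amp <- runif(3, 0.03, 0.09)
    gc <- 0.5
    for (k in 1:3) gc <- gc + amp[k] * sin(2 * pi * pos / period[k] + phase[k])
    gc <- pmin(0.7, pmax(0.3, gc))
    pieces[[i]] <- data.frame(
      marker_id = sprintf("%s_m%06d", names(chrom_lengths)[i], seq_len(n)),
      chrom = names(chrom_lengths)[i],
      pos = pos, pfb = pfb, gc = gc,
      stringsAsFactors = FALSE
    )
  }
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  validate_marker_map(map)
  map
}

#' @keywords internal
validate_marker_map <- function(map) {
  stopifnot(all(c("marker_id", "chrom", "pos", "pfb", "gc") %in% names(map)))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker_id in map")
  if (any(map$pfb < 0 | map$pfb > 1)) stop("pfb outside [0,1]")
  if (any(map$gc < 0 | map$gc > 1)) stop("gc outside [0,1]")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  invisible(map)
}

#' Simulate ground-truth CNVs for a set of samples
#'
#' Implants deletions and duplications at random map locations.  Per sample
#' the number of CNVs is Poisson(\code{mean_cnvs}); each event spans a
#' number of consecutive markers drawn uniformly from
#' \code{marker_span_range} and gets a copy number drawn from
#' \code{state_probs}.  Events within a sample never overlap.
#'
#' @param map marker map from \code{\link{simulate_marker_map}}.
#' @param sample_ids character vector of sample ids.
#' @param mean_cnvs expected CNVs per sample.
#' @param marker_span_range integer range (min, max) of markers per event.
#' @param state_probs named probabilities over copy numbers "0","1","3","4".
#' @param seed integer seed.
#' @return data.frame of truth CNVs: \code{sample_id}, \code{chrom},
#'   \code{start_pos}, \code{end_pos}, \code{copy_number} (never 2).
#' @export
simulate_truth_cnvs <- function(map, sample_ids, mean_cnvs = 3,
                                marker_span_range = c(5L, 50L),
                                state_probs = c("0" = 0.05, "1" = 0.55, "3" = 0.32, "4" = 0.08),
                                seed = 1L) {
  validate_marker_map(map)
  set.seed(seed)
  out <- list()
  n_map <- nrow(map)
  for (sid in sample_ids) {
    k <- stats::rpois(1, mean_cnvs)
    if (k == 0) next
    taken <- integer(0)
    rows <- list()
    for (j in seq_len(k)) {
      span <- sample(seq.int(marker_span_range[1], marker_span_range[2]), 1)
      for (attempt in 1:20) {
        i0 <- sample.int(n_map - span + 1L, 1)
        idx <- i0:(i0 + span - 1L)
        if (length(unique(map$chrom[idx])) > 1L) next
        if (any(idx %in% taken)) next
        taken <- c(taken, idx)
        cn <- as.integer(sample(names(state_probs), 1, prob = state_probs))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, chrom = map$chrom[i0],
          start_pos = map$pos[idx[1]], end_pos = map$pos[idx[span]],
          copy_number = cn, stringsAsFactors = FALSE
        )
        break
      }
    }
    if (length(rows)) out[[sid]] <- do.call(rbind, rows)
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start_pos = integer(), end_pos = integer(),
                      copy_number = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate LRR/BAF intensity signals with implanted CNVs
#'
#' For each sample, every marker gets copy number 2 except inside that
#' sample's truth CNV spans.  LRR is the state emission mean plus an
#' optional genomic-wave component (\code{gc_wave_coef} times the
#' standardised local GC) plus Gaussian noise of sd \code{lrr_sd}.  BAF is
#' generated by drawing a genotype (number of B alleles) from the marker
#' PFB under Hardy--Weinberg at the local copy number, taking the allelic
#' ratio, and adding Gaussian noise of sd \code{baf_sd} clipped to [0,1]
#' (homozygous clusters therefore pile up at the rails, as on real arrays);
#' at copy number 0 the BAF is uniform noise.
#'
#' One master seed is split hierarchically into per-sample seeds, so adding
#' or reordering samples does not perturb other samples' signals.
#'
#' @param map marker map.
#' @param truth data.frame of truth CNVs (may be empty); every span must
#'   contain at least one marker and lie on a chromosome present in the map.
#' @param sample_ids samples to generate; defaults to those in \code{truth}.
#' @param noise list with \code{lrr_sd}, \code{baf_sd}, \code{gc_wave_coef}.
#' @param lrr_means named emission means per copy number.
#' @param seed master integer seed.
#' @return named list of signals, one per sample: each a list with
#'   \code{sample_id}, \code{lrr}, \code{baf} aligned to \code{map}.
#' @export
simulate_signals <- function(map, truth,
                             sample_ids = unique(truth$sample_id),
                             noise = list(lrr_sd = 0.15, baf_sd = 0.04, gc_wave_coef = 0),
                             lrr_means = default_lrr_means(),
                             seed = 1L) {
  validate_marker_map(map)
  if (noise$lrr_sd < 0 || noise$baf_sd < 0) stop("noise sds must be >= 0")
  if (nrow(truth) > 0) {
    bad <- setdiff(unique(truth$chrom), unique(map$chrom))
    if (length(bad)) stop("truth CNV on chromosome absent from map: ", paste(bad, collapse = ", "))
    if (any(truth$copy_number == 2L)) stop("truth copy_number must not be 2")
  }
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max, length(sample_ids))
  gc_std <- standardize_gc(map$gc)

  out <- vector("list", length(sample_ids))
  names(out) <- sample_ids
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    set.seed(sample_seeds[i])
    cn <- rep.int(2L, nrow(map))
    tr <- truth[truth$sample_id == sid, , drop = FALSE]
    if (nrow(tr)) {
      for (j in seq_len(nrow(tr))) {
        hit <- map$chrom == tr$chrom[j] & map$pos >= tr$start_pos[j] & map$pos <= tr$end_pos[j]
        if (!any(hit)) stop("truth CNV contains no marker: ", sid, " ", tr$chrom[j],
                            ":", tr$start_pos[j], "-", tr$end_pos[j])
        cn[hit] <- tr$copy_number[j]
      }
    }
    lrr <- lrr_means[as.character(cn)] +
      noise$gc_wave_coef * gc_std +
      rnorm(nrow(map), 0, noise$lrr_sd)
    names(lrr) <- NULL
    b_alleles <- rbinom(nrow(map), size = cn, prob = map$pfb)
    baf0 <- ifelse(cn == 0L, runif(nrow(map)), b_alleles / pmax(cn, 1L))
    baf <- pmin(1, pmax(0, baf0 + rnorm(nrow(map), 0, noise$baf_sd)))
    out[[i]] <- list(sample_id = sid, lrr = as.numeric(lrr), baf = as.numeric(baf))
  }
  out
}

#' @keywords internal
standardize_gc <- function(gc) {
  s <- sd(gc)
  if (!is.finite(s) || s == 0) return(rep(0, length(gc)))
  (gc - mean(gc)) / s
}

#' Cohort configuration for the survival generator
#'
#' Defaults emulate a discovery-style cohort of long-lived individuals:
#' 603 samples, 75.1\% women, entry (baseline) age about 96.9 years
#' truncated to [90, 103], Gompertz baseline hazard calibrated so that
#' roughly 85--90\% of subjects die within the administrative follow-up
#' window, and a mean follow-up time of about three years.
#'
#' @param n_samples cohort size.
#' @param sex_fraction_female fraction of women.
#' @param entry_age_distribution c(mean, sd) of entry age in years.
#' @param entry_age_range truncation bounds for entry age.
#' @param gompertz_a,gompertz_b baseline hazard h0(t) = a * exp(b * t) on
#'   the age scale (per-year).
#' @param log_hr_per_covariate named vector of log hazard ratios; names must
#'   match covariate columns passed to \code{\link{simulate_survival}} (the
#'   generated \code{sex_female} column may be named too).
#' @param censor_date_offset administrative censoring at entry + offset years.
#' @param seed integer seed.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_samples = 603L,
                          sex_fraction_female = 0.751,
                          entry_age_distribution = c(96.9, 2.0),
                          entry_age_range = c(90, 103),
                          gompertz_a = 1.7e-5,
                          gompertz_b = 0.10,
                          log_hr_per_covariate = c(),
                          censor_date_offset = 6.0,
                          seed = 1L) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (gompertz_a <= 0) stop("gompertz_a must be positive")
  if (censor_date_offset < 0) stop("censor_date_offset must be non-negative")
  structure(list(
    n_samples = as.integer(n_samples),
    sex_fraction_female = sex_fraction_female,
    entry_age_distribution = entry_age_distribution,
    entry_age_range = entry_age_range,
    gompertz_a = gompertz_a, gompertz_b = gompertz_b,
    log_hr_per_covariate = log_hr_per_covariate,
    censor_date_offset = censor_date_offset,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate left-truncated survival outcomes under a Gompertz PH model
#'
#' Death ages are drawn from the hazard h(t) = a * exp(b * t) * exp(beta'x)
#' conditional on survival to the entry age (left truncation), by inversion
#' of the conditional cumulative hazard.  Follow-up is administratively
#' censored at entry + \code{censor_date_offset} years.  The time scale is
#' age, so downstream Cox fits must use delayed entry.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param covariates optional data.frame with \code{sample_id} plus numeric
#'   covariate columns (e.g. burden summaries); row count must equal
#'   \code{config$n_samples} if given.  Effects are taken from
#'   \code{config$log_hr_per_covariate} by column name; names without a
#'   matching column are an error.
#' @return data.frame of survival records: \code{sample_id}, \code{sex}
#'   ("female"/"male"), \code{entry_age}, \code{exit_age}, \code{event},
#'   \code{birth_cohort} (decade bin), \code{family_id}, plus any covariate
#'   columns passed in.
#' @export
simulate_survival <- function(config, covariates = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  if (is.null(covariates)) {
    covariates <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                             stringsAsFactors = FALSE)
  } else {
    if (nrow(covariates) != n) stop("covariates must have n_samples rows")
    if (anyNA(covariates)) stop("per-sample covariates must be complete")
  }
  sex_female <- as.integer(runif(n) < config$sex_fraction_female)
  mu <- config$entry_age_distribution[1]; s <- config$entry_age_distribution[2]
  entry <- rnorm(n, mu, s)
  entry <- pmin(config$entry_age_range[2], pmax(config$entry_age_range[1], entry))

  beta <- config$log_hr_per_covariate
  lp <- rep(0, n)
  if (length(beta)) {
    for (nm in names(beta)) {
      x <- if (nm == "sex_female") sex_female else covariates[[nm]]
      if (is.null(x)) stop("log_hr_per_covariate names a missing covariate: ", nm)
      lp <- lp + beta[[nm]] * x
    }
  }
  a <- config$gompertz_a; b <- config$gompertz_b
  u <- runif(n)
  # solve (a/b) exp(beta'x) (e^{bT} - e^{b t0}) = -log u  for death age T
  death <- log(exp(b * entry) - b * log(u) / (a * exp(lp))) / b
  cens <- entry + config$censor_date_offset
  exit <- pmin(death, cens)
  event <- as.integer(death <= cens)
  exit <- pmax(exit, entry + 1 / 365.25)  # at least one day of follow-up

  # birth decade assuming a common baseline calendar year
  baseline_year <- 2000
  birth_year <- baseline_year - entry
  birth_cohort <- sprintf("%d0s", floor(birth_year / 10))

  out <- data.frame(
    sample_id = covariates$sample_id,
    sex = ifelse(sex_female == 1L, "female", "male"),
    entry_age = entry, exit_age = exit, event = event,
    birth_cohort = birth_cohort,
    family_id = covariates$sample_id,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(covariates), "sample_id")
  for (nm in extra) out[[nm]] <- covariates[[nm]]
  stopifnot(all(out$entry_age < out$exit_age))
  out
}
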
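# End-to-end orchestration: simulate (or load) -> call -> QC -> regions /
# burden -> association -> flags, plus the two-study joint analysis.

#' Build and validate a pipeline run configuration
#'
#' All thresholds default to the study values: calls need >= 3 SNPs and
#' >= 1 kb; samples fail QC at LRR sd > 0.30, > 100 calls, |GC wave| >
#' 0.05; regions merge at >= 50\% reciprocal overlap of the shorter call
#' and are dropped below 1\% frequency; the burden family uses a
#' Bonferroni correction for 8 tests and region-wise significance uses
#' 0.05 / (number of tested regions); suggestive findings are p <= 0.05.
#'
#' @param study_id label for the study ("discovery", "replication", ...).
#' @param n_samples,n_markers,chrom_lengths synthetic cohort dimensions.
#' @param mean_cnvs expected implanted CNVs per sample.
#' @param noise list(lrr_sd, baf_sd, gc_wave_coef) for the generator.
#' @param log_hr_per_covariate named planted log hazard ratios (names are
#'   burden columns or "sex_female").
#' @param adjustments Cox adjustment covariates.
#' @param cluster_col optional cluster column ("family_id") for robust SEs.
#' @param min_snps,min_length_bp caller-level call filters.
#' @param qc QC thresholds, see \code{\link{qc_thresholds}}.
#' @param merge_min_frac reciprocal-overlap fraction for region merging.
#' @param min_freq region frequency floor.
#' @param burden_m number of tests in the burden Bonferroni family.
#' @param suggestive_alpha nominal level for suggestive findings.
#' @param censor_date_offset,entry_age_distribution,sex_fraction_female,
#'   gompertz_a,gompertz_b passed to \code{\link{cohort_config}}.
#' @param seed master seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(study_id = "discovery",
                       n_samples = 100L, n_markers = 5000L,
                       chrom_lengths = c(chr1 = 12e6, chr2 = 8e6),
                       mean_cnvs = 3,
                       noise = list(lrr_sd = 0.15, baf_sd = 0.04, gc_wave_coef = 0),
                       log_hr_per_covariate = c(),
                       adjustments = c("sex", "birth_cohort"),
                       cluster_col = NULL,
                       min_snps = 3L, min_length_bp = 1000L,
                       qc = qc_thresholds(),
                       merge_min_frac = 0.5, min_freq = 0.01,
                       burden_m = 8L, suggestive_alpha = 0.05,
                       censor_date_offset = 6.0,
                       entry_age_distribution = c(96.9, 2.0),
                       sex_fraction_female = 0.751,
                       gompertz_a = 1.7e-5, gompertz_b = 0.10,
                       seed = 1L) {
  if (min_freq < 0 || min_freq > 1)
    stop("invalid config: min_freq must be in [0, 1]")
  if (merge_min_frac <= 0 || merge_min_frac > 1)
    stop("invalid config: merge_min_frac must be in (0, 1]")
  if (n_samples < 1 || n_markers < 4) stop("invalid config: cohort too small")
  if (suggestive_alpha <= 0 || suggestive_alpha >= 1)
    stop("invalid config: suggestive_alpha must be in (0, 1)")
  cfg <- list(study_id = study_id, n_samples = as.integer(n_samples),
              n_markers = as.integer(n_markers), chrom_lengths = chrom_lengths,
              mean_cnvs = mean_cnvs, noise = noise,
              log_hr_per_covariate = log_hr_per_covariate,
              adjustments = adjustments, cluster_col = cluster_col,
              min_snps = as.integer(min_snps),
              min_length_bp = as.integer(min_length_bp),
              qc = qc, merge_min_frac = merge_min_frac, min_freq = min_freq,
              burden_m = as.integer(burden_m), suggestive_alpha = suggestive_alpha,
              censor_date_offset = censor_date_offset,
              entry_age_distribution = entry_age_distribution,
              sex_fraction_female = sex_fraction_female,
              gompertz_a = gompertz_a, gompertz_b = gompertz_b,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

# small rolling text hash (mod 2^31 - 1) so every output table can carry a
# config id; stability across runs matters, cryptographic strength does not
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the discovery-style pipeline on one cohort
#'
#' Executes signals -> calls -> QC -> regions/burden -> Cox -> flags.  With
#' no external inputs the synthetic generator produces the cohort from the
#' config (map, implanted CNVs, signals, and survival outcomes whose
#' planted effects are taken from \code{log_hr_per_covariate}).  A manifest
#' records row counts at every filtering step so the surviving-record
#' arithmetic is auditable.
#'
#' @param config \code{\link{run_config}}.
#' @param map,signals,phenotype optional externally supplied inputs (all
#'   three or none); \code{signals} is a named list as produced by
#'   \code{\link{simulate_signals}}.
#' @param exclusion optional exclusion intervals (from \code{\link{read_bed}}).
#' @return list of class \code{run_bundle} with the stage tables
#'   (\code{map}, \code{truth}, \code{calls_all}, \code{qc},
#'   \code{calls}, \code{burden}, \code{phenotype}, \code{regions_all},
#'   \code{regions}, \code{cmat}, \code{burden_assoc}, \code{region_assoc},
#'   \code{manifest}, \code{config}, \code{config_hash}).
#' @export
run_discovery <- function(config, map = NULL, signals = NULL,
                          phenotype = NULL, exclusion = NULL) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list()
  note <- function(stage, input, kept) {
    manifest[[stage]] <<- data.frame(stage = stage, input = input, kept = kept,
                                     dropped = input - kept, stringsAsFactors = FALSE)
  }
  simulate <- is.null(signals)
  truth <- NULL
  if (simulate) {
    set.seed(config$seed)
    seeds <- sample.int(.Machine$integer.max, 4)
    map <- simulate_marker_map(config$n_markers, config$chrom_lengths, seed = seeds[1])
    sample_ids <- sprintf("%s_S%04d", config$study_id, seq_len(config$n_samples))
    truth <- simulate_truth_cnvs(map, sample_ids, mean_cnvs = config$mean_cnvs,
                                 seed = seeds[2])
    signals <- simulate_signals(map, truth, sample_ids, noise = config$noise,
                                seed = seeds[3])
  } else {
    if (is.null(map) || is.null(phenotype))
      stop("external signals require an external map and phenotype")
    sample_ids <- names(signals)
  }

  params <- hmm_params()
  calls_list <- lapply(signals, call_cnvs, map = map, params = params,
                       min_snps = config$min_snps, min_length_bp = config$min_length_bp)
  calls_all <- do.call(rbind, c(calls_list, list(empty_calls())))
  rownames(calls_all) <- NULL

  qc_rows <- do.call(rbind, lapply(sample_ids, function(sid) {
    compute_qc_metrics(signals[[sid]], map, calls_list[[sid]])
  }))
  qc_res <- apply_sample_qc(qc_rows, config$qc)
  passing <- qc_res$sample_id[qc_res$pass]
  note("sample_qc", length(sample_ids), length(passing))

  calls <- calls_all[calls_all$sample_id %in% passing, , drop = FALSE]
  note("calls_qc_samples", nrow(calls_all), nrow(calls))

  burden <- compute_burden(calls, passing)

  if (simulate) {
    cc <- cohort_config(n_samples = length(passing),
                        sex_fraction_female = config$sex_fraction_female,
                        entry_age_distribution = config$entry_age_distribution,
                        gompertz_a = config$gompertz_a, gompertz_b = config$gompertz_b,
                        log_hr_per_covariate = config$log_hr_per_covariate,
                        censor_date_offset = config$censor_date_offset,
                        seed = seeds[4])
    phenotype <- simulate_survival(cc, covariates = burden)
  } else {
    missing_ids <- setdiff(passing, phenotype$sample_id)
    if (length(missing_ids))
      stop("phenotype table missing samples: ", paste(missing_ids, collapse = ", "))
    phenotype <- merge(phenotype, burden, by = "sample_id", sort = FALSE)
  }
  phenotype <- phenotype[match(passing, phenotype$sample_id), , drop = FALSE]

  regions_all <- merge_calls(calls, config$merge_min_frac, length(passing))
  regions <- filter_regions(regions_all, exclusion, config$min_freq)
  note("region_filters", nrow(regions_all), nrow(regions))
  cmat <- carrier_matrix(regions, passing)

  burden_terms <- as.vector(outer(c("all", "del", "dup"),
                                  c("n_per10", "avg_per10kb", "total_per100kb"),
                                  paste, sep = "_"))
  burden_assoc <- do.call(rbind, lapply(burden_terms, function(tm) {
    tryCatch(fit_cox(phenotype, tm, config$adjustments, config$cluster_col),
             error = function(e) {
               message("burden term ", tm, " not testable: ", conditionMessage(e))
               NULL
             })
  }))
  burden_th <- bonferroni(0.05, config$burden_m)
  if (!is.null(burden_assoc)) burden_assoc <- flag_results(burden_assoc, burden_th)

  region_assoc <- test_regions(cmat, phenotype, config$adjustments, config$cluster_col)
  if (nrow(region_assoc)) {
    region_th <- bonferroni(0.05, max(1L, nrow(region_assoc)))
    region_assoc <- flag_results(region_assoc, region_th)
  }

  structure(list(
    config = config, config_hash = config_hash(config),
    map = map, truth = truth, calls_all = calls_all, qc = qc_res,
    passing = passing, calls = calls, burden = burden, phenotype = phenotype,
    regions_all = regions_all, regions = regions, cmat = cmat,
    burden_assoc = burden_assoc, region_assoc = region_assoc,
    manifest = do.call(rbind, manifest)
  ), class = "run_bundle")
}

#' Joint (two-study) analysis of a discovery and a replication bundle
#'
#' Suggestive discovery regions (p <= \code{suggestive_alpha}) are matched
#' into the replication study by same-type overlap; matches below the
#' replication frequency floor become NA rows and are excluded from the
#' pooling, as are unmatched regions.  Matched rows are combined by
#' fixed-effect inverse-variance meta-analysis, and the burden terms are
#' pooled across the two studies the same way.
#'
#' @param discovery,replication \code{run_bundle}s.
#' @param min_overlap_bp replication matching threshold in bp.
#' @return list with \code{regions} (a joint table shaped like a published
#'   region table: per-study frequency/HR/CI/P plus joint HR/CI/P and
#'   flags) and \code{burden} (per-term pooled burden estimates).
#' @export
run_joint <- function(discovery, replication, min_overlap_bp = 1L) {
  stopifnot(inherits(discovery, "run_bundle"), inherits(replication, "run_bundle"))
  alpha <- discovery$config$suggestive_alpha
  min_freq <- discovery$config$min_freq

  da <- discovery$region_assoc
  sugg <- da[!is.na(da$p) & da$p <= alpha, , drop = FALSE]
  dreg <- discovery$regions[match(sugg$region_id, discovery$regions$region_id), , drop = FALSE]
  mm <- match_regions(dreg, replication$regions_all, min_overlap_bp)

  rows <- lapply(seq_len(nrow(sugg)), function(i) {
    rid <- sugg$region_id[i]
    out <- data.frame(
      region_id = rid, chrom = dreg$chrom[i],
      start_pos = dreg$start_pos[i], end_pos = dreg$end_pos[i],
      cnv_type = dreg$cnv_type[i],
      size_kb = (dreg$end_pos[i] - dreg$start_pos[i] + 1) / 1000,
      discovery_freq = dreg$frequency[i],
      hr_discovery = sugg$hr[i], ci_low_discovery = sugg$ci_low[i],
      ci_high_discovery = sugg$ci_high[i], p_discovery = sugg$p[i],
      log_hr_discovery = sugg$log_hr[i],
      replication_freq = NA_real_, hr_replication = NA_real_,
      ci_low_replication = NA_real_, ci_high_replication = NA_real_,
      p_replication = NA_real_, log_hr_replication = NA_real_,
      joint_hr = NA_real_, joint_ci_low = NA_real_, joint_ci_high = NA_real_,
      joint_p = NA_real_, stringsAsFactors = FALSE
    )
    rep_id <- mm$replication_id[mm$discovery_id == rid]
    if (is.na(rep_id)) return(out)
    rr <- replication$regions_all[replication$regions_all$region_id == rep_id, ]
    out$replication_freq <- rr$frequency
    if (rr$frequency < min_freq) return(out)  # NA: not testable in replication
    ra <- replication$region_assoc[replication$region_assoc$region_id == rep_id, , drop = FALSE]
    if (nrow(ra) != 1) return(out)
    out$hr_replication <- ra$hr; out$ci_low_replication <- ra$ci_low
    out$ci_high_replication <- ra$ci_high; out$p_replication <- ra$p
    out$log_hr_replication <- ra$log_hr
    m <- fixed_effect_meta(data.frame(
      study_id = c(discovery$config$study_id, replication$config$study_id),
      log_hr = c(sugg$log_hr[i], ra$log_hr),
      se_log_hr = c(sugg$se_log_hr[i], ra$se_log_hr)))
    out$joint_hr <- m$hr; out$joint_ci_low <- m$ci_low
    out$joint_ci_high <- m$ci_high; out$joint_p <- m$p
    out
  })
  regions <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(regions)) {
    regions$p <- regions$p_discovery
    th <- bonferroni(0.05, max(1L, nrow(discovery$region_assoc)))
    regions <- flag_results(regions, th, alpha, min_freq)
    regions$p <- NULL
  }

  burden <- NULL
  if (!is.null(discovery$burden_assoc) && !is.null(replication$burden_assoc)) {
    terms <- intersect(discovery$burden_assoc$term, replication$burden_assoc$term)
    burden <- do.call(rbind, lapply(terms, function(tm) {
      d <- discovery$burden_assoc[discovery$burden_assoc$term == tm, ]
      r <- replication$burden_assoc[replication$burden_assoc$term == tm, ]
      m <- fixed_effect_meta(data.frame(
        study_id = c(discovery$config$study_id, replication$config$study_id),
        log_hr = c(d$log_hr, r$log_hr), se_log_hr = c(d$se_log_hr, r$se_log_hr)))
      data.frame(term = tm, hr = m$hr, ci_low = m$ci_low, ci_high = m$ci_high,
                 p = m$p, stringsAsFactors = FALSE)
    }))
  }
  list(regions = regions, burden = burden)
}

#' Write a run bundle to a directory of TSV files
#'
#' Every table is written as plain TSV with a header comment carrying the
#' config hash; reruns with an identical config and seed produce
#' byte-identical files.
#'
#' @param bundle \code{run_bundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    if (is.null(x)) return()
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(sprintf("# config_hash=%s coordinates=1-based-inclusive",
                       bundle$config_hash), con)
    close(con)
    if (is.matrix(x)) x <- data.frame(sample_id = rownames(x), x,
                                      check.names = FALSE, stringsAsFactors = FALSE)
    for (nm in names(x)) if (is.list(x[[nm]])) x[[nm]] <- vapply(x[[nm]], paste, "", collapse = ",")
    suppressWarnings(write.table(x, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    written <<- c(written, path)
  }
  emit(bundle$map, "map"); emit(bundle$truth, "truth")
  emit(bundle$calls_all, "calls_all"); emit(bundle$qc, "qc")
  emit(bundle$calls, "calls"); emit(bundle$burden, "burden")
  emit(bundle$phenotype, "phenotype"); emit(bundle$regions, "regions")
  emit(bundle$cmat, "carrier_matrix"); emit(bundle$burden_assoc, "burden_assoc")
  emit(bundle$region_assoc, "region_assoc"); emit(bundle$manifest, "manifest")
  invisible(written)
}
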
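# Inverse-variance fixed-effect meta-analysis of per-study hazard ratios.

#' Reconstruct the standard error of a log hazard ratio from its CI
#'
#' Wald identity: se = (log ci_high - log ci_low) / (2 * z), with z the
#' normal quantile for the interval level (1.959964 at 95\%).  This is how
#' published per-study tables (HR with 95\% CI) are converted back to the
#' precision needed for pooling.
#'
#' @param hr point estimate (must lie inside the interval).
#' @param ci_low,ci_high interval bounds, both positive.
#' @param level confidence level (default 0.95).
#' @return standard error of the log hazard ratio.
#' @export
se_from_ci <- function(hr, ci_low, ci_high, level = 0.95) {
  if (any(c(hr, ci_low, ci_high) <= 0)) stop("hazard ratios and bounds must be positive")
  if (ci_low > hr || hr > ci_high) stop("hr must lie within [ci_low, ci_high]")
  z <- if (identical(level, 0.95)) Z95 else qnorm(1 - (1 - level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  if (se <= 0) stop("degenerate (zero-width) confidence interval")
  se
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-study log hazard ratios with weights 1/se^2:
#' pooled log HR = sum(w * log_hr) / sum(w), se = 1/sqrt(sum(w)).
#' The p-value is a two-sided normal (Wald) test of log HR = 0.
#'
#' @param estimates data.frame with columns \code{study_id}, \code{log_hr},
#'   \code{se_log_hr} (one row per study; at least one row).
#' @param conf_z Wald multiplier for the pooled CI.
#' @return list of class \code{meta_result}: \code{log_hr_pooled},
#'   \code{se_pooled}, \code{hr}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{study_weights} (named, sum to 1), \code{k} studies.
#' @export
fixed_effect_meta <- function(estimates, conf_z = Z95) {
  if (nrow(estimates) < 1) stop("at least one study estimate required")
  if (any(estimates$se_log_hr <= 0)) stop("se_log_hr must be > 0")
  w <- 1 / estimates$se_log_hr^2
  beta <- sum(w * estimates$log_hr) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  structure(list(
    log_hr_pooled = beta, se_pooled = se, hr = exp(beta),
    ci_low = exp(beta - conf_z * se), ci_high = exp(beta + conf_z * se),
    p = 2 * pnorm(-abs(z)),
    study_weights = setNames(w / sum(w), estimates$study_id),
    k = nrow(estimates)
  ), class = "meta_result")
}

#' Heterogeneity statistics (optional)
#'
#' Cochran's Q and I-squared for a set of study estimates; not computed by
#' default anywhere in the pipeline.
#'
#' @inheritParams fixed_effect_meta
#' @return list with \code{Q}, \code{df}, \code{p_Q}, \code{I2}.
#' @export
heterogeneity <- function(estimates) {
  m <- fixed_effect_meta(estimates)
  w <- 1 / estimates$se_log_hr^2
  Q <- sum(w * (estimates$log_hr - m$log_hr_pooled)^2)
  df <- nrow(estimates) - 1L
  list(Q = Q, df = df,
       p_Q = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
       I2 = if (df > 0) max(0, (Q - df) / Q) else NA_real_)
}

#' Pool published per-study HR/CI rows into joint estimates
#'
#' Published-table mode: takes per-study rows (hazard ratio with 95\% CI),
#' reconstructs standard errors with \code{\link{se_from_ci}}, and pools
#' each term by fixed-effect inverse variance.  Rows with missing HR or CI
#' (e.g. not testable in the replication study) are dropped from the pool;
#' a term left with no usable row is reported as NA.
#'
#' @param tab data.frame with columns \code{term}, \code{study_id},
#'   \code{hr}, \code{ci_low}, \code{ci_high}.
#' @return data.frame with one row per term: \code{term}, \code{k},
#'   \code{hr}, \code{ci_low}, \code{ci_high}, \code{p}.
#' @export
pool_published_estimates <- function(tab) {
  stopifnot(all(c("term", "study_id", "hr", "ci_low", "ci_high") %in% names(tab)))
  terms <- unique(tab$term)
  out <- lapply(terms, function(tm) {
    rows <- tab[tab$term == tm & complete.cases(tab[, c("hr", "ci_low", "ci_high")]), ,
                drop = FALSE]
    if (nrow(rows) == 0) {
      return(data.frame(term = tm, k = 0L, hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    est <- data.frame(
      study_id = rows$study_id,
      log_hr = log(rows$hr),
      se_log_hr = mapply(se_from_ci, rows$hr, rows$ci_low, rows$ci_high)
    )
    m <- fixed_effect_meta(est)
    data.frame(term = tm, k = m$k, hr = m$hr, ci_low = m$ci_low,
               ci_high = m$ci_high, p = m$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Load the bundled published per-study estimate tables
#'
#' Two plain-text tables of per-study hazard ratios with 95\% CIs shipped
#' with the package: \code{"burden"} (three burden measures x three CNV
#' classes, discovery + replication studies, with the printed joint
#' column for comparison) and \code{"regions"} (the twenty nominally
#' significant regions of the discovery study with replication rows where
#' the region frequency allowed testing).
#'
#' @param table \code{"burden"} or \code{"regions"}.
#' @return data.frame.
#' @export
published_estimates <- function(table = c("burden", "regions")) {
  table <- match.arg(table)
  path <- system.file("extdata",
                      sprintf("published_%s_estimates.tsv", table),
                      package = "cnvmort", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
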
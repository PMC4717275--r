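# Bonferroni thresholds and result flagging.

#' Bonferroni-corrected significance threshold
#'
#' alpha / m, optionally rounded to a number of significant digits for
#' display.  Decision rules elsewhere always use the unrounded value;
#' rounding is reporting only.
#'
#' @param alpha base level in (0, 1).
#' @param m number of tests (>= 1).
#' @param sig_digits optional significant digits for the returned value.
#' @return the threshold.
#' @export
bonferroni <- function(alpha, m, sig_digits = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  th <- alpha / m
  if (!is.null(sig_digits)) th <- signif(th, sig_digits)
  th
}

#' Flag association results against the study's significance policies
#'
#' Adds logical flags to a results table: \code{significant} (p at or below
#' the family-wise Bonferroni threshold), \code{suggestive} (p <= 0.05,
#' closed inequality), \code{replicated_consistent} (joint p <= 0.05 and
#' the per-study log hazard ratios share a sign), and \code{not_testable}
#' (replication frequency below the frequency floor, so no replication or
#' joint analysis is possible).
#'
#' @param results data.frame with column \code{p} (discovery p-value).
#'   For replication flags it must also carry \code{joint_p},
#'   \code{log_hr_discovery}, \code{log_hr_replication}, and optionally
#'   \code{replication_freq}.
#' @param family_threshold unrounded Bonferroni threshold for the family.
#' @param suggestive_alpha nominal level for suggestive findings (0.05).
#' @param min_freq replication-frequency floor below which a region is not
#'   testable (0.01).
#' @return the input with flag columns appended.
#' @export
flag_results <- function(results, family_threshold,
                         suggestive_alpha = 0.05, min_freq = 0.01) {
  stopifnot("p" %in% names(results))
  results$significant <- !is.na(results$p) & results$p <= family_threshold
  results$suggestive <- !is.na(results$p) & results$p <= suggestive_alpha
  if ("replication_freq" %in% names(results)) {
    results$not_testable <- is.na(results$replication_freq) |
      results$replication_freq < min_freq
  }
  if (all(c("joint_p", "log_hr_discovery", "log_hr_replication") %in% names(results))) {
    results$replicated_consistent <-
      !is.na(results$joint_p) & results$joint_p <= suggestive_alpha &
      !is.na(results$log_hr_discovery) & !is.na(results$log_hr_replication) &
      sign(results$log_hr_discovery) == sign(results$log_hr_replication)
  } else if (any(c("joint_p") %in% names(results))) {
    stop("replication flagging needs per-study effect directions ",
         "(log_hr_discovery, log_hr_replication)")
  }
  results
}
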
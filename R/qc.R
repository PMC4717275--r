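# Per-sample signal quality control: LRR noise, call count, genomic wave.

#' Default sample QC thresholds
#'
#' Exclusion cutoffs: LRR standard deviation above 0.30, more than 100
#' CNVs called, or an absolute GC wave factor above 0.05.  All strict
#' inequalities -- boundary values pass.
#'
#' @param lrr_sd,max_cnvs,gcwf override individual cutoffs.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(lrr_sd = 0.30, max_cnvs = 100L, gcwf = 0.05) {
  list(lrr_sd = lrr_sd, max_cnvs = max_cnvs, gcwf = gcwf)
}

#' Compute per-sample QC metrics
#'
#' \code{lrr_sd} is the standard deviation of the sample's autosomal LRR.
#' The GC wave factor is operationalised as the least-squares slope of LRR
#' on the standardised local GC track ((gc - mean) / sd), a signed measure
#' of genomic-wave contamination.  A constant GC track leaves the slope
#' undefined; the metric is then NA and the sample fails closed.
#'
#' @param signal list with \code{sample_id}, \code{lrr}, \code{baf}.
#' @param map marker map aligned to the signal.
#' @param calls data.frame of this sample's filtered calls.
#' @return one-row data.frame: \code{sample_id}, \code{lrr_sd},
#'   \code{n_cnvs_called}, \code{gc_wave_factor}.
#' @export
compute_qc_metrics <- function(signal, map, calls) {
  if (length(signal$lrr) != nrow(map)) stop("signal not aligned to map")
  lrr <- signal$lrr
  gsd <- sd(map$gc)
  gcwf <- if (!is.finite(gsd) || gsd == 0) {
    NA_real_
  } else {
    z <- (map$gc - mean(map$gc)) / gsd
    sum((z - mean(z)) * (lrr - mean(lrr))) / sum((z - mean(z))^2)
  }
  data.frame(sample_id = signal$sample_id,
             lrr_sd = sd(lrr),
             n_cnvs_called = nrow(calls),
             gc_wave_factor = gcwf,
             stringsAsFactors = FALSE)
}

#' Apply sample-level QC thresholds
#'
#' Fails iff lrr_sd > 0.30 OR n_cnvs_called > 100 OR |gc_wave_factor| >
#' 0.05 (defaults; all strict).  Every triggered reason is reported, in a
#' fixed order.  Missing metrics fail closed with reason "incomplete".
#'
#' @param metrics one-row data.frame from \code{\link{compute_qc_metrics}}
#'   (or many rows; the decision is applied row-wise).
#' @param thresholds see \code{\link{qc_thresholds}}.
#' @return the input with logical column \code{pass} and character column
#'   \code{reasons} (";"-separated, "" when passing) appended.
#' @export
apply_sample_qc <- function(metrics, thresholds = qc_thresholds()) {
  needed <- c("lrr_sd", "n_cnvs_called", "gc_wave_factor")
  stopifnot(all(needed %in% names(metrics)))
  pass <- logical(nrow(metrics))
  reasons <- character(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    m <- metrics[i, ]
    if (anyNA(m[needed])) {
      pass[i] <- FALSE; reasons[i] <- "incomplete"
      next
    }
    r <- character(0)
    if (m$lrr_sd > thresholds$lrr_sd) r <- c(r, sprintf("lrr_sd>%.2f", thresholds$lrr_sd))
    if (m$n_cnvs_called > thresholds$max_cnvs) r <- c(r, sprintf("n_cnvs>%d", thresholds$max_cnvs))
    if (abs(m$gc_wave_factor) > thresholds$gcwf) r <- c(r, sprintf("|gcwf|>%.2f", thresholds$gcwf))
    pass[i] <- length(r) == 0L
    reasons[i] <- paste(r, collapse = ";")
  }
  metrics$pass <- pass
  metrics$reasons <- reasons
  metrics
}
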
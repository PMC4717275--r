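# Per-individual CNV burden: count, average length, total length, by class.

#' Compute per-individual CNV burden profiles
#'
#' For each sample and each class (all CNVs, deletions, duplications):
#' the number of calls, the average call length in kb, and the total call
#' length in kb.  Burden is computed from filtered per-sample calls, not
#' from merged regions.  Samples with zero calls of a class get zeros for
#' all three summaries (they stay in the models); set
#' \code{drop_zero_burden = TRUE} to return NA for the average instead.
#'
#' Pre-scaled covariate columns are emitted so that fitted hazard ratios
#' are per additional 10 CNVs (\code{*_n_per10}), per additional 10 kb of
#' average length (\code{*_avg_per10kb}), and per additional 100 kb of
#' total length (\code{*_total_per100kb}).
#'
#' @param calls data.frame of calls across samples.
#' @param samples character vector of QC-passing sample ids; every call's
#'   sample must be listed.
#' @param drop_zero_burden if TRUE, zero-call averages are NA.
#' @return data.frame with one row per sample: for each class prefix in
#'   \code{all_}, \code{del_}, \code{dup_}: \code{n_cnvs},
#'   \code{avg_len_kb}, \code{total_len_kb} and the scaled columns.
#' @export
compute_burden <- function(calls, samples, drop_zero_burden = FALSE) {
  extra <- setdiff(unique(calls$sample_id), samples)
  if (length(extra))
    stop("calls from samples not in the passing list: ", paste(extra, collapse = ", "))
  res <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  classes <- list(all = c("deletion", "duplication"),
                  del = "deletion", dup = "duplication")
  for (cl in names(classes)) {
    sub <- calls[calls$cnv_type %in% classes[[cl]], , drop = FALSE]
    n <- integer(length(samples)); tot <- numeric(length(samples))
    if (nrow(sub)) {
      tb <- tapply(sub$length_bp, factor(sub$sample_id, levels = samples),
                   function(x) c(length(x), sum(x)))
      for (i in seq_along(samples)) {
        v <- tb[[i]]
        if (!is.null(v)) { n[i] <- v[1]; tot[i] <- v[2] }
      }
    }
    avg <- ifelse(n > 0, tot / n / 1000,
                  if (drop_zero_burden) NA_real_ else 0)
    res[[paste0(cl, "_n_cnvs")]] <- n
    res[[paste0(cl, "_avg_len_kb")]] <- avg
    res[[paste0(cl, "_total_len_kb")]] <- tot / 1000
    res[[paste0(cl, "_n_per10")]] <- n / 10
    res[[paste0(cl, "_avg_per10kb")]] <- avg / 10
    res[[paste0(cl, "_total_per100kb")]] <- tot / 1000 / 100
  }
  res
}
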
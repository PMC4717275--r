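# Left-truncated Cox proportional-hazards association on the age timescale.

#' Fit a delayed-entry Cox model for one exposure
#'
#' Maximises the left-truncated Cox partial likelihood on the age timescale
#' (subjects enter the risk set at their entry age), with Efron tie
#' handling, via \code{survival::coxph}.  When \code{cluster_col} is given,
#' the reported standard error is the cluster-robust (sandwich) estimate,
#' the usual adjustment for familial relations.  Adjustment covariates that
#' are constant in the data are dropped with a message rather than
#' producing an unstable fit; a constant exposure is a hard error.
#'
#' @param data data.frame with \code{entry_age}, \code{exit_age},
#'   \code{event} and all covariate columns.
#' @param exposure name of the exposure column (numeric or 0/1).
#' @param adjustments character vector of adjustment covariate names
#'   (factors allowed, e.g. sex or birth cohort).
#' @param cluster_col optional name of a cluster id column (families).
#' @param conf_z Wald multiplier for the confidence interval (default
#'   1.959964 for 95\%).
#' @return one-row data.frame: \code{term}, \code{log_hr}, \code{se_log_hr},
#'   \code{hr}, \code{ci_low}, \code{ci_high}, \code{p}, \code{n},
#'   \code{n_events}.
#' @export
fit_cox <- function(data, exposure, adjustments = character(),
                    cluster_col = NULL, conf_z = Z95) {
  stopifnot(all(c("entry_age", "exit_age", "event") %in% names(data)))
  if (!exposure %in% names(data)) stop("exposure column not found: ", exposure)
  if (sum(data$event) < 1) stop("no events in the data")
  x <- data[[exposure]]
  if (length(unique(x[!is.na(x)])) < 2L)
    stop("degenerate covariate: exposure '", exposure, "' is constant")
  keep <- character(0)
  for (a in adjustments) {
    if (!a %in% names(data)) stop("adjustment column not found: ", a)
    if (length(unique(data[[a]])) < 2L) {
      message("dropping constant adjustment covariate: ", a)
    } else keep <- c(keep, a)
  }
  rhs <- paste(c(sprintf("`%s`", exposure), sprintf("`%s`", keep)), collapse = " + ")
  if (!is.null(cluster_col)) rhs <- paste0(rhs, " + cluster(`", cluster_col, "`)")
  f <- stats::as.formula(paste("survival::Surv(entry_age, exit_age, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("beta may be infinite|Ran out of iterations", msg))
        stop("non-convergent fit for '", exposure, "': ", trimws(msg), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  co <- fit$coefficients
  term_idx <- which(names(co) == sprintf("`%s`", exposure) | names(co) == exposure)
  if (length(term_idx) != 1L) term_idx <- 1L
  beta <- unname(co[term_idx])
  if (!is.finite(beta)) stop("non-convergent or inestimable exposure effect")
  # with cluster(), coxph stores the robust (sandwich) variance in $var and
  # the model-based one in $naive.var
  se <- sqrt(fit$var[term_idx, term_idx])
  z <- beta / se
  data.frame(term = exposure, log_hr = beta, se_log_hr = se,
             hr = exp(beta), ci_low = exp(beta - conf_z * se),
             ci_high = exp(beta + conf_z * se),
             p = 2 * pnorm(-abs(z)),
             n = fit$n, n_events = fit$nevent,
             stringsAsFactors = FALSE)
}

#' Test every CNV region for association with mortality
#'
#' One carrier-vs-noncarrier delayed-entry Cox fit per region, with the
#' same adjustment set throughout.  Regions with zero carriers (or all
#' carriers) among the analyzable samples are skipped with a message.
#' Optionally restrict to one sex first (the sex adjustment is then
#' dropped automatically because the column becomes constant).
#'
#' @param cmat carrier matrix from \code{\link{carrier_matrix}} (rownames
#'   are sample ids).
#' @param data survival data.frame with \code{sample_id} and the model
#'   columns; must cover every row of \code{cmat}.
#' @param adjustments adjustment covariate names.
#' @param cluster_col optional cluster id column.
#' @param sex_subset optional value of \code{data$sex} to restrict to.
#' @return data.frame of per-region results sorted by p, with a
#'   \code{region_id} column.
#' @export
test_regions <- function(cmat, data, adjustments = character(),
                         cluster_col = NULL, sex_subset = NULL) {
  missing_ids <- setdiff(rownames(cmat), data$sample_id)
  if (length(missing_ids))
    stop("samples absent from phenotype table: ", paste(missing_ids, collapse = ", "))
  data <- data[match(rownames(cmat), data$sample_id), , drop = FALSE]
  if (!is.null(sex_subset)) {
    keep <- data$sex == sex_subset
    data <- data[keep, , drop = FALSE]
    cmat <- cmat[keep, , drop = FALSE]
  }
  out <- list()
  for (j in seq_len(ncol(cmat))) {
    data$carrier <- cmat[, j]
    res <- tryCatch(
      fit_cox(data, "carrier", adjustments, cluster_col),
      error = function(e) {
        message("skipping region ", colnames(cmat)[j], ": ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    res$term <- NULL
    res <- cbind(data.frame(region_id = colnames(cmat)[j], stringsAsFactors = FALSE), res)
    out[[length(out) + 1L]] <- res
  }
  if (!length(out)) {
    return(data.frame(region_id = character(), log_hr = numeric(),
                      se_log_hr = numeric(), hr = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p = numeric(), n = integer(),
                      n_events = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
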
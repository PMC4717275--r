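# Cross-sample CNV region (CNVR) construction: reciprocal-overlap merging
# with transitive closure, exclusion filtering, carrier matrix.

#' Overlap as a fraction of the shorter interval
#'
#' Overlap length (1-based inclusive coordinates) divided by the length of
#' the shorter of the two intervals; 0 when disjoint or on different
#' chromosomes (by contract).
#'
#' @param a,b intervals as list/data.frame rows with \code{chrom},
#'   \code{start_pos}, \code{end_pos}.
#' @return fraction in [0, 1].
#' @export
overlap_fraction_shorter <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- min(a$end_pos, b$end_pos) - max(a$start_pos, b$start_pos) + 1L
  if (ov <= 0) return(0)
  ov / min(a$end_pos - a$start_pos + 1L, b$end_pos - b$start_pos + 1L)
}

# vectorised pairwise version on parallel vectors (same chromosome assumed)
.overlap_frac_vec <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1L
  len <- pmin(e1 - s1 + 1L, e2 - s2 + 1L)
  ifelse(ov <= 0, 0, ov / len)
}

#' Merge per-sample CNV calls into cross-sample regions
#'
#' Within each (chromosome, type) stratum -- deletions (states 0/1) and
#' duplications (states 3/4) are always kept separate -- calls are joined
#' whenever they overlap by at least \code{min_frac} of the shorter call,
#' and regions are the connected components of that graph (transitive
#' closure, so the result is independent of input order).  Each region
#' spans the outermost boundaries of its component; its carriers are the
#' distinct samples contributing calls (a sample with both a state-0 and a
#' state-1 call in one deletion region counts once).
#'
#' @param calls data.frame of calls (see \code{\link{extract_calls}}).
#' @param min_frac reciprocal-overlap threshold in (0, 1]; closed
#'   inequality ("at least").
#' @param n_passing_samples frequency denominator: number of QC-passing
#'   samples in the study.
#' @return data.frame of regions: \code{region_id}, \code{chrom},
#'   \code{start_pos}, \code{end_pos}, \code{cnv_type}, \code{n_carriers},
#'   \code{frequency}, \code{carriers} (list column of sample ids).
#' @export
merge_calls <- function(calls, min_frac = 0.5, n_passing_samples) {
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  if (missing(n_passing_samples) || n_passing_samples < 1)
    stop("n_passing_samples must be a positive count")
  if (nrow(calls) == 0) return(empty_regions())
  out <- list()
  for (type in c("deletion", "duplication")) {
    for (ch in unique(calls$chrom[calls$cnv_type == type])) {
      cc <- calls[calls$cnv_type == type & calls$chrom == ch, , drop = FALSE]
      comp <- connected_components(cc$start_pos, cc$end_pos, min_frac)
      for (g in unique(comp)) {
        rows <- cc[comp == g, , drop = FALSE]
        carriers <- sort(unique(rows$sample_id))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start_pos = min(rows$start_pos), end_pos = max(rows$end_pos),
          cnv_type = type, n_carriers = length(carriers),
          frequency = length(carriers) / n_passing_samples,
          stringsAsFactors = FALSE
        )
        out[[length(out)]]$carriers <- list(carriers)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_pos, res$cnv_type), , drop = FALSE]
  res$region_id <- sprintf("%s_%s:%d-%d",
                           ifelse(res$cnv_type == "deletion", "DEL", "DUP"),
                           res$chrom, res$start_pos, res$end_pos)
  rownames(res) <- NULL
  res[, c("region_id", "chrom", "start_pos", "end_pos", "cnv_type",
          "n_carriers", "frequency", "carriers")]
}

# union-find connected components of the >= min_frac overlap graph;
# intervals are sorted by start so only nearby pairs need testing.
connected_components <- function(start, end, min_frac) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(start, end)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (start[j] > end[i]) break  # sorted starts: no later interval overlaps i
      if (.overlap_frac_vec(start[i], end[i], start[j], end[j]) >= min_frac) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' @keywords internal
empty_regions <- function() {
  d <- data.frame(region_id = character(), chrom = character(),
                  start_pos = integer(), end_pos = integer(),
                  cnv_type = character(), n_carriers = integer(),
                  frequency = numeric(), stringsAsFactors = FALSE)
  d$carriers <- list()
  d
}

#' Read a BED file of exclusion intervals
#'
#' Standard BED semantics (0-based, half-open) converted to the package's
#' internal 1-based inclusive coordinates on read.  A malformed line is a
#' hard error reporting its line number.
#'
#' @param path BED file (first three columns chrom, start, end; extra
#'   columns ignored; track/browser/comment lines skipped).
#' @return data.frame \code{chrom}, \code{start_pos}, \code{end_pos}
#'   (1-based inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\t|\\s+")[[1]]
    if (length(f) < 3) stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop("malformed BED line ", i, ": bad coordinates")
    out[[length(out) + 1L]] <- data.frame(chrom = f[1],
                                          start_pos = as.integer(s) + 1L,
                                          end_pos = as.integer(e),
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chrom = character(), start_pos = integer(),
                                      end_pos = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Filter regions by exclusion intervals and population frequency
#'
#' Drops any region overlapping an exclusion interval (centromere/telomere
#' track) by at least one bp, then drops regions with frequency below
#' \code{min_freq}.  Abutting-but-not-overlapping regions are kept.
#'
#' @param regions data.frame from \code{\link{merge_calls}}.
#' @param exclusion data.frame of 1-based inclusive intervals (e.g. from
#'   \code{\link{read_bed}}), or NULL for none.
#' @param min_freq frequency floor; regions with frequency < min_freq are
#'   dropped (default 0.01).
#' @return the surviving regions, unchanged.
#' @export
filter_regions <- function(regions, exclusion = NULL, min_freq = 0.01) {
  if (min_freq < 0 || min_freq > 1) stop("min_freq must be in [0, 1]")
  keep <- rep(TRUE, nrow(regions))
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    for (i in seq_len(nrow(regions))) {
      ex <- exclusion[exclusion$chrom == regions$chrom[i], , drop = FALSE]
      if (nrow(ex) == 0) next
      ov <- pmin(regions$end_pos[i], ex$end_pos) - pmax(regions$start_pos[i], ex$start_pos) + 1L
      if (any(ov >= 1L)) keep[i] <- FALSE
    }
  }
  keep <- keep & regions$frequency >= min_freq
  regions[keep, , drop = FALSE]
}

#' Binary carrier matrix (samples x regions)
#'
#' @param regions filtered regions with a \code{carriers} list column.
#' @param samples character vector of analyzable sample ids (QC-passing,
#'   present in the phenotype table).
#' @return integer matrix with rownames \code{samples} and colnames
#'   \code{region_id}; entry 1 iff the sample carries the region.
#' @export
carrier_matrix <- function(regions, samples) {
  m <- matrix(0L, nrow = length(samples), ncol = nrow(regions),
              dimnames = list(samples, regions$region_id))
  for (j in seq_len(nrow(regions))) {
    carr <- regions$carriers[[j]]
    unknown <- setdiff(carr, samples)
    if (length(unknown))
      stop("carriers absent from sample list: ", paste(unknown, collapse = ", "))
    m[carr, j] <- 1L
  }
  m
}

#' Match replication-study regions to discovery regions
#'
#' A replication region is "the same" CNV as a discovery region if it has
#' the same type and overlaps it by at least \code{min_overlap_bp}.
#' When several replication regions qualify, the one with the largest
#' overlap wins.
#'
#' @param discovery,replication region data.frames.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return data.frame with one row per discovery region:
#'   \code{discovery_id}, \code{replication_id} (NA when unmatched).
#' @export
match_regions <- function(discovery, replication, min_overlap_bp = 1L) {
  res <- data.frame(discovery_id = discovery$region_id,
                    replication_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(discovery))) {
    cand <- replication[replication$cnv_type == discovery$cnv_type[i] &
                          replication$chrom == discovery$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    ov <- pmin(discovery$end_pos[i], cand$end_pos) -
      pmax(discovery$start_pos[i], cand$start_pos) + 1L
    cand <- cand[ov >= min_overlap_bp, , drop = FALSE]
    ov <- ov[ov >= min_overlap_bp]
    if (nrow(cand)) res$replication_id[i] <- cand$region_id[which.max(ov)]
  }
  res
}
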
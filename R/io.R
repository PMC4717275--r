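# Plain-text readers/writers: TSV tables, PennCNV-style rawcnv lines, PFB.
# All coordinate-bearing writers use 1-based inclusive positions; BED input
# is converted on read (see read_bed).

#' Write/read a marker map as TSV
#'
#' Columns: marker_id, chrom, pos, pfb, gc.
#' @param map marker map data.frame.
#' @param path file path.
#' @export
write_marker_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  validate_marker_map(read.delim(path, stringsAsFactors = FALSE))
}

#' Write/read one sample's signal as TSV
#'
#' Columns: marker_id, lrr, baf, in map order.
#' @param signal list with sample_id, lrr, baf.
#' @param map marker map the signal is aligned to.
#' @param path file path.
#' @export
write_signal <- function(signal, map, path) {
  write.table(data.frame(marker_id = map$marker_id, lrr = signal$lrr, baf = signal$baf),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_signal
#' @param sample_id id to attach on read.
#' @export
read_signal <- function(path, map, sample_id) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(d$marker_id, map$marker_id))
    stop("signal file markers do not match the map: ", path)
  list(sample_id = sample_id, lrr = d$lrr, baf = d$baf)
}

#' Write/read a PFB table (PennCNV .pfb dialect)
#'
#' TSV with columns marker_id, chrom, pos, pfb.
#' @param pfb data.frame.
#' @param path file path.
#' @export
write_pfb <- function(pfb, path) {
  write.table(pfb[, c("marker_id", "chrom", "pos", "pfb")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_pfb
#' @export
read_pfb <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "chrom", "pos", "pfb") %in% names(d)))
  d
}

#' Write CNV calls as rawcnv-style text lines
#'
#' One line per call:
#' \code{chr:start-end numsnp=N length=L stateS,cn=C SAMPLE}
#' with 1-based inclusive coordinates and length = end - start + 1.  In
#' this package's 5-state dialect the state index equals the copy number.
#'
#' @param calls calls data.frame.
#' @param path file path.
#' @export
write_rawcnv <- function(calls, path) {
  lines <- sprintf("%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s",
                   calls$chrom, calls$start_pos, calls$end_pos, calls$n_snps,
                   calls$length_bp, calls$state, calls$state, calls$sample_id)
  writeLines(lines, path)
}

#' Read rawcnv-style call lines
#'
#' Accepts both this package's dialect and classic 6-state lines; the
#' \code{cn=} field is authoritative for the copy number.
#'
#' @param path file path.
#' @return calls data.frame (see \code{\link{extract_calls}}).
#' @export
read_rawcnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_calls())
  out <- lapply(seq_along(lines), function(i) {
    m <- regmatches(lines[i],
                    regexec("^(\\S+):(\\d+)-(\\d+)\\s+numsnp=(\\d+)\\s+length=([0-9,]+)\\s+state\\d+,cn=(\\d+)\\s+(\\S+)",
                            lines[i]))[[1]]
    if (length(m) != 8) stop("malformed rawcnv line ", i)
    cn <- as.integer(m[7])
    data.frame(sample_id = m[8], chrom = m[2],
               start_pos = as.integer(m[3]), end_pos = as.integer(m[4]),
               state = cn,
               cnv_type = if (cn < 2) "deletion" else "duplication",
               n_snps = as.integer(m[5]),
               length_bp = as.integer(gsub(",", "", m[6])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a generic TSV table
#'
#' @param x data.frame (list columns are collapsed with ",").
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  for (nm in names(x)) {
    if (is.list(x[[nm]])) x[[nm]] <- vapply(x[[nm]], paste, "", collapse = ",")
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype TSV
#'
#' Required columns: sample_id, sex, entry_age, exit_age, event; optional:
#' birth_cohort, family_id, any covariates.
#' @param path file path.
#' @export
read_phenotype <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "entry_age", "exit_age", "event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("phenotype file missing columns: ", paste(miss, collapse = ", "))
  d
}
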
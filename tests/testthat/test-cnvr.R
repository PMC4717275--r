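# region construction: overlap fraction, merging, filtering, carrier matrix

iv <- function(chrom, s, e) list(chrom = chrom, start_pos = s, end_pos = e)

test_that("overlap_fraction_shorter is exact on hand-countable cases", {
  expect_equal(overlap_fraction_shorter(iv("chr1", 100, 199), iv("chr1", 150, 249)), 0.5)
  expect_equal(overlap_fraction_shorter(iv("chr1", 100, 199), iv("chr1", 100, 199)), 1)
  expect_equal(overlap_fraction_shorter(iv("chr1", 1, 10), iv("chr1", 20, 30)), 0)
  expect_equal(overlap_fraction_shorter(iv("chr1", 1, 10), iv("chr2", 1, 10)), 0)
})

test_that("toy three-call merge gives the hand-derived components", {
  calls <- data.frame(
    sample_id = c("A", "B", "C"), chrom = "chr1",
    start_pos = c(100L, 150L, 240L), end_pos = c(199L, 249L, 339L),
    state = 1L, cnv_type = "deletion", n_snps = 5L,
    length_bp = 100L, stringsAsFactors = FALSE)
  reg <- merge_calls(calls, 0.5, n_passing_samples = 3)
  expect_equal(nrow(reg), 2)
  first <- reg[reg$start_pos == 100, ]
  expect_equal(first$end_pos, 249)
  expect_equal(first$n_carriers, 2L)
  expect_equal(first$frequency, 2 / 3)
  expect_setequal(first$carriers[[1]], c("A", "B"))
})

test_that("singletons, duplicate states, and type separation behave", {
  one <- data.frame(sample_id = "A", chrom = "chr3", start_pos = 10L,
                    end_pos = 2000L, state = 4L, cnv_type = "duplication",
                    n_snps = 4L, length_bp = 1991L, stringsAsFactors = FALSE)
  reg <- merge_calls(one, 0.5, 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start_pos, one$start_pos)
  expect_equal(reg$end_pos, one$end_pos)

  # same coordinates, one deletion + one duplication: two distinct regions
  both <- rbind(one, transform(one, sample_id = "B", state = 1L, cnv_type = "deletion"))
  reg2 <- merge_calls(both, 0.5, 10)
  expect_equal(nrow(reg2), 2)
  expect_setequal(reg2$cnv_type, c("deletion", "duplication"))

  # sample with state 0 and state 1 calls in one deletion region counts once
  mixed <- data.frame(sample_id = "A", chrom = "chr1",
                      start_pos = c(100L, 120L), end_pos = c(300L, 320L),
                      state = c(0L, 1L), cnv_type = "deletion",
                      n_snps = 5L, length_bp = 201L, stringsAsFactors = FALSE)
  reg3 <- merge_calls(mixed, 0.5, 10)
  expect_equal(nrow(reg3), 1)
  expect_equal(reg3$n_carriers, 1L)

  expect_error(merge_calls(one, 0, 10), "min_frac")
  expect_error(merge_calls(one, 0.5), "n_passing_samples")
})

test_that("merging matches the brute-force transitive-closure oracle", {
  set.seed(44)
  for (r in 1:120) {
    calls <- random_calls(sample.int(20, 1))
    got <- merge_calls(calls, 0.5, 8)
    want <- oracle_merge(calls, 0.5, 8)
    got <- got[order(got$chrom, got$start_pos, got$cnv_type, got$end_pos), ]
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
    # order invariance
    perm <- calls[sample.int(nrow(calls)), ]
    got_p <- merge_calls(perm, 0.5, 8)
    expect_identical(got_p$region_id, got$region_id)
    # idempotence: re-merging regions as calls changes nothing
    as_calls <- do.call(rbind, lapply(seq_len(nrow(got)), function(j) {
      data.frame(sample_id = got$carriers[[j]], chrom = got$chrom[j],
                 start_pos = got$start_pos[j], end_pos = got$end_pos[j],
                 state = if (got$cnv_type[j] == "deletion") 1L else 3L,
                 cnv_type = got$cnv_type[j], n_snps = 5L,
                 length_bp = got$end_pos[j] - got$start_pos[j] + 1L,
                 stringsAsFactors = FALSE)
    }))
    again <- merge_calls(as_calls, 0.5, 8)
    expect_setequal(again$region_id, got$region_id)
    # every call is contained in exactly one region of its type
    for (k in seq_len(nrow(calls))) {
      within <- got$cnv_type == calls$cnv_type[k] & got$chrom == calls$chrom[k] &
        got$start_pos <= calls$start_pos[k] & got$end_pos >= calls$end_pos[k] &
        vapply(got$carriers, function(cs) calls$sample_id[k] %in% cs, TRUE)
      expect_gte(sum(within), 1)
    }
    expect_true(all(got$frequency > 0 & got$frequency <= 1))
    expect_true(all(got$n_carriers <= 8))
  }
})

test_that("BED reading and region filtering follow the stated semantics", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=exclude", "chr1\t0\t1000", "chr2\t5000\t6000"), bed)
  ex <- read_bed(bed)
  expect_equal(ex$start_pos, c(1L, 5001L))   # 0-based half-open -> 1-based inclusive
  expect_equal(ex$end_pos, c(1000L, 6000L))

  writeLines(c("chr1\t0\t1000", "chr1\tnot_a_number\t5"), bed)
  expect_error(read_bed(bed), "line 2")

  regions <- data.frame(
    region_id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr2"),
    start_pos = c(500L, 1001L, 100L), end_pos = c(1500L, 2000L, 900L),
    cnv_type = "deletion", n_carriers = c(5L, 5L, 6L),
    frequency = c(0.05, 0.05, 0.009), stringsAsFactors = FALSE)
  regions$carriers <- list(letters[1:5], letters[1:5], letters[1:6])
  kept <- filter_regions(regions, ex, min_freq = 0.01)
  # "a" overlaps the chr1 exclusion, "b" abuts it (kept), "c" is sub-1%
  expect_identical(kept$region_id, "b")
  # empty exclusion: only the frequency rule applies
  kept2 <- filter_regions(regions, NULL, min_freq = 0.01)
  expect_setequal(kept2$region_id, c("a", "b"))
})

test_that("carrier matrix is consistent with region frequencies", {
  samples <- sprintf("S%02d", 1:10)
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start_pos = c(1L, 100L), end_pos = c(50L, 200L),
                        cnv_type = "deletion", n_carriers = c(3L, 1L),
                        frequency = c(0.3, 0.1), stringsAsFactors = FALSE)
  regions$carriers <- list(c("S01", "S05", "S09"), "S02")
  m <- carrier_matrix(regions, samples)
  expect_equal(unname(colSums(m)), c(3, 1))
  expect_equal(unname(colSums(m)) / length(samples), regions$frequency)
  expect_equal(ncol(carrier_matrix(regions[0, ], samples)), 0)
  regions$carriers[[2]] <- "ghost"
  expect_error(carrier_matrix(regions, samples), "ghost")
})

test_that("replication matching requires same type and >= 1 bp overlap", {
  disc <- data.frame(region_id = "d1", chrom = "chr1", start_pos = 100L,
                     end_pos = 200L, cnv_type = "deletion", stringsAsFactors = FALSE)
  repl <- data.frame(region_id = c("r_del", "r_dup", "r_far"),
                     chrom = "chr1", start_pos = c(200L, 150L, 500L),
                     end_pos = c(400L, 250L, 600L),
                     cnv_type = c("deletion", "duplication", "deletion"),
                     stringsAsFactors = FALSE)
  expect_equal(match_regions(disc, repl)$replication_id, "r_del")
  disc$cnv_type <- "duplication"
  expect_equal(match_regions(disc, repl)$replication_id, "r_dup")
  disc$start_pos <- 700L; disc$end_pos <- 800L
  expect_true(is.na(match_regions(disc, repl)$replication_id))
})
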
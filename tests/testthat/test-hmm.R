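# HMM caller: emissions, Viterbi decoding, call extraction

test_that("emission model obeys its defining properties", {
  p <- hmm_params()
  # a heterozygous marker is impossible at CN1
  ll2 <- emission_loglik(p$lrr_means[["2"]], 0.5, 0.5, 2, p)
  ll1 <- emission_loglik(p$lrr_means[["2"]], 0.5, 0.5, 1, p)
  expect_gt(ll2, ll1)
  # pfb = 0 collapses to the homozygous component; density integrates to 1
  for (s in 1:4) {
    dens <- function(b) vapply(b, function(bb)
      exp(emission_loglik(p$lrr_means[[as.character(s)]], bb, 0, s, p) -
            dnorm(p$lrr_means[[as.character(s)]], p$lrr_means[[as.character(s)]],
                  p$lrr_sds[[as.character(s)]], log = TRUE)), 0)
    expect_equal(integrate(dens, 0, 1)$value, 1, tolerance = 1e-6)
  }
  # allele-label symmetry
  expect_equal(emission_loglik(0.1, 0.31, 0.7, 3, p),
               emission_loglik(0.1, 1 - 0.31, 1 - 0.7, 3, p))
  expect_error(emission_loglik(NA, 0.5, 0.5, 2, p), "non-finite")
  expect_error(emission_loglik(0, 0.5, 1.5, 2, p), "pfb")
})

test_that("transition rows sum to one at any distance", {
  p <- hmm_params()
  for (d in c(0, 50, 5000, 1e5, 1e7)) {
    expect_equal(unname(rowSums(transition_matrix(d, p))), rep(1, 5), tolerance = 1e-12)
  }
})

test_that("a clean diploid signal yields a constant CN2 path and no calls", {
  set.seed(2)
  map <- toy_map(60)
  sig <- list(sample_id = "S1", lrr = rnorm(60, 0, 0.01),
              baf = pmin(1, pmax(0, 0.5 + rnorm(60, 0, 0.01))))
  path <- viterbi_decode(sig, map, hmm_params())
  expect_true(all(path == 2L))
  expect_equal(nrow(extract_calls(path, map, "S1")), 0)
})

test_that("Viterbi equals the exhaustive-enumeration oracle on small instances", {
  p <- hmm_params()
  set.seed(99)
  for (r in 1:60) {
    n <- sample(2:6, 1)
    map <- toy_map(n, spacing = sample(c(500, 2000, 50000), 1),
                   pfb = runif(n))
    sig <- list(sample_id = "S1",
                lrr = rnorm(n, sample(c(-0.7, 0, 0.4), 1), 0.4),
                baf = runif(n))
    got <- viterbi_decode(sig, map, p)
    want <- enum_best_path(sig, map, p)
    expect_identical(got, want$path)
    expect_equal(score_path(got, sig, map, p), want$score, tolerance = 1e-9)
  }
})

test_that("decoding is per-chromosome (invariant to concatenation order)", {
  set.seed(5)
  m1 <- toy_map(30, chrom = "chr1"); m2 <- toy_map(25, chrom = "chr2")
  s1 <- rnorm(30, 0, 0.2); s2 <- c(rnorm(10, 0, 0.2), rnorm(8, -0.66, 0.2), rnorm(7, 0, 0.2))
  b1 <- runif(30); b2 <- runif(25)
  p <- hmm_params()
  fwd <- viterbi_decode(list(lrr = c(s1, s2), baf = c(b1, b2)), rbind(m1, m2), p)
  rev <- viterbi_decode(list(lrr = c(s2, s1), baf = c(b2, b1)), rbind(m2, m1), p)
  expect_identical(fwd, c(rev[26:55], rev[1:25]))
})

test_that("noisier LRR never increases the likelihood of the truth path", {
  set.seed(31)
  map <- toy_map(15)
  truth_path <- c(rep(2L, 5), rep(1L, 6), rep(2L, 4))
  mu <- default_lrr_means()
  base_lrr <- mu[as.character(truth_path)]
  baf <- ifelse(truth_path == 1L, sample(c(0, 1), 15, TRUE), 0.5)
  noise <- rnorm(15)
  p <- hmm_params()
  scores <- vapply(c(0, 0.1, 0.3, 0.6, 1.2), function(s) {
    sig <- list(lrr = base_lrr + s * noise, baf = baf)
    score_path(truth_path, sig, map, p)
  }, 0)
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("extract_calls applies the SNP-count and size filters", {
  map <- data.frame(marker_id = sprintf("m%d", 1:10), chrom = "chr1",
                    pos = c(100, 300, 500, 700, 900, 5000, 10000, 15000, 20000, 25000),
                    pfb = 0.5, gc = 0.5, stringsAsFactors = FALSE)
  # run of 2 markers: too few SNPs
  p2 <- c(2, 1, 1, 2, 2, 2, 2, 2, 2, 2)
  expect_equal(nrow(extract_calls(p2, map, "S")), 0)
  # run of 3 markers spanning 800 bp total (< 1 kb): too short
  p3 <- c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2)
  expect_equal(nrow(extract_calls(p3, map, "S")), 0)
  # 5-marker duplication spanning 20 kb survives
  p5 <- c(2, 2, 2, 2, 2, 3, 3, 3, 3, 3)
  got <- extract_calls(p5, map, "S")
  expect_equal(nrow(got), 1)
  expect_equal(got$cnv_type, "duplication")
  expect_equal(got$n_snps, 5L)
  expect_equal(got$length_bp, 25000 - 5000 + 1)
  expect_equal(got$state, 3L)
})

test_that("per-sample calls never overlap and come out sorted", {
  set.seed(17)
  map <- simulate_marker_map(2000, c(chr1 = 3e6, chr2 = 2e6), seed = 3)
  truth <- simulate_truth_cnvs(map, sprintf("S%d", 1:5), mean_cnvs = 4, seed = 8)
  sigs <- simulate_signals(map, truth, sprintf("S%d", 1:5), seed = 9)
  for (sid in names(sigs)) {
    calls <- call_cnvs(sigs[[sid]], map)
    for (ch in unique(calls$chrom)) {
      cc <- calls[calls$chrom == ch, ]
      if (nrow(cc) < 2) next
      expect_true(all(diff(cc$start_pos) > 0))
      expect_true(all(cc$start_pos[-1] > cc$end_pos[-nrow(cc)]))
    }
    expect_true(all(calls$n_snps >= 3 & calls$length_bp >= 1000))
    expect_true(all(calls$state != 2))
  }
})

test_that("rawcnv writer and reader round-trip calls", {
  calls <- data.frame(sample_id = c("A", "B"), chrom = c("chr1", "chr2"),
                      start_pos = c(1000L, 5000L), end_pos = c(5000L, 9000L),
                      state = c(1L, 3L), cnv_type = c("deletion", "duplication"),
                      n_snps = c(5L, 7L), length_bp = c(4001L, 4001L),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".rawcnv")
  write_rawcnv(calls, f)
  expect_identical(readLines(f)[1], "chr1:1000-5000 numsnp=5 length=4001 state1,cn=1 A")
  expect_identical(read_rawcnv(f), calls)
})

test_that("PFB compiled from samples recovers marker BAF medians", {
  map <- toy_map(200, pfb = runif(200))
  truth <- data.frame(sample_id = character(), chrom = character(),
                      start_pos = integer(), end_pos = integer(), copy_number = integer())
  sigs <- simulate_signals(map, truth, sprintf("S%d", 1:30),
                           noise = list(lrr_sd = 0.1, baf_sd = 0.02, gc_wave_coef = 0),
                           seed = 12)
  pfb <- compile_pfb(sigs, map)
  expect_equal(pfb$marker_id, map$marker_id)
  # median BAF across samples tracks allele frequency monotonically
  expect_gt(cor(pfb$pfb, map$pfb), 0.8)
})
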
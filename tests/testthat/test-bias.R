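eventsFromMult <- function(mult, contig = "c1", sizes = NULL) {
  if (is.null(sizes)) sizes <- rep(300L, length(mult))
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = seq_along(mult) * 1000L,
                              width = sizes))
  S4Vectors::mcols(gr)$multiplicity <- as.integer(mult)
  S4Vectors::mcols(gr)$gc <- rep(0.5, length(mult))
  gr
}

test_that("coverage CV matches hand-computed values", {
  expect_equal(coverageCV(c(4, 4, 4, 4)), 0)
  expect_equal(coverageCV(c(2, 4)), 100 * sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(round(coverageCV(c(2, 4)), 2), 47.14)
  expect_equal(coverageCV(c(0, 0, 6, 6)), 100 * sqrt(12) / 3,
               tolerance = 1e-12)
  expect_equal(round(coverageCV(c(0, 0, 6, 6)), 2), 115.47)
  expect_true(is.na(coverageCV(c(0, 0, 0))))
})

test_that("70%/30% depth classes are relative to the contig maximum", {
  ev <- eventsFromMult(c(10, 7, 3, 2))
  expect_equal(as.character(classifyEventDepth(ev)),
               c("high", "high", "low", "low"))

  ev2 <- eventsFromMult(c(10, 5))
  expect_equal(as.character(classifyEventDepth(ev2))[2], "intermediate")

  single <- eventsFromMult(5)
  expect_equal(as.character(classifyEventDepth(single)), "high")

  # maxima are per contig, not global: 10 is high on c1 (max 10) even
  # though it would be intermediate against c2's max of 20
  two <- suppressWarnings(
    c(eventsFromMult(c(10, 3)), eventsFromMult(c(20, 2), contig = "c2")))
  expect_equal(as.character(classifyEventDepth(two)),
               c("high", "low", "high", "low"))

  # partition invariant
  set.seed(4)
  ev3 <- eventsFromMult(sample(1:20, 50, replace = TRUE))
  expect_equal(sum(table(classifyEventDepth(ev3))), 50)
})

test_that("insert-size bias test reproduces hand-derived KS and d", {
  r <- insertSizeBiasTest(c(100, 100, 200), c(200, 300))
  expect_equal(r$ks_distance, 2 / 3, tolerance = 1e-12)

  same <- insertSizeBiasTest(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$ks_distance, 0)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$d_magnitude, "negligible")

  r2 <- insertSizeBiasTest(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r2$cohens_d, -2, tolerance = 1e-12)
  expect_equal(r2$d_magnitude, "large")
  expect_equal(r2$mean_high, 2)
  expect_equal(r2$mean_low, 4)

  empty <- insertSizeBiasTest(numeric(), c(1, 2))
  expect_false(empty$estimable)
  expect_true(is.na(empty$ks_distance))
})

test_that("Cohen's d uses (n-1)-weighted pooling and magnitude bands", {
  x <- c(2, 4, 6, 8)
  y <- c(1, 2, 3)
  nx <- 4; ny <- 3
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  expect_equal(cohensD(x, y)$d, (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_equal(cohensD(c(0, 0.1), c(0, 0.1))$magnitude, "negligible")
  expect_equal(cohensD(1, c(1, 2))$magnitude, "not estimable")
})

test_that("duplication ratio counts exact pair matches", {
  r1 <- c(rep("AAAA", 4), rep("CCCC", 3), "GGGG", "TTTT", "ACGT")
  r2 <- c(rep("TTTT", 4), rep("GGGG", 3), "AAAA", "CCCC", "TGCA")
  expect_equal(duplicationRatio(r1, r2)$pairs, 1 - 5 / 10)

  ten <- duplicationRatio(rep(c("A", "C", "G", "T"), length.out = 10),
                          rep("X", 10))
  expect_equal(ten$pairs, 0.6)  # 10 pairs, 4 distinct

  expect_equal(duplicationRatio(letters[1:5], letters[6:10])$pairs, 0)
  expect_equal(duplicationRatio(rep("ACGT", 5), rep("TTTT", 5))$pairs, 0.8)

  # a substitution breaks duplicate identity (exact match only)
  expect_equal(duplicationRatio(c("AAAA", "AAAT"), c("CCCC", "CCCC"))$pairs,
               0)
})

test_that("duplication ratio equals the O(n^2) pairwise oracle", {
  set.seed(12)
  for (i in 1:3) {
    n <- 120
    pool <- vapply(1:40, function(i)
      paste0(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
      character(1))
    r1 <- sample(pool, n, replace = TRUE)
    r2 <- sample(pool, n, replace = TRUE)
    expect_equal(duplicationRatio(r1, r2)$pairs, bruteDupRatio(r1, r2))
  }
})

test_that("normalized coverage scales by library Gbp", {
  expect_equal(normalizedContigCoverage(6, 2e9), 3)
  expect_equal(normalizedContigCoverage(0, 2e9), 0)
  expect_equal(normalizedContigCoverage(4, 2e9),
               2 * normalizedContigCoverage(4, 4e9))
})

test_that("cross-library agreement reports correlations and detection", {
  covA <- c(a = 1, b = 2, c = 3, d = 4)
  r <- crossLibraryAgreement(covA, 2 * covA)
  expect_equal(r$pearson_r2, 1)
  expect_equal(r$spearman_rho, 1)

  rev <- crossLibraryAgreement(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1))
  expect_equal(rev$spearman_rho, -1)

  det <- crossLibraryAgreement(covA, covA,
                               mapped_reads = c(0, 2, 6, 8),
                               mean_depth = c(0, 2, 6, 8))
  expect_equal(det$detected_fraction, 3 / 4)
  expect_equal(det$frac_ge_5x, 2 / 4)

  few <- crossLibraryAgreement(c(1, 0, 0), c(1, 0, 0))
  expect_false(few$estimable)
})

test_that("KS distance matches ECDF enumeration on random samples", {
  set.seed(99)
  for (i in 1:10) {
    x <- sample(50:500, sample(5:60, 1), replace = TRUE)
    y <- sample(50:500, sample(5:60, 1), replace = TRUE)
    expect_equal(insertSizeBiasTest(x, y)$ks_distance, bruteKS(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the per-library report ties the pieces together", {
  cfg <- tinyConfig(pcr_cycles = 14, n_reads = 4000,
                    contig_len = c(10000, 12000), n_molecules = 2000)
  lib <- simulateLibrary(cfg)
  pairs <- truthToPairs(lib$truth, cfg@read_len)
  rep <- computeBiasReport(pairs, lib$reference, r1 = lib$r1, r2 = lib$r2,
                           library_id = "lib14")
  expect_s4_class(rep, "LibraryBiasReport")
  expect_equal(rep@library_id, "lib14")
  expect_equal(length(rep@cv_per_contig), cfg@n_contigs)
  # components reproducible in isolation
  expect_equal(rep@dup_ratio, duplicationRatio(lib$r1, lib$r2)$pairs)
  ev <- collapseEvents(pairs, lib$reference)
  lab <- classifyEventDepth(ev)
  manual <- insertSizeBiasTest(
    GenomicRanges::width(ev)[lab == "high"],
    GenomicRanges::width(ev)[lab == "low"])
  expect_equal(rep@ks_distance, manual$ks_distance)
  expect_equal(rep@cohens_d, manual$cohens_d)
  expect_equal(rep@n_high + rep@n_low <= length(ev), TRUE)

  # not-estimable library: no contig reaches 2 kb
  tiny <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 300)))
  p0 <- truthToPairs(data.frame(contig_id = "s1", start = 0L,
                                insert_len = 300L), read_len = 100)
  ne <- computeBiasReport(p0, tiny)
  expect_equal(ne@mode_flag, "not estimable")
  expect_true(is.na(ne@ks_distance))
})
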
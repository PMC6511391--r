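makeSam <- function(records, path,
                    sq = c("c1" = 1000L)) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, records), path)
  path
}

test_that("SAM ingest converts coordinates and filters records", {
  sam <- tempfile(fileext = ".sam")
  seq50 <- strrep("A", 50)
  q50 <- strrep("I", 50)
  makeSam(c(
    # proper pair, leftmost mate POS=101 (1-based), TLEN=350
    paste("p1", 99, "c1", 101, 60, "50M", "=", 401, 350, seq50, q50,
          sep = "\t"),
    paste("p1", 147, "c1", 401, 60, "50M", "=", 101, -350, seq50, q50,
          sep = "\t"),
    # secondary alignment: must be excluded and counted
    paste("p2", 355, "c1", 11, 0, "50M", "=", 201, 240, seq50, q50,
          sep = "\t")
  ), sam)
  pairs <- parseAlignments(sam)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$start, 100L)      # 0-based
  expect_equal(pairs$insert_len, 350L)
  expect_equal(pairs$mate2_start, 400L)
  expect_equal(pairs$read_len, 50L)
  expect_equal(attr(pairs, "dropped")[["secondary_supplementary"]], 1L)
})

test_that("ingest fails on alignments to unknown contigs", {
  sam <- tempfile(fileext = ".sam")
  seq50 <- strrep("A", 50)
  q50 <- strrep("I", 50)
  makeSam(c(
    paste("p1", 99, "c1", 101, 60, "50M", "=", 401, 350, seq50, q50,
          sep = "\t")
  ), sam)
  expect_error(parseAlignments(sam, refs = c(other = 5000)),
               "unknown contig")
})

test_that("truth TSV ingest conserves pair count", {
  truth <- data.frame(contig_id = "c1", start = c(0L, 10L, 10L),
                      insert_len = c(200L, 210L, 210L), copy_id = 1:3)
  tsv <- tempfile(fileext = ".tsv")
  write.table(truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parseAlignments(tsv), "read_len")
  pairs <- parseAlignments(tsv, read_len = 100)
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$mate2_start, truth$start + truth$insert_len - 100L)
})

test_that("simulator SAM output round-trips through the SAM parser", {
  cfg <- tinyConfig(n_reads = 400)
  dir <- file.path(tempdir(), "samround")
  lib <- simulateLibrary(cfg, outdir = dir, write_sam = TRUE)
  pairs <- parseAlignments(file.path(dir, "truth.sam"), refs = lib$reference)
  expect_equal(nrow(pairs), nrow(lib$truth))
  key <- function(d) sort(paste(d$contig_id, d$start, d$insert_len))
  expect_equal(key(pairs), key(lib$truth))
})

test_that("event collapse groups exact (contig, start, insert) mappings", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 200)))
  pairs <- truthToPairs(
    data.frame(contig_id = "c1",
               start = c(100L, 100L, 100L, 100L),
               insert_len = c(350L, 350L, 350L, 300L)),
    read_len = 100)
  ev <- collapseEvents(pairs, ref)
  expect_equal(length(ev), 2L)
  expect_equal(sort(S4Vectors::mcols(ev)$multiplicity), c(1L, 3L))
  expect_equal(sum(S4Vectors::mcols(ev)$multiplicity), nrow(pairs))

  # gc from direct substring counting; "ACGT" repeats have GC = 0.5
  expect_equal(unname(S4Vectors::mcols(ev)$gc), c(0.5, 0.5))

  empty <- collapseEvents(pairs[0, ], ref)
  expect_equal(length(empty), 0L)

  bad <- truthToPairs(data.frame(contig_id = "c1", start = 700L,
                                 insert_len = 200L), read_len = 90)
  expect_error(collapseEvents(bad, ref), "exceeds contig length")
})

test_that("collapse is idempotent and gc matches character counting", {
  set.seed(8)
  ref <- generateReference(tinyConfig(seed = 9))
  pairs <- randomPairs(300, names(ref), min(Biostrings::width(ref)))
  ev <- collapseEvents(pairs, ref)
  expect_equal(sum(S4Vectors::mcols(ev)$multiplicity), nrow(pairs))

  # expand events of multiplicity 1 back to pairs and re-collapse
  ones <- ev[S4Vectors::mcols(ev)$multiplicity == 1L]
  back <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(ones)),
    start = GenomicRanges::start(ones) - 1L,
    insert_len = GenomicRanges::width(ones))
  ev2 <- collapseEvents(truthToPairs(back, read_len = 50), ref)
  expect_equal(length(ev2), length(ones))
  expect_true(all(S4Vectors::mcols(ev2)$multiplicity == 1L))

  # gc oracle: direct character counting on the reference substring
  for (i in c(1L, 5L, length(ev))) {
    cid <- as.character(GenomicRanges::seqnames(ev))[i]
    s <- substr(as.character(ref[[cid]]),
                GenomicRanges::start(ev)[i], GenomicRanges::end(ev)[i])
    gcCount <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
    expect_equal(S4Vectors::mcols(ev)$gc[i], gcCount / nchar(s))
  }
})

test_that("depth counts aligned read bases per position", {
  # two mates covering [0,5) and [5,10) of a 10 bp contig
  p <- data.frame(contig_id = "c1", start = 0L, insert_len = 10L,
                  mate1_start = 0L, mate2_start = 5L, read_len = 5L)
  prof <- depthProfile(p, "c1", 10)
  expect_equal(prof@depth, rep(1L, 10))

  # mates covering [0,5) and [3,8): positions 3 and 4 are hit twice
  p2 <- data.frame(contig_id = "c1", start = 0L, insert_len = 8L,
                   mate1_start = 0L, mate2_start = 3L, read_len = 5L)
  prof2 <- depthProfile(p2, "c1", 10)
  expect_equal(prof2@depth, c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 0L, 0L))

  # insert-span mode counts the gap too
  prof3 <- depthProfile(p, "c1", 10, mode = "insert")
  expect_equal(prof3@depth, rep(1L, 10))
})

test_that("windowed depth applies the tile and edge-exclusion rules", {
  # two pairs tiling the contig end to end: constant depth 2 on 1000 bp
  p <- data.frame(contig_id = "c1", start = 0L, insert_len = 1000L,
                  mate1_start = 0L, mate2_start = 500L, read_len = 500L)
  p <- rbind(p, p)
  prof <- depthProfile(p, "c1", 1000)
  expect_equal(prof@depth, rep(2L, 1000))
  w <- windowedDepth(prof)
  expect_equal(nrow(w), 6L)            # tiles [200,300) .. [700,800)
  expect_true(all(w$mean_depth == 2))
  expect_true(all(w$start >= 200 & w$end <= 800))
})

test_that("depth profile equals naive per-base counting on random input", {
  set.seed(33)
  for (rep_i in 1:5) {
    pairs <- randomPairs(400, c("cA", "cB"), 3000)
    for (cid in c("cA", "cB")) {
      expect_identical(depthProfile(pairs, cid, 3000)@depth,
                       naiveDepth(pairs, cid, 3000))
    }
  }
})

test_that("bias-contig selection follows the 10 kb / 50 kb / 2 kb rule", {
  sel <- selectBiasContigs(c(a = 40000, b = 12000, c = 3000))
  expect_equal(sel$mode, "ge10kb")
  expect_equal(sort(names(sel$selected)), c("a", "b"))

  sel2 <- selectBiasContigs(c(a = 30000, b = 12000, c = 3000))
  expect_equal(sel2$mode, "ge2kb")
  expect_equal(sort(names(sel2$selected)), c("a", "b", "c"))

  sel3 <- selectBiasContigs(c(a = 1500, b = 900))
  expect_equal(sel3$mode, "not estimable")
  expect_equal(length(sel3$selected), 0L)
})
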
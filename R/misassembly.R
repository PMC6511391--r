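#' Read contig-to-reference segment alignments
#'
#' `readPaf()` parses the first 12 columns of a PAF file (minimap2 and
#' friends); `readSegments()` parses a headered 7-column TSV with columns
#' `query_id`, `q_start`, `q_end`, `ref_id`, `r_start`, `r_end`, `strand`.
#' Both use 0-based half-open coordinates (PAF's native convention).
#'
#' @param path input file.
#' @param min_seg_len minimum aligned query length of a segment; shorter
#'   segments are dropped (default 65 bp).
#' @return data.frame with the 7 segment columns above.
#' @export
readPaf <- function(path, min_seg_len = 65) {
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad))
    stop("malformed PAF record at line ", bad[1L])
  take <- function(i, as = identity)
    as(vapply(fields, `[[`, character(1), i))
  seg <- data.frame(
    query_id = take(1L),
    q_start = take(3L, as.integer),
    q_end = take(4L, as.integer),
    ref_id = take(6L),
    r_start = take(8L, as.integer),
    r_end = take(9L, as.integer),
    strand = take(5L),
    stringsAsFactors = FALSE
  )
  seg[seg$q_end - seg$q_start >= min_seg_len, , drop = FALSE]
}

#' @rdname readPaf
#' @export
readSegments <- function(path, min_seg_len = 65) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "q_start", "q_end", "ref_id", "r_start", "r_end",
            "strand")
  if (!all(need %in% names(seg)))
    stop("segment TSV must have columns: ", paste(need, collapse = ", "))
  seg <- seg[, need]
  seg[seg$q_end - seg$q_start >= min_seg_len, , drop = FALSE]
}

#' Classify breakpoints between adjacent segment alignments
#'
#' For each assembled (query) contig, segments are ordered along the query
#' and every adjacent pair is inspected:
#' \itemize{
#'   \item different reference contigs: \emph{translocation};
#'   \item same reference, opposite strands: \emph{inversion};
#'   \item same reference and strand, but the reference gap differs from the
#'     query gap by more than `gap_threshold` bp (including
#'     order-inconsistent, i.e. strongly negative, reference gaps):
#'     \emph{relocation};
#'   \item otherwise contiguous: no event.
#' }
#' Adjacent segments overlapping on the query by more than `overlap_tol` bp
#' (beyond normal aligner trimming slack) are skipped with a warning.
#'
#' @param segments data.frame as returned by [readPaf()] /
#'   [readSegments()].
#' @param gap_threshold relocation distance threshold in bp (default 1000).
#' @param overlap_tol tolerated query overlap between adjacent segments in
#'   bp (default 50).
#' @param min_seg_len minimum segment length (default 65 bp).
#' @return data.frame with one row per breakpoint: `query_id`, `q_pos`
#'   (query coordinate of the junction), `type` (factor: `relocation`,
#'   `inversion`, `translocation`).
#' @export
classifyBreakpoints <- function(segments, gap_threshold = 1000,
                                overlap_tol = 50, min_seg_len = 65) {
  seg <- segments[segments$q_end - segments$q_start >= min_seg_len, ,
                  drop = FALSE]
  if (any(seg$q_start >= seg$q_end) || any(seg$r_start >= seg$r_end))
    stop("segment intervals must satisfy start < end")
  out <- list()
  n_skipped <- 0L
  for (qid in unique(seg$query_id)) {
    s <- seg[seg$query_id == qid, , drop = FALSE]
    s <- s[order(s$q_start, s$q_end), , drop = FALSE]
    if (nrow(s) < 2L)
      next
    for (i in seq_len(nrow(s) - 1L)) {
      a <- s[i, ]
      b <- s[i + 1L, ]
      overlap <- a$q_end - b$q_start
      if (overlap > overlap_tol) {
        n_skipped <- n_skipped + 1L
        next
      }
      type <- if (a$ref_id != b$ref_id) {
        "translocation"
      } else if (a$strand != b$strand) {
        "inversion"
      } else {
        q_gap <- b$q_start - a$q_end
        r_gap <- if (a$strand == "+") {
          b$r_start - a$r_end
        } else {
          a$r_start - b$r_end
        }
        if (abs(r_gap - q_gap) > gap_threshold) "relocation" else NA
      }
      if (!is.na(type)) {
        out[[length(out) + 1L]] <-
          data.frame(query_id = qid, q_pos = b$q_start, type = type,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped,
            " adjacent segment pair(s) overlapped on the query beyond ",
            overlap_tol, " bp and were skipped")
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(query_id = character(), q_pos = integer(),
               type = character(), stringsAsFactors = FALSE)
  }
  res$type <- factor(res$type,
                     levels = c("relocation", "inversion", "translocation"))
  res
}

#' Misassembly rate per bp
#'
#' (relocations + inversions) divided by the cumulative length of all query
#' contigs >= `min_contig` bp. Translocations are counted but excluded from
#' the numerator: against a reference that is itself a metagenome assembly
#' they may reflect two correct, overlapping contigs rather than an error.
#'
#' @param breakpoints data.frame from [classifyBreakpoints()].
#' @param contig_lengths named numeric, lengths of all query contigs.
#' @param min_contig minimum contig length entering the denominator
#'   (default 1000 bp).
#' @return a [MisassemblyReport-class]; `rate` is `NA` when no contig
#'   reaches `min_contig`.
#' @examples
#' bp <- data.frame(query_id = "q1", q_pos = 1L,
#'                  type = factor(c("relocation", "relocation", "inversion"),
#'                  levels = c("relocation", "inversion", "translocation")))
#' misassemblyRate(bp, c(q1 = 300000))@rate # 1e-5
#' @export
misassemblyRate <- function(breakpoints, contig_lengths, min_contig = 1000) {
  counts <- table(factor(breakpoints$type,
                         levels = c("relocation", "inversion",
                                    "translocation")))
  total <- sum(contig_lengths[contig_lengths >= min_contig])
  n_err <- as.integer(counts[["relocation"]] + counts[["inversion"]])
  methods::new("MisassemblyReport",
    n_relocation = as.integer(counts[["relocation"]]),
    n_inversion = as.integer(counts[["inversion"]]),
    n_translocation = as.integer(counts[["translocation"]]),
    rate = if (total > 0) n_err / total else NA_real_,
    total_bp_ge_1kb = as.numeric(total))
}

#' Construct query contigs with planted misassemblies
#'
#' Builds a synthetic set of contig-to-reference segment alignments with a
#' known number of planted relocations, inversions and translocations,
#' spread across `n_contigs` query contigs (contigs beyond the planted
#' events map as a single clean segment). Useful for validating the
#' breakpoint classifier: each planted event produces exactly one
#' misclassification-free breakpoint.
#'
#' @param n_contigs number of query contigs (>= planted events).
#' @param n_relocation,n_inversion,n_translocation planted event counts
#'   (one event per affected contig).
#' @param contig_len length of each query contig in bp (default 10000).
#' @param jump reference jump planted for relocations, in bp (default
#'   5000; must exceed the classifier's `gap_threshold`).
#' @param seed seed for shuffling which contigs carry which event.
#' @return list: `segments` (data.frame), `contig_lengths` (named numeric),
#'   `truth` (named integer counts), `kinds` (character vector naming each
#'   query contig's planted event, `"clean"` for none).
#' @export
plantMisassemblies <- function(n_contigs = 20, n_relocation = 4,
                               n_inversion = 4, n_translocation = 4,
                               contig_len = 10000, jump = 5000, seed = 1) {
  n_events <- n_relocation + n_inversion + n_translocation
  if (n_contigs < n_events)
    stop("need at least as many contigs as planted events")
  set.seed(as.integer(seed))
  kinds <- sample(c(rep("relocation", n_relocation),
                    rep("inversion", n_inversion),
                    rep("translocation", n_translocation),
                    rep("clean", n_contigs - n_events)))
  half <- contig_len %/% 2L
  segs <- vector("list", n_contigs)
  for (i in seq_len(n_contigs)) {
    qid <- sprintf("query_%03d", i)
    rid <- sprintf("ref_%03d", i)
    r0 <- 1000L
    segs[[i]] <- switch(kinds[i],
      clean = data.frame(
        query_id = qid, q_start = 0L, q_end = contig_len,
        ref_id = rid, r_start = r0, r_end = r0 + contig_len,
        strand = "+", stringsAsFactors = FALSE),
      relocation = data.frame(
        query_id = qid, q_start = c(0L, half),
        q_end = c(half, contig_len),
        ref_id = rid,
        r_start = c(r0, r0 + half + jump),
        r_end = c(r0 + half, r0 + contig_len + jump),
        strand = "+", stringsAsFactors = FALSE),
      inversion = data.frame(
        query_id = qid, q_start = c(0L, half),
        q_end = c(half, contig_len),
        ref_id = rid,
        r_start = c(r0, r0 + half),
        r_end = c(r0 + half, r0 + contig_len),
        strand = c("+", "-"), stringsAsFactors = FALSE),
      translocation = data.frame(
        query_id = qid, q_start = c(0L, half),
        q_end = c(half, contig_len),
        ref_id = c(rid, sprintf("ref_%03d_b", i)),
        r_start = c(r0, r0),
        r_end = c(r0 + half, r0 + contig_len - half),
        strand = "+", stringsAsFactors = FALSE))
  }
  segments <- do.call(rbind, segs)
  list(
    segments = segments,
    contig_lengths = stats::setNames(rep(contig_len, n_contigs),
                                     sprintf("query_%03d", seq_len(n_contigs))),
    truth = c(relocation = n_relocation, inversion = n_inversion,
              translocation = n_translocation),
    kinds = stats::setNames(kinds, sprintf("query_%03d", seq_len(n_contigs)))
  )
}
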
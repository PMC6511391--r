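#' Parse paired-end alignments into read-pair records
#'
#' Reads a SAM/BAM file (via Rsamtools) or a simulator truth TSV into one
#' record per properly paired, primary alignment. For SAM/BAM only the
#' leftmost mate of each pair (positive TLEN) is kept, so each pair appears
#' once; secondary, supplementary, unpaired, improper and cross-contig
#' records are dropped and counted. SAM's 1-based positions are converted to
#' 0-based on ingest, and the insert length is the absolute template length
#' (|TLEN|) of the proper pair.
#'
#' @param path a `.sam`/`.bam` file, or a tab-separated truth table with
#'   columns `contig_id`, `start`, `insert_len` (0-based coordinates).
#' @param refs optional reference contigs: a [Biostrings::DNAStringSet] or a
#'   named vector of contig lengths. When given, alignments to unknown
#'   contigs raise an error.
#' @param read_len read length in bp; required for the TSV branch (the truth
#'   table does not store it), ignored for SAM/BAM where it is taken from
#'   the records.
#' @return data.frame with columns `contig_id`, `start`, `insert_len`,
#'   `mate1_start`, `mate2_start`, `read_len`, and an attribute `dropped`
#'   (named integer: `secondary_supplementary`, `improper_or_unpaired`,
#'   `zero_tlen_or_cross_contig`).
#' @export
parseAlignments <- function(path, refs = NULL, read_len = NULL) {
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pairs <- if (ext %in% c("sam", "bam")) {
    parseSamPairs(path)
  } else {
    if (is.null(read_len))
      stop("read_len is required when parsing a truth TSV")
    truth <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig_id", "start", "insert_len")
    if (!all(need %in% names(truth)))
      stop("truth TSV must have columns: ", paste(need, collapse = ", "))
    out <- truthToPairs(truth, read_len)
    attr(out, "dropped") <- c(secondary_supplementary = 0L,
                              improper_or_unpaired = 0L,
                              zero_tlen_or_cross_contig = 0L)
    out
  }
  if (!is.null(refs)) {
    lens <- contigLengths(refs)
    unknown <- setdiff(unique(pairs$contig_id), names(lens))
    if (length(unknown))
      stop("alignments reference unknown contig(s): ",
           paste(unknown, collapse = ", "))
  }
  pairs
}

parseSamPairs <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "mrnm", "mpos", "isize", "qwidth"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  flag <- rec$flag
  sec_sup <- bitwAnd(flag, 0x100L) > 0L | bitwAnd(flag, 0x800L) > 0L
  n_secsup <- sum(sec_sup)
  primary <- !sec_sup
  proper <- primary & bitwAnd(flag, 0x1L) > 0L & bitwAnd(flag, 0x2L) > 0L &
    bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x8L) == 0L
  n_improper <- sum(primary & !proper)
  same_contig <- proper & !is.na(rec$isize) & rec$isize != 0L &
    (is.na(rec$mrnm) | as.character(rec$mrnm) == as.character(rec$rname))
  same_contig[is.na(same_contig)] <- FALSE
  n_bad_tlen <- sum(proper & !same_contig)
  keep <- same_contig & rec$isize > 0L  # leftmost mate carries the pair
  out <- data.frame(
    contig_id = as.character(rec$rname[keep]),
    start = rec$pos[keep] - 1L,
    insert_len = rec$isize[keep],
    mate1_start = rec$pos[keep] - 1L,
    mate2_start = rec$mpos[keep] - 1L,
    read_len = rec$qwidth[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- c(secondary_supplementary = n_secsup,
                            improper_or_unpaired = n_improper,
                            zero_tlen_or_cross_contig = n_bad_tlen)
  out
}

# accept either sequences or a named length vector
contigLengths <- function(refs) {
  if (methods::is(refs, "DNAStringSet")) {
    stats::setNames(Biostrings::width(refs), names(refs))
  } else if (is.numeric(refs) && !is.null(names(refs))) {
    refs
  } else {
    stop("refs must be a DNAStringSet or a named length vector")
  }
}

#' Collapse read pairs into unique insert-mapping events
#'
#' A unique insert-mapping event is a distinct combination of contig, mapping
#' start coordinate and insert size; its multiplicity is the number of read
#' pairs sharing this exact mapping. The GC fraction of each event is
#' computed from the reference substring spanned by the insert.
#'
#' @param pairs data.frame from [parseAlignments()] or [truthToPairs()].
#' @param refs reference contigs ([Biostrings::DNAStringSet]) or a named
#'   length vector (in which case `gc` is `NA`).
#' @return a [GenomicRanges::GRanges] (one range per event, width = insert
#'   length) with metadata columns `multiplicity` and `gc`. The sum of
#'   multiplicities equals `nrow(pairs)`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 200)))
#' pairs <- truthToPairs(
#'   data.frame(contig_id = "c1", start = c(100, 100, 100, 100),
#'              insert_len = c(350, 350, 350, 300)), read_len = 100)
#' collapseEvents(pairs, ref)
#' @export
collapseEvents <- function(pairs, refs) {
  lens <- contigLengths(refs)
  if (nrow(pairs) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = lens)
    S4Vectors::mcols(gr)$multiplicity <- integer()
    S4Vectors::mcols(gr)$gc <- numeric()
    return(gr)
  }
  over <- pairs$start + pairs$insert_len > lens[pairs$contig_id]
  if (any(over, na.rm = TRUE)) {
    i <- which(over)[1L]
    stop(sprintf("insert span exceeds contig length: %s:%d+%d",
                 pairs$contig_id[i], pairs$start[i], pairs$insert_len[i]))
  }
  key <- paste(pairs$contig_id, pairs$start, pairs$insert_len, sep = "\r")
  tab <- table(key)
  first <- pairs[!duplicated(key), , drop = FALSE]
  first <- first[order(match(
    paste(first$contig_id, first$start, first$insert_len, sep = "\r"),
    names(tab))), , drop = FALSE]
  mult <- as.integer(tab)
  gr <- GenomicRanges::GRanges(
    seqnames = first$contig_id,
    ranges = IRanges::IRanges(start = first$start + 1L,
                              width = first$insert_len),
    seqlengths = lens[unique(c(names(lens)))]
  )
  gc <- if (methods::is(refs, "DNAStringSet")) {
    eventGC(gr, refs)
  } else {
    rep(NA_real_, length(gr))
  }
  S4Vectors::mcols(gr)$multiplicity <- mult
  S4Vectors::mcols(gr)$gc <- gc
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::width(gr))
  gr[ord]
}

# GC fraction of the reference substring under each event
eventGC <- function(gr, refs) {
  gc <- numeric(length(gr))
  for (cid in unique(as.character(GenomicRanges::seqnames(gr)))) {
    i <- which(as.character(GenomicRanges::seqnames(gr)) == cid)
    segs <- Biostrings::extractAt(refs[[cid]], IRanges::ranges(gr)[i])
    gc[i] <- as.numeric(Biostrings::letterFrequency(
      segs, letters = "GC", as.prob = TRUE))
  }
  gc
}

#' Per-base depth profile of one contig
#'
#' Counts aligned read bases per reference position: both mates of each pair
#' contribute their `read_len` bases independently, and the unsequenced gap
#' between mates is not counted. Set `mode = "insert"` to count the full
#' insert span instead (sensitivity analysis).
#'
#' @param pairs data.frame from [parseAlignments()] or [truthToPairs()].
#' @param contig_id contig to profile.
#' @param contig_length its length in bp.
#' @param window_size,edge_exclusion parameters stored for the windowed view
#'   (see [windowedDepth()]).
#' @param mode `"read"` (default) or `"insert"`.
#' @return a [DepthProfile-class].
#' @export
depthProfile <- function(pairs, contig_id, contig_length,
                         window_size = 100, edge_exclusion = 200,
                         mode = c("read", "insert")) {
  mode <- match.arg(mode)
  p <- pairs[pairs$contig_id == contig_id, , drop = FALSE]
  ir <- if (mode == "read") {
    c(IRanges::IRanges(start = p$mate1_start + 1L, width = p$read_len),
      IRanges::IRanges(start = p$mate2_start + 1L, width = p$read_len))
  } else {
    IRanges::IRanges(start = p$start + 1L, width = p$insert_len)
  }
  ir <- IRanges::restrict(ir, start = 1L, end = as.integer(contig_length))
  depth <- as.integer(IRanges::coverage(ir, width = as.integer(contig_length)))
  methods::new("DepthProfile",
    contig_id = contig_id,
    depth = depth,
    window_size = as.integer(window_size),
    edge_exclusion = as.integer(edge_exclusion))
}

#' @describeIn windowedDepth mean depth over complete, non-overlapping tiles
#'   whose span avoids both contig ends.
#' @export
setMethod("windowedDepth", "DepthProfile", function(x, ...) {
  L <- length(x@depth)
  w <- x@window_size
  e <- x@edge_exclusion
  starts <- seq.int(0L, L - 1L, by = w)
  ends <- starts + w
  keep <- starts >= e & ends <= L - e
  starts <- starts[keep]
  ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(start = integer(), end = integer(),
                      mean_depth = numeric()))
  }
  cs <- c(0, cumsum(as.numeric(x@depth)))
  data.frame(start = starts, end = ends,
             mean_depth = (cs[ends + 1L] - cs[starts + 1L]) / w)
})

#' Select the contigs used for coverage-bias estimation
#'
#' Mode `"ge10kb"`: all contigs >= 10 kb, provided they total >= 50 kb;
#' otherwise mode `"ge2kb"`: all contigs >= 2 kb. When no contig reaches
#' 2 kb, the bias is not estimable for that library and an empty selection is
#' returned with mode `"not estimable"`.
#'
#' @param lengths named numeric vector of contig lengths (bp).
#' @param min_large,min_small,min_total the 10 kb / 2 kb / 50 kb thresholds.
#' @return list with `mode` (one of `"ge10kb"`, `"ge2kb"`,
#'   `"not estimable"`) and `selected` (named lengths, possibly empty).
#' @examples
#' selectBiasContigs(c(a = 40000, b = 12000, c = 3000))$mode # "ge10kb"
#' @export
selectBiasContigs <- function(lengths, min_large = 10000,
                              min_small = 2000, min_total = 50000) {
  large <- lengths[lengths >= min_large]
  if (sum(large) >= min_total) {
    return(list(mode = "ge10kb", selected = large))
  }
  small <- lengths[lengths >= min_small]
  if (length(small)) {
    list(mode = "ge2kb", selected = small)
  } else {
    list(mode = "not estimable", selected = lengths[0])
  }
}
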
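REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full diagnostic pipeline on one library
#'
#' Orchestrates ingest and statistics for a single library and writes one
#' machine-readable JSON report plus TSV tables. Inputs beyond contigs and
#' alignments are optional; the corresponding report sections are omitted
#' when absent. The report also carries an explicit, configurable
#' recommendation rule: the flag `dedup_single_cell_advised` is set when the
#' duplication ratio reaches `rec_dup_min` and Cohen's d is at most
#' `rec_d_max`, i.e. when the library shows both heavy duplication and a
#' shorter-insert enrichment in high-depth regions - the regime in which
#' read deduplication plus a single-cell assembler is expected to outperform
#' a standard metagenome pipeline. The raw statistics are always reported
#' alongside the flag.
#'
#' @param contigs path to the reference/assembly contigs (FASTA).
#' @param alignments path to paired-end alignments (SAM/BAM or truth TSV).
#' @param reads_r1,reads_r2 optional FASTQ mate files (for the duplication
#'   ratio and library size).
#' @param gene_table optional TSV with columns `gene_len`, `ref_len`,
#'   `evalue`, `score` (for the partial-gene fraction).
#' @param segments optional PAF or segment TSV of contig-to-reference
#'   alignments (for the misassembly report).
#' @param out_dir output directory; created if needed.
#' @param library_id library name.
#' @param read_len read length, required when `alignments` is a truth TSV.
#' @param hi_frac,lo_frac,window_size,edge_exclusion,gap_threshold analysis
#'   thresholds (see the underlying functions).
#' @param rec_dup_min,rec_d_max recommendation-rule thresholds (defaults
#'   0.25 and -0.2).
#' @param subsample_n,seed partial-gene subsampling parameters.
#' @return (invisibly) the report as a nested list; side effects: writes
#'   `report.json`, `per_contig.tsv`, `per_event.tsv` under `out_dir`.
#' @export
runReport <- function(contigs, alignments, out_dir,
                      reads_r1 = NULL, reads_r2 = NULL,
                      gene_table = NULL, segments = NULL,
                      library_id = "library", read_len = NULL,
                      hi_frac = 0.70, lo_frac = 0.30,
                      window_size = 100, edge_exclusion = 200,
                      gap_threshold = 1000,
                      rec_dup_min = 0.25, rec_d_max = -0.2,
                      subsample_n = 20000, seed = 1) {
  for (p in c(contigs, alignments, reads_r1, reads_r2, gene_table, segments)) {
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::readDNAStringSet(contigs)
  names(ref) <- sub("\\s.*$", "", names(ref))
  pairs <- parseAlignments(alignments, refs = ref, read_len = read_len)
  r1 <- if (!is.null(reads_r1))
    Biostrings::readDNAStringSet(reads_r1, format = "fastq")
  r2 <- if (!is.null(reads_r2))
    Biostrings::readDNAStringSet(reads_r2, format = "fastq")
  bias <- computeBiasReport(pairs, ref, r1 = r1, r2 = r2,
                            library_id = library_id,
                            hi_frac = hi_frac, lo_frac = lo_frac,
                            window_size = window_size,
                            edge_exclusion = edge_exclusion)
  asm <- assemblySummary(Biostrings::width(ref))
  library_total_bp <- if (!is.null(r1)) {
    sum(as.numeric(Biostrings::width(r1))) +
      sum(as.numeric(Biostrings::width(r2)))
  } else {
    NA_real_
  }

  # per-contig and per-event tables over the selected contigs
  lens <- contigLengths(ref)
  sel <- selectBiasContigs(lens)
  per_contig <- data.frame(contig_id = names(lens), length = unname(lens),
                           mean_depth = NA_real_, cv_pct = NA_real_,
                           normalized_coverage = NA_real_,
                           stringsAsFactors = FALSE)
  per_event <- data.frame()
  if (length(sel$selected)) {
    for (cid in names(sel$selected)) {
      prof <- depthProfile(pairs, cid, lens[[cid]],
                           window_size = window_size,
                           edge_exclusion = edge_exclusion)
      i <- which(per_contig$contig_id == cid)
      per_contig$mean_depth[i] <- mean(prof@depth)
      per_contig$cv_pct[i] <- coverageCV(prof)
      if (!is.na(library_total_bp))
        per_contig$normalized_coverage[i] <-
          normalizedContigCoverage(prof, library_total_bp)
    }
    p_sel <- pairs[pairs$contig_id %in% names(sel$selected), , drop = FALSE]
    ev <- collapseEvents(p_sel, ref)
    per_event <- data.frame(
      contig_id = as.character(GenomicRanges::seqnames(ev)),
      start = GenomicRanges::start(ev) - 1L,
      insert_len = GenomicRanges::width(ev),
      multiplicity = S4Vectors::mcols(ev)$multiplicity,
      gc = S4Vectors::mcols(ev)$gc,
      class = as.character(classifyEventDepth(ev, hi_frac, lo_frac)),
      stringsAsFactors = FALSE
    )
  }

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    library_id = library_id,
    inputs = list(contigs = contigs, alignments = alignments,
                  n_pairs = nrow(pairs),
                  dropped = as.list(attr(pairs, "dropped"))),
    bias = biasReportToList(bias),
    assembly = assemblySummaryToList(asm),
    library_total_bp = library_total_bp,
    recommendation = list(
      dedup_single_cell_advised =
        !is.na(bias@dup_ratio) && !is.na(bias@cohens_d) &&
        bias@dup_ratio >= rec_dup_min && bias@cohens_d <= rec_d_max,
      rule = sprintf("dup_ratio >= %g AND cohens_d <= %g",
                     rec_dup_min, rec_d_max))
  )
  if (!is.null(gene_table)) {
    rec <- utils::read.delim(gene_table, stringsAsFactors = FALSE)
    report$partial_genes <- partialGeneFraction(
      rec, subsample_n = subsample_n, seed = seed)
  }
  if (!is.null(segments)) {
    seg <- if (tolower(tools::file_ext(segments)) == "paf") {
      readPaf(segments)
    } else {
      readSegments(segments)
    }
    bp <- classifyBreakpoints(seg, gap_threshold = gap_threshold)
    report$misassembly <- misassemblyReportToList(
      misassemblyRate(bp, lens))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.table(per_contig, file.path(out_dir, "per_contig.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(per_event, file.path(out_dir, "per_event.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Flatten report objects to plain lists
#'
#' Helpers turning the S4 report classes into JSON-ready lists; every value
#' is computed by the underlying operation, never re-derived here.
#'
#' @param x the object to flatten.
#' @return a named list.
#' @export
biasReportToList <- function(x) {
  list(
    library_id = x@library_id,
    dup_ratio = x@dup_ratio,
    dup_ratio_reads = x@dup_ratio_reads,
    cv_per_contig = as.list(x@cv_per_contig),
    cv_mean_pct = if (length(x@cv_per_contig))
      mean(x@cv_per_contig, na.rm = TRUE) else NA_real_,
    ks_distance = x@ks_distance,
    ks_pvalue = x@ks_pvalue,
    cohens_d = x@cohens_d,
    d_magnitude = x@d_magnitude,
    mean_insert_high = x@mean_insert_high,
    mean_insert_low = x@mean_insert_low,
    n_high = x@n_high,
    n_low = x@n_low,
    mode_flag = x@mode_flag
  )
}

#' @rdname biasReportToList
#' @export
assemblySummaryToList <- function(x) {
  list(total_bp = x@total_bp, total_bp_ge_10kb = x@total_bp_ge_10kb,
       n_contigs = x@n_contigs, n50 = x@n50, n90 = x@n90,
       largest = x@largest)
}

#' @rdname biasReportToList
#' @export
misassemblyReportToList <- function(x) {
  list(n_relocation = x@n_relocation, n_inversion = x@n_inversion,
       n_translocation = x@n_translocation, rate = x@rate,
       total_bp_ge_1kb = x@total_bp_ge_1kb)
}
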
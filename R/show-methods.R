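setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_contigs, "contigs of",
      paste(object@contig_len, collapse = "-"), "bp,",
      object@n_molecules, "molecules,", object@n_reads, "read pairs\n")
  cat(sprintf("  inserts %g +/- %g bp, reads 2 x %d bp, error rate %g\n",
              object@insert_mean, object@insert_sd, object@read_len,
              object@error_rate))
  cat(sprintf("  PCR: %d cycles, e0 = %g, lambda = %g /bp, L0 = %g bp\n",
              object@pcr_cycles, object@base_efficiency,
              object@length_bias_rate, object@ref_insert_len))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile of %s: %d bp, mean depth %.2f, CV %.1f%%\n",
              object@contig_id, length(object@depth), mean(object@depth),
              coverageCV(object)))
  cat(sprintf("  windows: %d bp tiles, %d bp edge exclusion\n",
              object@window_size, object@edge_exclusion))
})

setMethod("show", "LibraryBiasReport", function(object) {
  cat("LibraryBiasReport for", object@library_id,
      sprintf("(contig selection: %s)\n", object@mode_flag))
  cat(sprintf("  duplication ratio: %s (pairs), %s (reads)\n",
              fmtOrNA(object@dup_ratio, "%.3f"),
              fmtOrNA(object@dup_ratio_reads, "%.3f")))
  if (length(object@cv_per_contig)) {
    cat(sprintf("  coverage CV: mean %.1f%% over %d contig(s)\n",
                mean(object@cv_per_contig, na.rm = TRUE),
                length(object@cv_per_contig)))
  }
  cat(sprintf("  insert-size bias: KS D = %s (p = %s), Cohen's d = %s (%s)\n",
              fmtOrNA(object@ks_distance, "%.3f"),
              fmtOrNA(object@ks_pvalue, "%.2e"),
              fmtOrNA(object@cohens_d, "%.3f"), object@d_magnitude))
  cat(sprintf("  events: %d high depth (mean insert %s bp), %d low (%s bp)\n",
              object@n_high, fmtOrNA(object@mean_insert_high, "%.1f"),
              object@n_low, fmtOrNA(object@mean_insert_low, "%.1f")))
})

setMethod("show", "AssemblySummary", function(object) {
  cat(sprintf("AssemblySummary: %d contigs, %s bp total (%s bp in >= 10 kb)\n",
              object@n_contigs, format(object@total_bp, big.mark = ","),
              format(object@total_bp_ge_10kb, big.mark = ",")))
  cat(sprintf("  N50 = %s, N90 = %s, largest = %s bp\n",
              format(object@n50, big.mark = ","),
              format(object@n90, big.mark = ","),
              format(object@largest, big.mark = ",")))
})

setMethod("show", "MisassemblyReport", function(object) {
  cat(sprintf(
    "MisassemblyReport: %d relocation(s), %d inversion(s), %d translocation(s)\n",
    object@n_relocation, object@n_inversion, object@n_translocation))
  cat(sprintf("  rate: %s per bp over %s bp (contigs >= 1 kb; translocations excluded)\n",
              fmtOrNA(object@rate, "%.3g"),
              format(object@total_bp_ge_1kb, big.mark = ",")))
})

fmtOrNA <- function(x, fmt) {
  if (is.na(x)) "NA" else sprintf(fmt, x)
}
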
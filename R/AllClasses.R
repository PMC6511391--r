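#' Simulation configuration for a PCR-amplified library
#'
#' Holds every parameter of the forward simulator: the reference contig set,
#' the pool of original insert molecules, the per-cycle amplification model,
#' and the final sequencing step. Amplification efficiency decays with insert
#' length as \eqn{e(L) = e_0 \exp(-\lambda \max(0, L - L_0))}, so after
#' \eqn{c} cycles a molecule of length \eqn{L} has expected copy number
#' \eqn{(1 + e(L))^c}: short inserts are amplified preferentially, which is
#' the mechanism that makes PCR-amplified libraries unevenly covered.
#'
#' @slot n_contigs number of reference contigs.
#' @slot contig_len integer length-2 vector, min/max contig length (bp).
#' @slot gc_target per-base probability of G or C, in \[0, 1\].
#' @slot n_molecules number of original (pre-PCR) insert molecules.
#' @slot insert_mean,insert_sd Gaussian insert-length parameters (bp).
#' @slot pcr_cycles number of PCR cycles \eqn{c \ge 0}.
#' @slot base_efficiency \eqn{e_0}, per-cycle amplification efficiency of a
#'   short insert, in \[0, 1\].
#' @slot length_bias_rate \eqn{\lambda}, per-bp decay rate of the efficiency
#'   (0 switches the length bias off).
#' @slot ref_insert_len \eqn{L_0}, pivot length (bp) below which no decay
#'   applies.
#' @slot n_reads number of read pairs sampled from the amplified pool.
#' @slot read_len read length (bp).
#' @slot error_rate per-base substitution probability, in \[0, 1\].
#' @slot seed integer seed driving the single RNG stream
#'   (reference -> inserts -> sampling -> errors).
#'
#' @seealso [SimConfig()] for the user-facing constructor,
#'   [simulateLibrary()] for the end-to-end simulator.
#' @export
setClass("SimConfig",
  representation(
    n_contigs = "integer",
    contig_len = "integer",
    gc_target = "numeric",
    n_molecules = "integer",
    insert_mean = "numeric",
    insert_sd = "numeric",
    pcr_cycles = "integer",
    base_efficiency = "numeric",
    length_bias_rate = "numeric",
    ref_insert_len = "numeric",
    n_reads = "integer",
    read_len = "integer",
    error_rate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_contigs < 1L)
    msg <- c(msg, "n_contigs must be >= 1")
  if (length(object@contig_len) != 2L || any(object@contig_len < 1L) ||
      object@contig_len[1L] > object@contig_len[2L])
    msg <- c(msg, "contig_len must be a valid (min, max) bp range")
  for (p in c("gc_target", "base_efficiency", "error_rate")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a probability in [0, 1]", p))
  }
  if (object@pcr_cycles < 0L)
    msg <- c(msg, "pcr_cycles must be >= 0")
  if (object@length_bias_rate < 0)
    msg <- c(msg, "length_bias_rate must be >= 0")
  if (object@insert_sd < 0)
    msg <- c(msg, "insert_sd must be >= 0")
  if (object@read_len > object@insert_mean)
    msg <- c(msg, "read_len must not exceed insert_mean")
  if (object@insert_mean + 4 * object@insert_sd > object@contig_len[1L])
    msg <- c(msg, "insert_mean + 4*insert_sd must fit inside the shortest contig")
  if (object@n_molecules < 1L || object@n_reads < 1L || object@read_len < 1L)
    msg <- c(msg, "n_molecules, n_reads and read_len must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Per-base read depth along one contig
#'
#' Depth counts aligned read bases (both mates of a pair separately, not the
#' unsequenced insert gap). The windowed view averages depth over
#' non-overlapping tiles of `window_size` bp, discarding tiles that intersect
#' the first or last `edge_exclusion` bp of the contig, where depth estimates
#' are unreliable.
#'
#' @slot contig_id contig name.
#' @slot depth integer vector, one entry per reference base.
#' @slot window_size tile width (bp) for [windowedDepth()].
#' @slot edge_exclusion bp excluded at each contig end in the windowed view.
#'
#' @seealso [depthProfile()], [windowedDepth()], [coverageCV()]
#' @export
setClass("DepthProfile",
  representation(
    contig_id = "character",
    depth = "integer",
    window_size = "integer",
    edge_exclusion = "integer"
  )
)

setValidity("DepthProfile", function(object) {
  msg <- character()
  if (length(object@contig_id) != 1L)
    msg <- c(msg, "contig_id must be a single string")
  if (any(object@depth < 0L))
    msg <- c(msg, "depth entries must be >= 0")
  if (object@window_size < 1L || object@edge_exclusion < 0L)
    msg <- c(msg, "window_size must be >= 1 and edge_exclusion >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-library coverage-bias diagnostics
#'
#' One object per sequencing library, combining the duplication ratio, the
#' per-contig coefficient of variation of depth, and the comparison of
#' insert-size distributions between high- and low-depth unique insert events
#' (Kolmogorov-Smirnov distance and Cohen's d). A negative `cohens_d` means
#' inserts in high-depth regions are shorter on average - the signature of
#' preferential PCR amplification of short inserts.
#'
#' @slot library_id library name.
#' @slot dup_ratio fraction of read pairs that are exact-sequence duplicates
#'   of another pair (`NA` when read sequences were not supplied).
#' @slot dup_ratio_reads same quantity counted over individual reads.
#' @slot cv_per_contig named numeric, percent CV of per-base depth per
#'   analysed contig.
#' @slot ks_distance,ks_pvalue two-sample KS statistic and asymptotic
#'   two-sided p-value, high- vs low-depth insert sizes.
#' @slot cohens_d standardized mean difference (high minus low, pooled sd).
#' @slot d_magnitude one of negligible/small/medium/large (|d| cut at
#'   0.2/0.5/0.8).
#' @slot mean_insert_high,mean_insert_low mean insert size (bp) per class.
#' @slot n_high,n_low number of unique insert events per class.
#' @slot mode_flag contig-selection mode: `"ge10kb"`, `"ge2kb"` or
#'   `"not estimable"`.
#'
#' @seealso [computeBiasReport()], [insertSizeBiasTest()],
#'   [classifyEventDepth()]
#' @export
setClass("LibraryBiasReport",
  representation(
    library_id = "character",
    dup_ratio = "numeric",
    dup_ratio_reads = "numeric",
    cv_per_contig = "numeric",
    ks_distance = "numeric",
    ks_pvalue = "numeric",
    cohens_d = "numeric",
    d_magnitude = "character",
    mean_insert_high = "numeric",
    mean_insert_low = "numeric",
    n_high = "integer",
    n_low = "integer",
    mode_flag = "character"
  )
)

setValidity("LibraryBiasReport", function(object) {
  msg <- character()
  if (!is.na(object@ks_distance) &&
      (object@ks_distance < 0 || object@ks_distance > 1))
    msg <- c(msg, "ks_distance must lie in [0, 1]")
  if (!is.na(object@dup_ratio) &&
      (object@dup_ratio < 0 || object@dup_ratio >= 1))
    msg <- c(msg, "dup_ratio must lie in [0, 1)")
  if (!object@d_magnitude %in%
      c("negligible", "small", "medium", "large", "not estimable"))
    msg <- c(msg, "invalid d_magnitude")
  if (any(c(object@n_high, object@n_low) < 0L))
    msg <- c(msg, "class counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Assembly contiguity summary
#'
#' Contiguity metrics of one contig set: cumulative sizes (all contigs, and
#' contigs >= 10 kb), contig count, N50, N90 and largest contig. N50 (N90) is
#' the minimal contig length among the largest contigs that together make up
#' 50% (90%) of the total assembly size.
#'
#' @slot total_bp cumulative length of all contigs.
#' @slot total_bp_ge_10kb cumulative length of contigs >= 10 kb.
#' @slot n_contigs number of contigs.
#' @slot n50,n90 N50 and N90 (bp).
#' @slot largest length of the largest contig (bp).
#'
#' @seealso [assemblySummary()]
#' @export
setClass("AssemblySummary",
  representation(
    total_bp = "numeric",
    total_bp_ge_10kb = "numeric",
    n_contigs = "integer",
    n50 = "numeric",
    n90 = "numeric",
    largest = "numeric"
  )
)

setValidity("AssemblySummary", function(object) {
  msg <- character()
  if (object@largest < object@n50 || object@n50 < object@n90)
    msg <- c(msg, "must satisfy largest >= n50 >= n90")
  if (object@total_bp_ge_10kb > object@total_bp)
    msg <- c(msg, "total_bp_ge_10kb cannot exceed total_bp")
  if (any(c(object@total_bp, object@n50, object@n90, object@largest,
            object@total_bp_ge_10kb) < 0) || object@n_contigs < 0L)
    msg <- c(msg, "all metrics must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Misassembly counts and per-bp rate
#'
#' Counts of breakpoints classified as relocation, inversion or translocation
#' between an assembled contig set and a reference contig set. The rate is
#' (relocations + inversions) divided by the cumulative length of all query
#' contigs >= 1 kb; translocations are reported but excluded from the rate,
#' because when the reference is itself a metagenome assembly a split across
#' reference contigs may simply reflect two correct, overlapping assemblies.
#'
#' @slot n_relocation,n_inversion,n_translocation breakpoint counts.
#' @slot rate misassemblies per bp (`NA` when no >= 1 kb contigs exist).
#' @slot total_bp_ge_1kb cumulative length (bp) of contigs >= 1 kb.
#'
#' @seealso [classifyBreakpoints()], [misassemblyRate()]
#' @export
setClass("MisassemblyReport",
  representation(
    n_relocation = "integer",
    n_inversion = "integer",
    n_translocation = "integer",
    rate = "numeric",
    total_bp_ge_1kb = "numeric"
  )
)

setValidity("MisassemblyReport", function(object) {
  msg <- character()
  if (any(c(object@n_relocation, object@n_inversion,
            object@n_translocation) < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (!is.na(object@rate) && object@rate < 0)
    msg <- c(msg, "rate must be >= 0")
  if (length(msg)) msg else TRUE
})
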
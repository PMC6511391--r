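#' @describeIn coverageCV percent CV of a numeric depth vector.
#' @export
setMethod("coverageCV", "numeric", function(x, ...) {
  m <- mean(x)
  if (!length(x) || is.na(m) || m == 0)
    return(NA_real_)
  100 * stats::sd(x) / m
})

#' @describeIn coverageCV percent CV of the full per-base depth vector of a
#'   profile (no edge exclusion).
#' @export
setMethod("coverageCV", "DepthProfile", function(x, ...) {
  coverageCV(as.numeric(x@depth))
})

#' Classify unique insert events as high, low or intermediate depth
#'
#' Within each contig, events whose depth is >= `hi_frac` of the contig
#' maximum are "high", events at <= `lo_frac` of the maximum are "low", the
#' rest "intermediate". By default an event's depth is its duplicate
#' multiplicity and the maximum is taken over events of the same contig; pass
#' `event_depth` (e.g. mean per-base depth across each insert span) to use a
#' different depth measure.
#'
#' @param events [GenomicRanges::GRanges] from [collapseEvents()].
#' @param hi_frac,lo_frac class thresholds as fractions of the contig
#'   maximum (defaults 0.70 and 0.30).
#' @param event_depth optional numeric vector overriding
#'   `mcols(events)$multiplicity` as the per-event depth.
#' @return factor with levels `high`, `intermediate`, `low`, parallel to
#'   `events`.
#' @export
classifyEventDepth <- function(events, hi_frac = 0.70, lo_frac = 0.30,
                               event_depth = NULL) {
  depth <- if (is.null(event_depth)) {
    S4Vectors::mcols(events)$multiplicity
  } else {
    event_depth
  }
  if (length(depth) != length(events))
    stop("event_depth must be parallel to events")
  cid <- as.character(GenomicRanges::seqnames(events))
  mx <- tapply(depth, cid, max)[cid]
  lab <- rep("intermediate", length(events))
  lab[depth >= hi_frac * mx] <- "high"
  lab[depth <= lo_frac * mx] <- "low"
  factor(lab, levels = c("high", "intermediate", "low"))
}

#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with
#' (n-1)-weighted pooling, and its conventional magnitude band (|d| cut at
#' 0.2 / 0.5 / 0.8 into negligible / small / medium / large).
#'
#' @param x,y numeric samples.
#' @return list with `d` and `magnitude`; `d` is `NA` (magnitude
#'   `"not estimable"`) when either sample has fewer than 2 values.
#' @examples
#' cohensD(c(1, 2, 3), c(3, 4, 5)) # d = -2, large
#' @export
cohensD <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L)
    return(list(d = NA_real_, magnitude = "not estimable"))
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  dm <- mean(x) - mean(y)
  d <- if (sp2 == 0) {
    if (dm == 0) 0 else sign(dm) * Inf
  } else {
    dm / sqrt(sp2)
  }
  mag <- if (is.na(d)) "not estimable"
    else if (abs(d) < 0.2) "negligible"
    else if (abs(d) < 0.5) "small"
    else if (abs(d) < 0.8) "medium"
    else "large"
  list(d = d, magnitude = mag)
}

#' Compare insert sizes of high- versus low-depth events
#'
#' Two-sample Kolmogorov-Smirnov test (maximum absolute ECDF difference,
#' asymptotic two-sided p-value) plus Cohen's d between the insert-size
#' distributions of high- and low-depth unique insert events. The sign
#' convention is high minus low: a negative d means high-depth regions hold
#' shorter inserts, the direction expected under preferential PCR
#' amplification of short inserts.
#'
#' @param high_sizes,low_sizes insert lengths (bp) of the two classes.
#' @return list: `ks_distance`, `ks_pvalue`, `cohens_d`, `d_magnitude`,
#'   `mean_high`, `mean_low`, `n_high`, `n_low`, `estimable`. When either
#'   class is empty the statistics are `NA` and `estimable` is `FALSE`.
#' @examples
#' insertSizeBiasTest(c(100, 100, 200), c(200, 300))$ks_distance # 2/3
#' @export
insertSizeBiasTest <- function(high_sizes, low_sizes) {
  nh <- length(high_sizes)
  nl <- length(low_sizes)
  if (nh == 0L || nl == 0L) {
    return(list(ks_distance = NA_real_, ks_pvalue = NA_real_,
                cohens_d = NA_real_, d_magnitude = "not estimable",
                mean_high = if (nh) mean(high_sizes) else NA_real_,
                mean_low = if (nl) mean(low_sizes) else NA_real_,
                n_high = nh, n_low = nl, estimable = FALSE))
  }
  ks <- suppressWarnings(
    stats::ks.test(high_sizes, low_sizes, exact = FALSE))
  d <- cohensD(high_sizes, low_sizes)
  list(ks_distance = unname(ks$statistic),
       ks_pvalue = unname(ks$p.value),
       cohens_d = d$d,
       d_magnitude = d$magnitude,
       mean_high = mean(high_sizes),
       mean_low = mean(low_sizes),
       n_high = nh, n_low = nl, estimable = TRUE)
}

#' Exact-duplicate ratio of a paired-end library
#'
#' A pair's identity key is the ordered tuple (mate-1 sequence, mate-2
#' sequence); only exact string matches count as duplicates (no
#' substitutions, no reverse-complement canonicalization). The pair-level
#' ratio is `1 - distinct pairs / input pairs`; the read-level ratio applies
#' the same definition to each mate pool separately.
#'
#' @param r1,r2 mate sequences, character vectors or
#'   [Biostrings::DNAStringSet]s of equal length.
#' @return list with `pairs` and `reads` duplication ratios, plus
#'   `n_pairs` and `n_distinct_pairs`.
#' @examples
#' duplicationRatio(rep("ACGT", 5), rep("TTTT", 5))$pairs # 0.8
#' @export
duplicationRatio <- function(r1, r2) {
  r1 <- as.character(r1)
  r2 <- as.character(r2)
  if (length(r1) != length(r2))
    stop("r1 and r2 must have the same length")
  n <- length(r1)
  if (n == 0L)
    stop("need at least one read pair")
  key <- paste(r1, r2, sep = "\r")
  nd <- length(unique(key))
  list(
    pairs = 1 - nd / n,
    reads = 1 - (length(unique(r1)) + length(unique(r2))) / (2 * n),
    n_pairs = n,
    n_distinct_pairs = nd
  )
}

#' Library-size-normalized contig coverage
#'
#' Mean per-base depth divided by the library size in Gbp, so coverages of
#' libraries sequenced to different depths are comparable.
#'
#' @param x a [DepthProfile-class] or a mean-depth numeric vector.
#' @param library_total_bp total number of sequenced bases in the library.
#' @return depth per Gbp of library.
#' @examples
#' normalizedContigCoverage(6, 2e9) # 3
#' @export
normalizedContigCoverage <- function(x, library_total_bp) {
  if (library_total_bp <= 0)
    stop("library_total_bp must be > 0")
  md <- if (methods::is(x, "DepthProfile")) mean(x@depth) else as.numeric(x)
  md / (library_total_bp / 1e9)
}

#' Agreement between two libraries over a shared contig set
#'
#' Pearson r-squared and Spearman rho of normalized coverages over contigs
#' covered in both libraries, plus detection statistics for library B
#' against the reference contigs: the fraction of contigs with at least one
#' mapped read and the fraction at >= 5x average depth.
#'
#' @param covA,covB named numeric, normalized coverage per contig (same
#'   contig universe).
#' @param mapped_reads optional named integer, raw mapped-read counts per
#'   contig in library B (for `detected_fraction`).
#' @param mean_depth optional named numeric, average depth per contig in
#'   library B (for `frac_ge_5x`).
#' @param min_depth detection threshold on average depth (default 5).
#' @return list: `pearson_r2`, `spearman_rho`, `n_shared`, `estimable`,
#'   `detected_fraction`, `frac_ge_5x`.
#' @export
crossLibraryAgreement <- function(covA, covB, mapped_reads = NULL,
                                  mean_depth = NULL, min_depth = 5) {
  if (length(covA) != length(covB))
    stop("covA and covB must cover the same contig universe")
  if (!is.null(names(covA)) && !is.null(names(covB))) {
    if (!setequal(names(covA), names(covB)))
      stop("covA and covB must name the same contigs")
    covB <- covB[names(covA)]
  }
  shared <- which(covA > 0 & covB > 0)
  if (length(shared) >= 3L) {
    r2 <- stats::cor(covA[shared], covB[shared])^2
    rho <- stats::cor(covA[shared], covB[shared], method = "spearman")
    est <- TRUE
  } else {
    r2 <- NA_real_
    rho <- NA_real_
    est <- FALSE
  }
  list(
    pearson_r2 = unname(r2),
    spearman_rho = unname(rho),
    n_shared = length(shared),
    estimable = est,
    detected_fraction = if (is.null(mapped_reads)) NA_real_
      else mean(mapped_reads >= 1),
    frac_ge_5x = if (is.null(mean_depth)) NA_real_
      else mean(mean_depth >= min_depth)
  )
}

#' Full per-library coverage-bias report
#'
#' Runs the whole diagnostic chain for one library: contig selection
#' ([selectBiasContigs()]), collapse into unique insert events
#' ([collapseEvents()]), high/low depth classification
#' ([classifyEventDepth()]), the insert-size bias test
#' ([insertSizeBiasTest()]), per-contig depth CVs, and (when read sequences
#' are supplied) the exact-duplicate ratio.
#'
#' @param pairs data.frame from [parseAlignments()] or [truthToPairs()].
#' @param refs reference contigs ([Biostrings::DNAStringSet]) or named
#'   length vector.
#' @param r1,r2 optional mate sequences for the duplication ratio.
#' @param library_id library name for the report.
#' @param hi_frac,lo_frac depth-class thresholds.
#' @param weight_by_multiplicity when `TRUE`, each event contributes its
#'   insert size once per supporting read pair instead of once per unique
#'   event (default `FALSE`).
#' @param window_size,edge_exclusion stored in the per-contig depth
#'   profiles.
#' @return a [LibraryBiasReport-class].
#' @export
computeBiasReport <- function(pairs, refs, r1 = NULL, r2 = NULL,
                              library_id = "library",
                              hi_frac = 0.70, lo_frac = 0.30,
                              weight_by_multiplicity = FALSE,
                              window_size = 100, edge_exclusion = 200) {
  lens <- contigLengths(refs)
  sel <- selectBiasContigs(lens)
  dup <- if (!is.null(r1) && !is.null(r2)) {
    duplicationRatio(r1, r2)
  } else {
    list(pairs = NA_real_, reads = NA_real_)
  }
  if (sel$mode == "not estimable" || nrow(pairs) == 0L) {
    return(methods::new("LibraryBiasReport",
      library_id = library_id,
      dup_ratio = dup$pairs, dup_ratio_reads = dup$reads,
      cv_per_contig = stats::setNames(numeric(), character()),
      ks_distance = NA_real_, ks_pvalue = NA_real_,
      cohens_d = NA_real_, d_magnitude = "not estimable",
      mean_insert_high = NA_real_, mean_insert_low = NA_real_,
      n_high = 0L, n_low = 0L, mode_flag = "not estimable"))
  }
  keep <- pairs$contig_id %in% names(sel$selected)
  p <- pairs[keep, , drop = FALSE]
  events <- collapseEvents(p, refs)
  lab <- classifyEventDepth(events, hi_frac = hi_frac, lo_frac = lo_frac)
  sizes <- GenomicRanges::width(events)
  reps <- if (weight_by_multiplicity) {
    S4Vectors::mcols(events)$multiplicity
  } else {
    rep(1L, length(events))
  }
  high <- rep.int(sizes[lab == "high"], reps[lab == "high"])
  low <- rep.int(sizes[lab == "low"], reps[lab == "low"])
  test <- insertSizeBiasTest(high, low)
  cvs <- vapply(names(sel$selected), function(cid) {
    coverageCV(depthProfile(p, cid, sel$selected[[cid]],
                            window_size = window_size,
                            edge_exclusion = edge_exclusion))
  }, numeric(1))
  methods::new("LibraryBiasReport",
    library_id = library_id,
    dup_ratio = dup$pairs,
    dup_ratio_reads = dup$reads,
    cv_per_contig = cvs,
    ks_distance = test$ks_distance,
    ks_pvalue = test$ks_pvalue,
    cohens_d = test$cohens_d,
    d_magnitude = test$d_magnitude,
    mean_insert_high = test$mean_high,
    mean_insert_low = test$mean_low,
    n_high = as.integer(test$n_high),
    n_low = as.integer(test$n_low),
    mode_flag = sel$mode)
}
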
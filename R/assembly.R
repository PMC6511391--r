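#' Assembly contiguity summary
#'
#' Computes cumulative size, cumulative size of contigs >= 10 kb, contig
#' count, N50, N90 and largest contig. N50 is the minimal contig length among
#' the largest contigs that together make up 50% of total assembly size: the
#' length at which the descending cumulative sum first reaches half the
#' total; N90 analogous at 90%.
#'
#' @param lengths contig lengths in bp (any order; all > 0). An empty vector
#'   yields the defined-empty summary (all zeros).
#' @return an [AssemblySummary-class].
#' @examples
#' assemblySummary(c(10, 6, 4)) # N50 = 10, N90 = 4
#' @export
assemblySummary <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (!length(lengths)) {
    return(methods::new("AssemblySummary", total_bp = 0, total_bp_ge_10kb = 0,
                        n_contigs = 0L, n50 = 0, n90 = 0, largest = 0))
  }
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("contig lengths must all be > 0")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  total <- cum[length(cum)]
  methods::new("AssemblySummary",
    total_bp = total,
    total_bp_ge_10kb = sum(s[s >= 10000]),
    n_contigs = length(s),
    n50 = s[which(cum >= 0.5 * total)[1L]],
    n90 = s[which(cum >= 0.9 * total)[1L]],
    largest = s[1L])
}

#' Read contig lengths from FASTA or a two-column TSV
#'
#' @param path a FASTA file, or a headered TSV with columns `contig_id` and
#'   `length`.
#' @return named numeric vector of contig lengths.
#' @export
readContigLengths <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna")) {
    Biostrings::fasta.seqlengths(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("contig_id", "length") %in% names(tab)))
      stop("TSV must have columns contig_id and length")
    stats::setNames(as.numeric(tab$length), tab$contig_id)
  }
}

#' Compare an assembly metric between two pipelines
#'
#' Per-library fold change B/A, the median fold over finite values, a
#' two-sample Kolmogorov-Smirnov p-value on the two metric distributions and
#' Cohen's d (mean B minus mean A, pooled sd). Libraries with a zero A value
#' but positive B are reported as infinite folds and excluded from the
#' median; zero in both is excluded as undefined.
#'
#' @param a,b numeric metric per library (e.g. cumulative bp in long
#'   contigs); when both are named the names must match and `b` is
#'   reordered to `a`.
#' @return list: `fold_ratios`, `median_fold`, `n_infinite`, `n_undefined`,
#'   `ks_pvalue`, `cohens_d`, `d_magnitude`.
#' @examples
#' compareAssemblies(c(1, 2, 4), c(2, 4, 8))$median_fold # 2
#' @export
compareAssemblies <- function(a, b) {
  if (length(a) != length(b))
    stop("a and b must describe the same library set")
  if (length(a) < 3L)
    stop("need at least 3 libraries to compare")
  if (!is.null(names(a)) && !is.null(names(b))) {
    miss <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    if (length(miss))
      stop("mismatched library ids: ", paste(unique(miss), collapse = ", "))
    b <- b[names(a)]
  }
  fold <- ifelse(a == 0, ifelse(b > 0, Inf, NA_real_), b / a)
  finite <- fold[is.finite(fold)]
  ks <- suppressWarnings(stats::ks.test(b, a, exact = FALSE))
  d <- cohensD(b, a)
  list(
    fold_ratios = fold,
    median_fold = if (length(finite)) stats::median(finite) else NA_real_,
    n_infinite = sum(is.infinite(fold)),
    n_undefined = sum(is.na(fold)),
    ks_pvalue = unname(ks$p.value),
    cohens_d = d$d,
    d_magnitude = d$magnitude
  )
}

#' Fraction of partial genes
#'
#' A predicted gene is partial when its length is < 90% of its best database
#' hit's length (both in amino acids). Records are first filtered on the
#' best-hit quality (e-value <= `evalue_max` and score >= `score_min`), then
#' subsampled without replacement to at most `subsample_n` genes. The median
#' length ratio is reported alongside, with a warning flag when it strays
#' more than 0.1 from 1 (the ratio distribution is expected to be centered
#' around 1 for a sound reference database).
#'
#' @param records data.frame with columns `gene_len`, `ref_len`, `evalue`,
#'   `score`.
#' @param subsample_n subsample size (default 20000).
#' @param seed optional seed for the subsample; when `subsample_n >= n` no
#'   RNG is consumed and the result is seed-independent.
#' @param evalue_max,score_min best-hit filters (defaults 1e-5 and 100).
#' @param partial_below length-ratio threshold; partial iff ratio <
#'   `partial_below` (default 0.90, the boundary itself is complete).
#' @return list: `fraction`, `median_ratio`, `n_used`, `n_filtered_out`,
#'   `centered` (logical, `FALSE` triggers the off-center warning),
#'   `estimable`.
#' @export
partialGeneFraction <- function(records, subsample_n = 20000, seed = NULL,
                                evalue_max = 1e-5, score_min = 100,
                                partial_below = 0.90) {
  need <- c("gene_len", "ref_len", "evalue", "score")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!nrow(records))
    stop("records is empty")
  keep <- records$evalue <= evalue_max & records$score >= score_min
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) {
    return(list(fraction = NA_real_, median_ratio = NA_real_, n_used = 0L,
                n_filtered_out = sum(!keep), centered = NA,
                estimable = FALSE))
  }
  if (nrow(rec) > subsample_n) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    rec <- rec[sample.int(nrow(rec), subsample_n), , drop = FALSE]
  }
  ratio <- rec$gene_len / rec$ref_len
  med <- stats::median(ratio)
  centered <- abs(med - 1) <= 0.1
  if (!centered)
    warning("length-ratio distribution is not centered around 1 (median ",
            round(med, 3), ")")
  list(fraction = mean(ratio < partial_below),
       median_ratio = med,
       n_used = nrow(rec),
       n_filtered_out = sum(!keep),
       centered = centered,
       estimable = TRUE)
}
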
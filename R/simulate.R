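#' Construct a simulation configuration
#'
#' User-facing constructor for [SimConfig-class]. Defaults describe a small
#' but realistic low-input virome library: ten reference contigs of 10-15 kb,
#' 25,000 original insert molecules with 350 +/- 50 bp inserts, 50,000
#' sequenced read pairs of 2 x 151 bp, and a per-cycle amplification
#' efficiency of 0.9 that decays at 0.01/bp beyond a 200 bp pivot.
#'
#' @param n_contigs number of reference contigs.
#' @param contig_len length-2 numeric, min/max contig length in bp.
#' @param gc_target per-base probability of G or C.
#' @param n_molecules number of original insert molecules.
#' @param insert_mean,insert_sd insert-length distribution (bp).
#' @param pcr_cycles number of PCR cycles (0 = unamplified).
#' @param base_efficiency per-cycle efficiency `e0` of a short insert.
#' @param length_bias_rate decay rate `lambda` (per bp); 0 disables the
#'   length bias.
#' @param ref_insert_len pivot length `L0` (bp) below which efficiency does
#'   not decay.
#' @param n_reads number of read pairs sampled after amplification.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed; drives reference, inserts, sampling and errors
#'   through separate derived streams so each stage is reproducible in
#'   isolation.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(pcr_cycles = 20, seed = 1)
#' @export
SimConfig <- function(n_contigs = 10,
                      contig_len = c(10000, 15000),
                      gc_target = 0.5,
                      n_molecules = 25000,
                      insert_mean = 350,
                      insert_sd = 50,
                      pcr_cycles = 10,
                      base_efficiency = 0.9,
                      length_bias_rate = 0.01,
                      ref_insert_len = 200,
                      n_reads = 50000,
                      read_len = 151,
                      error_rate = 0.001,
                      seed = 1) {
  methods::new("SimConfig",
    n_contigs = as.integer(n_contigs),
    contig_len = as.integer(contig_len),
    gc_target = as.numeric(gc_target),
    n_molecules = as.integer(n_molecules),
    insert_mean = as.numeric(insert_mean),
    insert_sd = as.numeric(insert_sd),
    pcr_cycles = as.integer(pcr_cycles),
    base_efficiency = as.numeric(base_efficiency),
    length_bias_rate = as.numeric(length_bias_rate),
    ref_insert_len = as.numeric(ref_insert_len),
    n_reads = as.integer(n_reads),
    read_len = as.integer(read_len),
    error_rate = as.numeric(error_rate),
    seed = as.integer(seed)
  )
}

# one derived stream per simulator stage, so stages are independently
# reproducible: 1 = reference, 2 = inserts, 3 = sampling, 4 = errors
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage) %% 2147483629)
}

#' Per-cycle amplification efficiency and expected copy number
#'
#' `amplificationEfficiency()` evaluates
#' \eqn{e(L) = e_0 \exp(-\lambda \max(0, L - L_0))};
#' `expectedCopyNumber()` evaluates \eqn{(1 + e(L))^c}, the expected number
#' of copies of a length-`L` molecule after `c` PCR cycles.
#'
#' @param length insert length(s) in bp.
#' @param config a [SimConfig-class].
#' @return numeric vector, same length as `length`.
#' @examples
#' cfg <- SimConfig(pcr_cycles = 10, base_efficiency = 0.9,
#'                  length_bias_rate = 0.01, ref_insert_len = 200)
#' expectedCopyNumber(200, cfg) / expectedCopyNumber(400, cfg)
#' @export
amplificationEfficiency <- function(length, config) {
  config@base_efficiency *
    exp(-config@length_bias_rate * pmax(0, length - config@ref_insert_len))
}

#' @rdname amplificationEfficiency
#' @export
expectedCopyNumber <- function(length, config) {
  (1 + amplificationEfficiency(length, config))^config@pcr_cycles
}

#' Generate a random reference contig set
#'
#' Contig lengths are drawn uniformly from `config@contig_len`; bases are
#' i.i.d. with per-base G/C probability `config@gc_target` (split equally
#' between G and C, and between A and T).
#'
#' @param config a [SimConfig-class].
#' @return a named [Biostrings::DNAStringSet] of `n_contigs` sequences.
#' @examples
#' ref <- generateReference(SimConfig(n_contigs = 2, seed = 7))
#' @export
generateReference <- function(config) {
  methods::validObject(config)
  set.seed(stageSeed(config@seed, 1L))
  gc <- config@gc_target
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- config@contig_len[1L] +
    floor(runif(config@n_contigs) * (diff(config@contig_len) + 1))
  seqs <- vapply(lens, function(L) {
    paste0(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("contig_%03d", seq_len(config@n_contigs))
  out
}

#' Simulate the original (pre-PCR) insert molecules
#'
#' Each molecule picks a contig with probability proportional to contig
#' length, an insert length from a Normal(`insert_mean`, `insert_sd`)
#' truncated (by rejection) to `[2 * read_len, contig length]` and rounded,
#' and a uniform start among valid positions. The expected post-PCR copy
#' number (`weight`) is `(1 + e(L))^c` with the efficiency decay of
#' [amplificationEfficiency()].
#'
#' @param ref reference contigs ([Biostrings::DNAStringSet]).
#' @param config a [SimConfig-class].
#' @return data.frame with columns `contig_id`, `start` (0-based), `length`
#'   (bp) and `weight`.
#' @export
simulateInserts <- function(ref, config) {
  methods::validObject(config)
  if (length(ref) == 0L)
    stop("reference contig set is empty")
  set.seed(stageSeed(config@seed, 2L))
  clen <- Biostrings::width(ref)
  lo <- 2L * config@read_len
  if (all(clen < lo))
    stop("no contig can host the minimum insert length (", lo, " bp)")
  n <- config@n_molecules
  hostable <- clen >= lo
  ci <- sample(which(hostable), n, replace = TRUE, prob = clen[hostable])
  hi <- clen[ci]
  # truncated-normal insert lengths by rejection
  mass <- stats::pnorm(max(hi), config@insert_mean, config@insert_sd) -
    stats::pnorm(lo, config@insert_mean, config@insert_sd)
  if (mass < 1e-6)
    stop("insert-length bounds leave negligible probability mass")
  len <- as.integer(round(stats::rnorm(n, config@insert_mean, config@insert_sd)))
  bad <- which(len < lo | len > hi)
  while (length(bad)) {
    len[bad] <- as.integer(round(
      stats::rnorm(length(bad), config@insert_mean, config@insert_sd)))
    bad <- bad[len[bad] < lo | len[bad] > hi[bad]]
  }
  start <- as.integer(floor(runif(n) * (hi - len + 1)))
  data.frame(
    contig_id = names(ref)[ci],
    start = start,
    length = len,
    weight = expectedCopyNumber(len, config),
    stringsAsFactors = FALSE
  )
}

#' Sample read pairs from the amplified molecule pool
#'
#' Draws `config@n_reads` insert copies from a multinomial with category
#' probabilities proportional to each molecule's expected copy number.
#' Repeated draws of the same molecule are the exact-duplicate read pairs a
#' deduplicator would collapse.
#'
#' @param inserts data.frame from [simulateInserts()].
#' @param config a [SimConfig-class].
#' @return data.frame with one row per sampled copy: `insert_id` (row index
#'   into `inserts`), `copy_id` (1..multiplicity), `contig_id`, `start`,
#'   `insert_len`.
#' @export
amplifyAndSample <- function(inserts, config) {
  methods::validObject(config)
  if (nrow(inserts) == 0L || sum(inserts$weight) <= 0)
    stop("need at least one insert with positive weight")
  set.seed(stageSeed(config@seed, 3L))
  counts <- as.integer(stats::rmultinom(
    1L, config@n_reads, prob = inserts$weight))
  idx <- rep.int(seq_len(nrow(inserts)), counts)
  data.frame(
    insert_id = idx,
    copy_id = sequence(counts[counts > 0L]),
    contig_id = inserts$contig_id[idx],
    start = inserts$start[idx],
    insert_len = inserts$length[idx],
    stringsAsFactors = FALSE
  )
}

# substitute bases in place with per-base probability `rate`;
# replacement drawn uniformly from the three other bases
injectErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L)
    return(reads)
  w <- Biostrings::width(reads)
  nerr <- stats::rbinom(length(reads), w, rate)
  hit <- which(nerr > 0L)
  if (!length(hit))
    return(reads)
  bases <- c("A", "C", "G", "T")
  chars <- as.character(reads[hit])
  for (j in seq_along(hit)) {
    s <- chars[j]
    pos <- sample.int(w[hit[j]], nerr[hit[j]])
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, cur), 1L)
    }
    chars[j] <- s
  }
  reads[hit] <- Biostrings::DNAStringSet(chars)
  reads
}

# extract [start+1, start+width] substrings of ref, grouped by contig
extractSubseqs <- function(ref, contig_id, start, width) {
  cids <- unique(contig_id)
  chunks <- vector("list", length(cids))
  idx <- vector("list", length(cids))
  for (k in seq_along(cids)) {
    i <- which(contig_id == cids[k])
    idx[[k]] <- i
    chunks[[k]] <- Biostrings::extractAt(
      ref[[cids[k]]], IRanges::IRanges(start = start[i] + 1L,
                                       width = width[i]))
  }
  combined <- do.call(c, chunks)
  combined[order(unlist(idx))]
}

#' Render sampled insert copies as a paired-end FASTQ library
#'
#' Each sampled copy yields a forward read (first `read_len` bases of the
#' insert) and a reverse read (reverse complement of the last `read_len`
#' bases). Per-base substitution errors are applied at `config@error_rate`.
#' Copies shorter than `read_len` are skipped with a warning and counted.
#'
#' @param samples data.frame from [amplifyAndSample()].
#' @param ref reference contigs ([Biostrings::DNAStringSet]).
#' @param config a [SimConfig-class].
#' @param outdir optional directory; when given, writes `reads_R1.fastq`,
#'   `reads_R2.fastq`, `truth.tsv` and (if `write_sam`) `truth.sam`.
#' @param write_sam also emit a SAM rendering of the truth alignments.
#' @return list with elements `r1`, `r2` (named [Biostrings::DNAStringSet],
#'   synchronized order), `truth` (data.frame `contig_id`, `start`,
#'   `insert_len`, `copy_id`), `n_skipped`, and `paths` when `outdir` is
#'   given.
#' @export
renderLibrary <- function(samples, ref, config, outdir = NULL,
                          write_sam = FALSE) {
  methods::validObject(config)
  if (nrow(samples) == 0L)
    stop("no sampled insert copies to render")
  set.seed(stageSeed(config@seed, 4L))
  rl <- config@read_len
  keep <- samples$insert_len >= rl
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " sampled copies shorter than read_len were skipped")
    samples <- samples[keep, , drop = FALSE]
  }
  fwd <- extractSubseqs(ref, samples$contig_id, samples$start,
                        rep.int(rl, nrow(samples)))
  rev_start <- samples$start + samples$insert_len - rl
  rev <- Biostrings::reverseComplement(
    extractSubseqs(ref, samples$contig_id, rev_start,
                   rep.int(rl, nrow(samples))))
  fwd <- injectErrors(fwd, config@error_rate)
  rev <- injectErrors(rev, config@error_rate)
  ids <- sprintf("pair_%06d", seq_len(nrow(samples)))
  names(fwd) <- ids
  names(rev) <- ids
  truth <- data.frame(
    contig_id = samples$contig_id,
    start = samples$start,
    insert_len = samples$insert_len,
    copy_id = samples$copy_id,
    stringsAsFactors = FALSE
  )
  out <- list(r1 = fwd, r2 = rev, truth = truth, n_skipped = n_skipped)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      r1 = file.path(outdir, "reads_R1.fastq"),
      r2 = file.path(outdir, "reads_R2.fastq"),
      truth = file.path(outdir, "truth.tsv")
    )
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(fwd)))
    Biostrings::writeXStringSet(fwd, paths[["r1"]], format = "fastq",
                                qualities = qual)
    Biostrings::writeXStringSet(rev, paths[["r2"]], format = "fastq",
                                qualities = qual)
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (write_sam) {
      paths[["sam"]] <- file.path(outdir, "truth.sam")
      writeTruthSam(samples, fwd, rev, ref, config, paths[["sam"]])
    }
    out$paths <- paths
  }
  out
}

# minimal SAM rendering of the truth alignments: two records per pair,
# proper-pair flags (99/147), TLEN signed by leftmost convention
writeTruthSam <- function(samples, fwd, rev, ref, config, path) {
  rl <- config@read_len
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref), Biostrings::width(ref))
  )
  qual <- strrep("I", rl)
  cigar <- sprintf("%dM", rl)
  pos1 <- samples$start + 1L
  pos2 <- samples$start + samples$insert_len - rl + 1L
  qname <- names(fwd)
  rec1 <- paste(qname, 99L, samples$contig_id, pos1, 60L, cigar, "=", pos2,
                samples$insert_len, as.character(fwd), qual, sep = "\t")
  # SAM stores the forward-strand sequence for reverse-strand reads
  rec2 <- paste(qname, 147L, samples$contig_id, pos2, 60L, cigar, "=", pos1,
                -samples$insert_len,
                as.character(Biostrings::reverseComplement(rev)), qual,
                sep = "\t")
  recs <- character(2L * length(rec1))
  recs[c(TRUE, FALSE)] <- rec1
  recs[c(FALSE, TRUE)] <- rec2
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Run the full library simulation
#'
#' Convenience wrapper running reference generation, molecule simulation,
#' amplification + multinomial read sampling, and FASTQ rendering in order,
#' each stage on its own derived RNG stream. Identical `config` (including
#' `seed`) gives byte-identical outputs.
#'
#' @param config a [SimConfig-class].
#' @param outdir,write_sam passed to [renderLibrary()]; when `outdir` is
#'   given the reference is also written as `reference.fasta`.
#' @return list: `config`, `reference`, `inserts`, `samples`, plus the
#'   elements of [renderLibrary()]'s result.
#' @examples
#' lib <- simulateLibrary(SimConfig(n_molecules = 500, n_reads = 1000,
#'                                  n_contigs = 2, seed = 3))
#' @export
simulateLibrary <- function(config, outdir = NULL, write_sam = FALSE) {
  ref <- generateReference(config)
  inserts <- simulateInserts(ref, config)
  samples <- amplifyAndSample(inserts, config)
  lib <- renderLibrary(samples, ref, config, outdir = outdir,
                       write_sam = write_sam)
  if (!is.null(outdir)) {
    fa <- file.path(outdir, "reference.fasta")
    Biostrings::writeXStringSet(ref, fa)
    lib$paths <- c(lib$paths, reference = fa)
  }
  c(list(config = config, reference = ref, inserts = inserts,
         samples = samples), lib)
}

#' Expand a truth table into read-pair alignments
#'
#' Converts the simulator's ground-truth table (one row per sampled insert
#' copy) into the read-pair alignment layout used by [collapseEvents()] and
#' [depthProfile()], deriving the two mate positions from the insert
#' coordinates.
#'
#' @param truth data.frame with `contig_id`, `start`, `insert_len`.
#' @param read_len read length in bp.
#' @return data.frame with columns `contig_id`, `start`, `insert_len`,
#'   `mate1_start`, `mate2_start`, `read_len` (all coordinates 0-based).
#' @export
truthToPairs <- function(truth, read_len) {
  data.frame(
    contig_id = truth$contig_id,
    start = as.integer(truth$start),
    insert_len = as.integer(truth$insert_len),
    mate1_start = as.integer(truth$start),
    mate2_start = as.integer(truth$start + truth$insert_len - read_len),
    read_len = as.integer(read_len),
    stringsAsFactors = FALSE
  )
}
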
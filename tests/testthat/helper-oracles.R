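# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and first-principles definitions only.

# per-base depth by explicit position counting over both mates
naiveDepth <- function(pairs, contig_id, contig_length) {
  depth <- integer(contig_length)
  p <- pairs[pairs$contig_id == contig_id, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    for (s in c(p$mate1_start[i], p$mate2_start[i])) {
      pos <- (s + 1):(s + p$read_len[i])
      pos <- pos[pos >= 1 & pos <= contig_length]
      depth[pos] <- depth[pos] + 1L
    }
  }
  depth
}

# max |ECDF_x - ECDF_y| by enumeration over all observed values
bruteKS <- function(x, y) {
  v <- sort(unique(c(x, y)))
  d <- 0
  for (t in v) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# pair duplication ratio by O(n^2) pairwise sequence comparison
bruteDupRatio <- function(r1, r2) {
  n <- length(r1)
  distinct <- 0L
  for (i in seq_len(n)) {
    new <- TRUE
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        if (r1[i] == r1[j] && r2[i] == r2[j]) {
          new <- FALSE
          break
        }
      }
    }
    if (new) distinct <- distinct + 1L
  }
  1 - distinct / n
}

# N50/N90 and totals by sort + scan
bruteAssemblySummary <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  cum <- 0
  n50 <- NA
  n90 <- NA
  for (L in s) {
    cum <- cum + L
    if (is.na(n50) && cum >= 0.5 * total) n50 <- L
    if (is.na(n90) && cum >= 0.9 * total) n90 <- L
  }
  list(total_bp = total, total_bp_ge_10kb = sum(s[s >= 10000]),
       n_contigs = length(s), n50 = n50, n90 = n90, largest = s[1])
}

# small, fast simulation settings for unit tests (any field overridable)
tinyConfig <- function(...) {
  defaults <- list(n_contigs = 3, contig_len = c(4000, 6000),
                   n_molecules = 1500, n_reads = 3000, insert_mean = 300,
                   insert_sd = 40, read_len = 100, error_rate = 0,
                   seed = 11)
  do.call(SimConfig, utils::modifyList(defaults, list(...)))
}

# random read-pair table on synthetic contigs, for depth-oracle checks
randomPairs <- function(n, contig_ids, contig_len, read_len = 50) {
  cid <- sample(contig_ids, n, replace = TRUE)
  ins <- sample(seq(2 * read_len, 400), n, replace = TRUE)
  start <- vapply(ins, function(l) sample.int(contig_len - l + 1, 1) - 1L,
                  integer(1))
  data.frame(contig_id = cid, start = start, insert_len = ins,
             mate1_start = start, mate2_start = start + ins - read_len,
             read_len = read_len, stringsAsFactors = FALSE)
}
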
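# AmpBias

Diagnostics for PCR amplification bias in low-input metagenomes.

## The problem

Metagenomes built from nanogram to sub-nanogram DNA inputs (viromes,
flow-sorted mini-metagenomes, low-biomass samples) need several rounds of PCR
after adapter ligation. PCR amplifies short inserts preferentially, so with
every cycle short fragments take up a larger share of the read pool. The
consequences are visible directly in the mapped reads:

* a large fraction of read pairs are **exact duplicates** of each other;
* **read depth along each contig becomes uneven**, with high-depth regions
  enriched in short inserts;
* standard metagenome assemblers, which lean on even coverage, produce
  smaller and more fragmented assemblies.

AmpBias quantifies this bias for a library, and ships a forward simulator of
the mechanism so every statistic can be verified against ground truth without
any real sequencing data.

## The statistics

For one library mapped to a set of reference contigs, AmpBias works on
**unique insert-mapping events**: distinct combinations of contig, mapping
start coordinate and insert size. An event's *multiplicity* is the number of
read pairs sharing that exact mapping. Contigs enter the analysis when those
≥ 10 kb total ≥ 50 kb, otherwise all contigs ≥ 2 kb are used. Per library it
reports:

* **duplication ratio** — `1 − distinct pairs / input pairs`, with pair
  identity the ordered tuple of exact mate sequences;
* **coefficient of variation of coverage** — per contig,
  `100 · sd(depth) / mean(depth)` over per-base read depth;
* **insert-size bias** — events at ≥ 70% of their contig's maximum depth are
  *high depth*, events at ≤ 30% are *low depth*; the two insert-size
  distributions are compared with the two-sample Kolmogorov–Smirnov distance
  *D* and Cohen's *d* = (mean_high − mean_low) / pooled sd. Negative *d*
  means high-depth regions hold shorter inserts — the PCR-bias signature;
* **assembly contiguity** — totals, cumulative bp in contigs ≥ 10 kb, N50,
  N90, largest contig; plus cross-pipeline comparison (fold ratios, KS,
  Cohen's *d*) and the fraction of predicted genes < 90% of their best hit's
  length;
* **misassembly rate** — relocations and inversions between assembled
  contigs and a reference, per bp of contigs ≥ 1 kb (translocations counted
  but excluded from the rate).

The simulator draws insert molecules from reference contigs, amplifies each
molecule of length *L* to an expected copy number `(1 + e(L))^c` over *c*
cycles with efficiency `e(L) = e0 · exp(−λ · max(0, L − L0))`, then samples
read pairs multinomially — reproducing both the duplicate structure and the
short-insert enrichment.

## Worked example

```r
library(AmpBias)

cfg <- SimConfig(pcr_cycles = 20, seed = 42)   # 50,000 pairs, 2 x 151 bp
lib <- simulateLibrary(cfg)
pairs <- truthToPairs(lib$truth, cfg@read_len)
computeBiasReport(pairs, lib$reference, r1 = lib$r1, r2 = lib$r2,
                  library_id = "sim_20cycles")
```

```
LibraryBiasReport for sim_20cycles (contig selection: ge10kb)
  duplication ratio: 0.459 (pairs), 0.579 (reads)
  coverage CV: mean 24.7% over 10 contig(s)
  insert-size bias: KS D = 0.931 (p = 0.00e+00), Cohen's d = -1.709 (large)
  events: 246 high depth (mean insert 305.9 bp), 12813 low (355.4 bp)
```

After 20 cycles, 46% of pairs are exact duplicates and the insert-size
distributions of high- and low-depth regions are nearly disjoint (KS D =
0.93) with a large negative effect size: high-depth events carry inserts
~50 bp shorter on average. Rerunning with `pcr_cycles = 0` gives KS D ≈ 0.04
and a negligible *d* — no false signal without amplification. Contiguity of
any contig set:

```r
assemblySummary(Biostrings::width(lib$reference))
#> AssemblySummary: 10 contigs, 126,283 bp total (126,283 bp in >= 10 kb)
#>   N50 = 12,715, N90 = 10,915, largest = 14,554 bp
```

`runReport()` runs the whole chain on files (FASTA + SAM/BAM + optional
FASTQ/gene-table/PAF) and writes a versioned JSON report, including a
configurable recommendation flag (`dedup_single_cell_advised`) that fires
when duplication ≥ 0.25 and Cohen's *d* ≤ −0.2 — the regime where read
deduplication plus a single-cell assembler pays off. A thin CLI over the same
functions lives at `inst/scripts/ampbias-cli.R` (subcommands `simulate`,
`bias`, `asm-stats`, `genes`, `misassembly`, `report`).

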
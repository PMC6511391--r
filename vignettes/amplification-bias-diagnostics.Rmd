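---
title: "Quantifying PCR amplification bias in low-input metagenomes"
author: "AmpBias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PCR amplification bias in low-input metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AmpBias)
```

## Why these diagnostics

Sequencing libraries built from nanogram or sub-nanogram DNA (virus
fractions, flow-sorted cell pools, low-biomass samples) require PCR
amplification — often 9 to 25 cycles — between adapter ligation and
sequencing. PCR does not treat all fragments equally: shorter inserts
amplify more efficiently, so each cycle shifts the read pool toward short
fragments. When such a library is mapped back to assembled contigs, the bias
shows up as exact-duplicate read pairs, uneven depth of coverage along each
contig, and an enrichment of short inserts exactly where depth is highest.
Standard metagenome assemblers interpret depth as abundance signal, so this
unevenness degrades assembly.

AmpBias measures the bias from paired-end alignments, and ships a forward
simulator of the mechanism so that every statistic can be validated against
a known ground truth. This vignette documents the model, the parameter
choices, the numerical conventions, and what the simulation-based tests do
and do not establish about real libraries.

## The amplification model

The simulator represents a library as `n_molecules` original insert
molecules drawn from a set of reference contigs. A molecule picks its contig
with probability proportional to contig length, a length from
Normal(`insert_mean`, `insert_sd`) truncated to
`[2 * read_len, contig length]`, and a uniform start among valid positions.
After `c` PCR cycles a molecule of length `L` has expected copy number

$$ w(L) = \bigl(1 + e(L)\bigr)^{c}, \qquad
   e(L) = e_0 \exp\bigl(-\lambda \max(0,\, L - L_0)\bigr), $$

and the sequencer draws `n_reads` pairs from a multinomial with
probabilities proportional to the weights. Repeated draws of the same
molecule are the exact-duplicate pairs a deduplicator would collapse.

The exponential decay `e(L)` is a deliberate modeling choice: per-cycle PCR
efficiency is known to fall with amplicon length, and a single-parameter
exponential beyond a pivot `L_0` is the simplest monotone form that (i)
reduces to unbiased amplification at `λ = 0`, (ii) leaves short fragments at
the full efficiency `e_0`, and (iii) produces the short-insert enrichment
observed in real PCR-amplified libraries. We track *expected* copy numbers
deterministically and leave all stochasticity to the final multinomial
draw, rather than branching every molecule per cycle: memory stays linear in
the number of molecules and the duplicate structure of the sampled pool is
the same.

Two further conventions: insert lengths are truncated below at
`2 * read_len` so mates never read past each other (degenerate template
lengths would otherwise need special-casing throughout), and the four
simulation stages (reference → molecules → sampling → errors) run on
separate streams derived from one seed, so each stage is reproducible in
isolation.

### Default study conditions

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_contigs`, `contig_len` | 10 of 10–15 | kb | all contigs pass the 10 kb selection rule and total > 50 kb |
| `gc_target` | 0.5 | fraction | bias under study is length-driven, not GC-driven |
| `n_molecules` | 25,000 | molecules | see below |
| `insert_mean`, `insert_sd` | 350 ± 50 | bp | conventional short-insert Illumina library |
| `n_reads`, `read_len` | 50,000 of 2×151 | pairs, bp | typical HiSeq read length; enough events per contig |
| `e0` | 0.9 | per cycle | efficient PCR on short fragments |
| `λ` | 0.01 | per bp | spreads weights ~10-fold across 350 ± 100 bp at one cycle^20 |
| `L0` | 200 | bp | fragments at or below the read footprint amplify at full efficiency |
| `pcr_cycles` | 0–20 | cycles | the range used for low-input viromes |
| `error_rate` | 0.001 | per base | Illumina-like substitution rate |

The ratio `n_reads / n_molecules = 2` sets the mean event multiplicity near
2. This matters: the high/low depth classes are defined *relative to each
contig's maximum multiplicity*, so if multiplicities were almost all 1 (many
molecules, few reads) the low-depth class would be empty and the bias test
not estimable; if they were very large and tightly concentrated, the class
tails would starve instead. A mean around 2 keeps both classes populated
with hundreds to thousands of events at 50,000 pairs, which is what makes
the null configuration (`λ = 0`) testable at all.

## From alignments to statistics

**Ingest.** SAM/BAM files are read through Rsamtools; only properly paired,
primary alignments are kept, one record per pair (the leftmost mate,
TLEN > 0). The insert is the template span |TLEN| — the only portable
definition across mappers. Pairs with TLEN = 0 or mates on different contigs
are dropped and counted. SAM's 1-based positions become 0-based internally;
all intervals are half-open. Multi-mapping is assumed resolved upstream by
the mapper (e.g. random assignment); ingest does not re-randomize. Duplicate
pairs are *kept* at ingest — deduplication enters only as an explicit
statistic.

**Unique insert events.** Pairs collapse into events keyed on
(contig, start, insert length); the multiplicity of an event counts its
supporting pairs and always sums back to the number of usable pairs. The GC
fraction of the reference span is carried along for descriptive purposes
only: we deliberately do not model or correct GC effects, since the bias
under study is not a systematic GC bias.

**Depth.** Per-base depth counts aligned read bases: both mates contribute
`read_len` bases each and the unsequenced gap between them does not count
(an insert-span mode exists for sensitivity analysis). The windowed view
averages non-overlapping 100 bp tiles and discards tiles intersecting the
first or last 200 bp of a contig, where depth estimates are unreliable;
tiles rather than sliding windows keep the view deterministic and
non-redundant. The coefficient of variation, however, is computed on the
full per-base vector without edge exclusion — the edge rule is a display
convention for windowed plots, not part of the CV definition. CV uses the
sample (n−1) standard deviation, matching the defaults of the statistical
environments these analyses are usually run in, and is undefined (reported
missing) for contigs with zero mean depth.

**Contig selection.** Per library, the bias is estimated on all contigs
≥ 10 kb when these total ≥ 50 kb, otherwise on all contigs ≥ 2 kb, otherwise
flagged "not estimable" — libraries assembling only fragments below 2 kb
simply do not support the estimate.

**High/low classes and the bias test.** Within each contig, events at
≥ 70% of the contig's maximum depth are high-depth, ≤ 30% low-depth
(thresholds inclusive, configurable). "Depth" of an event here is its
multiplicity. A per-base reading (mean depth across the insert span) is
exposed via the `event_depth` argument of `classifyEventDepth()`; the
multiplicity reading is the default because it is self-contained in the
event table and the two agree on direction in simulation. Each unique event
contributes its insert size once; a multiplicity-weighted mode is available
(`weight_by_multiplicity`), which skews both distributions toward
high-multiplicity events and is off by default. The two insert-size
distributions are compared with the two-sample Kolmogorov–Smirnov statistic
(asymptotic two-sided p-value; the exact method buys nothing at thousands of
events) and Cohen's d with (n−1)-weighted pooled standard deviation, signed
high minus low so that preferential amplification of short inserts gives
d < 0. Magnitude bands at |d| = 0.2/0.5/0.8 follow the usual convention.

**Duplication ratio.** A pair's identity is the ordered tuple of its exact
mate sequences — no substitutions tolerated, no reverse-complement
canonicalization, matching strict exact-match deduplication. The ratio is
reported per pair (primary) and per mate pool; with whole-pair
deduplication the two differ only when single mates recur across different
partners. Note the simulator's sequencing errors *reduce* the measurable
ratio below the true sampling-duplicate rate, exactly as in real data.

**Normalization and cross-library agreement.** Contig coverage is
normalized per Gbp of library (the scale is cosmetic for correlations).
Agreement between two libraries over the same contigs reports Pearson r² and
Spearman ρ on contigs covered in both (at least 3 required), the fraction
of contigs detected (≥ 1 mapped read), and the fraction at ≥ 5× mean depth.

## Assembly metrics and misassemblies

N50 (N90) is the minimal contig length among the largest contigs that
together reach 50% (90%) of total assembly size — computed by descending
sort and cumulative sum, with ties resolved by reporting the
threshold-crossing length itself. Cross-pipeline comparison reports
per-library fold ratios (zero baselines yield infinite folds, which are
counted separately and excluded from the median rather than clamped — real
comparisons do produce near-zero baselines), a KS p-value and Cohen's d. The
partial-gene fraction keeps best hits at e-value ≤ 1e−5 and score ≥ 100,
subsamples to 20,000 genes *after* filtering (the filter defines which genes
have a usable reference length at all), and calls a gene partial when
gene/reference length < 0.90 — the 0.90 boundary itself is complete. Gene
and reference lengths are both in amino acids. The median length ratio is
reported with a warning flag when it strays more than 0.1 from 1.

The misassembly classifier takes contig-to-reference segment alignments
(PAF or TSV; it never aligns sequences itself) and inspects adjacent
segments along each query: different reference contigs → translocation; same
reference, opposite strands → inversion; same reference and strand with the
reference gap differing from the query gap by more than 1,000 bp (the
conventional "extensive misassembly" distance) → relocation. Segments
shorter than 65 bp are dropped, and adjacent segments overlapping by more
than 50 bp on the query (beyond aligner trimming slack) are skipped with a
warning; all three constants are configurable. The rate divides relocations
plus inversions by the cumulative length of contigs ≥ 1 kb. Translocations
are excluded from the rate because when the "reference" is itself a
metagenome assembly, a query spanning two reference contigs may mean both
assemblies are correct and merely overlap.

## The recommendation rule

`runReport()` emits a single flag, `dedup_single_cell_advised`, set when the
duplication ratio is ≥ 0.25 and Cohen's d ≤ −0.2. Heavily duplicated
libraries with a short-insert enrichment in high-depth regions are the
regime where exact-match read deduplication followed by an assembler
designed for uneven coverage (single-cell mode) outperforms a standard
metagenome pipeline. The thresholds sit at the bottom of the duplication
range where the effect is material and at the edge of a non-negligible
effect size; both are configurable, and the raw statistics are always
printed next to the flag so the rule never hides the evidence.

## Numerical and degenerate-input conventions

* All coordinates 0-based half-open internally; SAM positions converted on
  ingest; GRanges views are 1-based as usual for Bioconductor.
* KS distances are exact max-ECDF differences (ties handled by `ks.test`'s
  statistic); the test suite checks them against brute-force enumeration to
  1e−12.
* Cohen's d with a zero pooled sd is 0 when the means agree and signed
  infinite otherwise; samples with fewer than 2 values make d
  "not estimable".
* Empty contig-length input yields the defined-empty assembly summary; zero
  mean depth yields a missing CV; an empty high or low class makes the bias
  test "not estimable" rather than an error.
* `partialGeneFraction()` with `subsample_n >= n` consumes no randomness and
  restores the caller's RNG state when it does subsample.
* Event collapse is idempotent, and expanding unit-multiplicity events back
  to pairs reproduces the event table.

## What the simulation does and does not establish

The simulator reproduces the *mechanism* — length-biased amplification,
exact-duplicate pairs, depth unevenness localized at short-insert loci — and
the test suite verifies the direction and null behavior of every statistic
against it: duplication ratio and KS distance non-decreasing over cycles
0–20, Cohen's d negative from 10 cycles on, mean CV strictly higher at 20
cycles than at 0, and no false signal (KS < 0.05, |d| < 0.2) when `λ = 0`.
At the default scale the null KS distance is sampling-limited at roughly
`0.87 / sqrt(n_high)` with a few hundred high-depth events, so it hovers
near 0.04; the null check is run at a fixed seed.

Real libraries differ in ways the simulator does not attempt: fragmentation
is not Gaussian and is itself length-biased by size selection; amplification
efficiency varies per cycle and per sequence (GC, secondary structure)
rather than following one smooth curve; polymerase errors propagate through
cycles instead of appearing only at readout; quality scores, indels,
chimeras and optical duplicates are absent; and communities have uneven
taxon abundances where our contigs are sampled uniformly by length. Passing
the simulation tests therefore establishes that the statistics measure what
they claim and respond in the right direction at realistic magnitudes — not
that any particular real library will show a particular value.

Problem sizes were chosen so the full suite runs in well under a minute per
module: oracle equivalences use 200 random assemblies, 50 alignment sets,
100 KS sample pairs and up to 500 read pairs; the cycle sweep uses five
libraries of 50,000 pairs each.

## Session info

```{r}
sessionInfo()
```
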
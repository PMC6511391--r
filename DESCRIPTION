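Package: AmpBias
Title: Diagnostics for PCR Amplification Bias in Low-Input Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the coverage unevenness that PCR amplification of
    low-input (nanogram to sub-nanogram) metagenomic libraries introduces
    through preferential amplification of short inserts. Provides a forward
    simulator of PCR-amplified paired-end libraries with ground truth, ingest
    of paired-end alignments into unique insert-mapping events and per-base
    depth profiles, per-library bias diagnostics (duplication ratio,
    coefficient of variation of coverage, Kolmogorov-Smirnov distance and
    Cohen's d between insert-size distributions of high- versus low-depth
    regions), assembly contiguity metrics (N50/N90, cumulative sizes),
    cross-pipeline comparison statistics, a partial-gene fraction estimator,
    and a simplified misassembly classifier (relocations, inversions,
    translocations) with a per-bp error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
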
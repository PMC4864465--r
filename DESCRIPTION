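Package: telofuse
Title: Detection and Mutational Profiling of Telomere Fusion Events from
    Paired-End Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for single-molecule telomere fusion sequencing analysis.
    Models custom subtelomeric references with landmark coordinates (fusion
    primer, telomere-repeat start, optional nuclease cleavage site), simulates
    fusion amplicons and paired-end reads with known junction architecture,
    detects inter-chromosomal (telomere-genomic) and intra-chromosomal
    (head-to-head sister chromatid) fusion events from discordant read pairs,
    resolves fusion junctions at base-pair resolution from soft-clipped reads,
    scores microhomology, templated and untemplated insertions, resection and
    nuclease-footprint proximity, and computes population statistics: fusion
    frequency per diploid genome, inter:intra read ratios, binned subtelomere
    profiles and chromatid asymmetry classes, gene-overlap chi-square tests,
    permutation-based feature proximity tests, junction-proximal GC content
    and Welch t comparisons of strand-specific error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer
Config/testthat/edition: 3
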
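Package: snpcontig
Title: BAC Contig Building for Homoeologous Regions via Intergenomic SNP
    Screening of Multidimensional Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for establishing bacterial artificial chromosome (BAC)
    contigs of homoeologous regions in an allopolyploid genome using
    intergenomic single nucleotide polymorphisms (SNPs). Covers assay design
    from progenitor-genome alignments (high-scoring segment pair filtering,
    genome-survey-sequence contig assembly, flanking-sequence constraints),
    threshold-based calling of multiplexed two-channel genotyping signals on
    multidimensional BAC pools, group-testing deconvolution of positive pools
    into clone coordinates, subgenome assignment of assay nucleotides and
    clones, rule-based clone selection, and contig assembly with false-call
    resolution and contig bridging. A synthetic-data module simulates diverged
    progenitor regions, an amphidiploid, a pooled clone library and noisy pool
    signals with full ground truth, so the whole pipeline can be exercised and
    calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
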
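Package: homeosort
Title: Bisulfite-Aware Subgenome Read Classification for Allopolyploid WGBS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype-free sorting of whole-genome bisulfite sequencing (WGBS)
    reads from an allopolyploid into its two parental subgenomes. Each read is
    aligned to both progenitor assemblies and the two placements are compared
    under a base-quality-driven, bisulfite-aware likelihood in which C-to-T
    (and G-to-A on the opposite conversion strand) substitutions are scored as
    matches, so that bisulfite conversion never penalises a correct placement.
    The package also provides per-cytosine methylation extraction in CG, CHG
    and CHH contexts, a bisulfite conversion-efficiency estimator based on an
    unmethylated control genome, an evaluation harness that benchmarks the
    classifier against the genome-concatenation baseline on reads of known
    parental origin, overlap of significant differentially methylated regions
    with gene annotations, and a seeded WGBS read simulator producing
    truth-labelled fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
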
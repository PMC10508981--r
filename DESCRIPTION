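Package: retrotether
Title: Mining and Classification of LTR Retrotransposons Carrying an
    Additional Ribonuclease H Domain
Version: 0.1.0
Authors@R:
    person("Retrotether", "Developers", email = "retrotether@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully deterministic pipeline for studying Ty3/gypsy
    LTR retrotransposons that acquired an additional archaeal-type ribonuclease
    H (aRH) domain. Simulates genomes with planted elements of known structure
    and ground truth; recovers elements by position-specific scoring matrix
    (PSSM) scanning of six-frame translations, hit chaining, and seeded long
    terminal repeat detection; classifies elements into five structural
    variants by aRH placement and ORF membership; scores tether-like
    degradation of the DEDD catalytic core of the native RH domain; builds
    neighbor-joining trees with Felsenstein bootstrap support, tests clade
    monophyly, applies a two-of-three lineage credibility filter; and
    reconstructs minimal structural-rearrangement scenarios on a species tree
    by Fitch parsimony.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    withr,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
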
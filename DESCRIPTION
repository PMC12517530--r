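Package: MusicDNA
Title: Bidirectional Inheritance Between DNA Genotype and Musical Phenotype
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An artificial inheritance system in which synthetic DNA serves
    as genotype and a monophonic musical score as phenotype. A redundant
    genetic code of 256 four-letter codons encodes 64 note/duration
    elements, so information can flow in both directions: translation
    (DNA to music) and reverse translation (music to DNA) with random
    synonymous codon assignment and no codon memory across generations.
    The package provides the code-table machinery, the bidirectional
    codec with homopolymer recoding, six mutational regimes for
    multi-generation simulations of mutational load, Needleman-Wunsch
    global alignment of musical scores with a bespoke scoring scheme,
    needle-style global DNA alignment, square-wave audio rendering with a
    parameterised noisy-capture channel, and a selection experiment
    contrasting purifying and neutral selection over rounds of evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Alignment, SequenceMatching, Genetics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
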
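Package: stopflux
Title: Stop Codon Flux, Mutational Equilibria and GC-Biased Gene Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting GC-biased gene conversion acting on stop
    codons and trinucleotides. Infers stop-codon substitution flux from
    species trios by maximum-likelihood ancestral state reconstruction,
    computes the equilibrium TGA share (pTGA) implied by TAA/TGA flux with
    bootstrap uncertainty and Monte-Carlo null significance, derives mono-
    and dinucleotide mutational-equilibrium frequencies from de novo
    mutation spectra, simulates Markov null sequences to obtain expected
    trinucleotide frequencies, and quantifies the GC-coupled fixation
    "boost" of each trinucleotide in GC-rich versus GC-poor sequence.
    Includes a fully parameterised synthetic-data generator (isochore
    genomes, trio alignments with a tunable AT-to-GC fixation bias, de novo
    mutation tables, GC-correlated recombination maps, protein abundances)
    so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    GenomicRanges,
    Matrix,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
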
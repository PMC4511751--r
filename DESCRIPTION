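Package: bittersweep
Title: Population Genetics of a Locally Private Bitter-Taste Receptor Allele
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a population-private allele rose to
    high frequency too fast, and stayed too local, to be neutral. Implements
    nucleotide diversity, Watterson's theta and Tajima's D with a coalescent
    null, Hudson F_ST and island-model Nm migration estimates, haplotype
    sharing spectra, median-joining haplotype networks with a four-gamete
    recombination scan, a Poisson star-phylogeny upper bound on haplotype
    age, a forward Wright-Fisher drift-plus-emigration simulator of allele
    expansion and "allele privacy", Nei-Gojobori synonymous/nonsynonymous
    site accounting, and four-parameter logistic fits for calcium-imaging
    titrations and two-bottle preference assays. Includes coalescent,
    island-model, star-phylogeny and dose-response synthetic data
    generators so every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
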
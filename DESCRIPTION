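Package: ace1kit
Title: Target-Site Carbamate Resistance Analysis at the Anopheles Ace-1 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for target-site insecticide resistance studies at
    the acetylcholinesterase-1 (Ace-1) locus of Anopheles mosquitoes.  Provides
    genotype-phenotype association statistics (odds ratios with Woolf
    confidence intervals, Fisher exact tests, Hardy-Weinberg exact tests, WHO
    bioassay classification), sequence polymorphism and neutrality statistics
    (haplotype and nucleotide diversity, Watterson's estimator, Tajima's D,
    Fu and Li's D*, Fu's Fs with a coalescent null), statistical-parsimony
    haplotype networks, Tamura 3-parameter distances with neighbor-joining
    trees, duplication calling from cloned amplicon haplotypes, and a seeded
    synthetic-study generator emulating a selective sweep on the resistant
    G119S background.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
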
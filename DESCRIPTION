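Package: xxdsdmap
Title: Mapping an Autosomal Insertion Underlying Canine XX Disorder of Sex
    Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-stage inference pipeline for localizing a recessive
    autosomal insertion associated with SRY-negative XX disorder of sex
    development (XX DSD) in the dog. Implements Mendelian
    segregation-pattern variant filtering of multi-sample genotypes,
    sliding-window variant-density enrichment scanning,
    homozygosity/haplotype-block mapping with breed-sharing summaries,
    candidate-locus cohort association under genetic models with
    Bonferroni and Benjamini-Hochberg control, a penalized
    quasi-likelihood logistic mixed model with genetic relationship
    matrix and genotype principal components plus per-variant score
    tests, segregation-distortion (embryonic lethality) chi-squared
    testing of breeding-cross outcomes, and a stringent FPKM
    fold-change differential-expression filter with genomic binning and
    pathway summaries. A forward pedigree/cohort/expression simulator
    with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
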
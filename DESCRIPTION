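Package: kbsa
Title: Bulked Segregant Analysis of k-mers for Trait Mapping in
    Heterozygous Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference-free trait mapping for unphased heterozygous diploid
    crosses by bulked segregant analysis of k-mer counts. Counts canonical
    k-mers per sample, aggregates them into phenotypic bulks, and tests each
    k-mer for differential abundance between bulks with a nested-Poisson
    log-likelihood-ratio test followed by Bonferroni correction and a fold
    change gate. Enriched k-mers are assigned a parental origin by
    presence/absence in parental read sets, localized on a reference genome
    by backtracking to source reads and binned read dosage, and used to
    pseudo-phase the causal parent's haplotypes from bulk allele
    frequencies. Includes a pedigree and short-read simulator for
    four-haplotype F2 intercross designs, a closed-form calculator for
    expected within-bulk haplotype frequencies under dominant or recessive
    single-locus models, and a conventional parental-SNP binned genotyping
    and association-scan comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    methods,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
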
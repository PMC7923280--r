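Package: alpacapanel
Title: SNP Microarray Panel Design and Validation for the Alpaca Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and validate a medium-density SNP genotyping
    microarray from genotyping-by-sequencing callsets, modelled on the
    alpaca (Vicugna pacos) 76K array. Implements staged per-variant quality
    filtering (Phred quality, genotyping rate, minor allele frequency,
    probe design score, clear flanking sequence), location-score selection
    of one SNP per 40 kbp genome fragment with a second-pass 8 kbp
    subfragment densification, candidate-gene SNP inclusion, genome
    coverage and SNP density accounting, and panel validation through
    VanRaden-type genomic relationships, trio parentage checks, SNP-based
    inbreeding and heterozygosity, cross-platform genotype concordance,
    Weir-Cockerham FST, principal components and LD pruning. A synthetic
    data module simulates multi-scaffold genomes, subdivided pedigreed
    populations and depth-limited sequencing genotype calls so the whole
    pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
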
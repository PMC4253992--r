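Package: haplomm
Title: Candidate-Gene Association Analysis in Half-Sib Designs with
    Polygenic Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-SNP and haplotype-based association analysis for
    candidate-gene studies in paternal half-sib designs that use estimated
    breeding values (EBVs) as phenotypes. Builds the pedigree additive
    relationship matrix and its inverse, fits weighted polygenic mixed
    models by Henderson's mixed model equations with REML variance
    components, performs haplotype trend regression on EM-estimated
    haplotype dosages, computes Hardy-Weinberg goodness-of-fit tests,
    D-prime linkage disequilibrium and haplotype blocks, pools rare
    haplotypes, applies Benjamini-Hochberg FDR correction, and simulates
    half-sib daughter populations with heterogeneous EBV reliabilities for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
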
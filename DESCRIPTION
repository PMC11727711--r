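Package: duckmap
Title: Genetic Mapping of a Two-Locus Epistatic Plumage Trait in Duck F2 Intercrosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a qualitative plumage-colour trait controlled by
    two epistatically interacting autosomal loci in an F2 intercross between two
    duck breeds. Provides a synthetic intercross simulator (founder breeds, F1
    and F2 cohorts with Haldane recombination, planted causal loci, copy-number
    variants and read-depth data), the two-locus segregation model with a
    chi-squared goodness-of-fit test, VCF input/output with standard SNP filters,
    an EMMAX-style mixed-linear-model association scan with kinship and principal
    component covariates, allele-frequency divergence statistics (delta-AF and
    Hudson FST with 10-kb window averages), identity-by-descent style
    haplotype-block fine-mapping with a cross-breed causative-mutation screen,
    windowed read-depth copy-number genotyping, and small expression utilities
    (CPM, group log2 fold change, 2^-ddCt).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
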
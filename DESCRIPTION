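Package: grnperturb
Title: Two-Level Gene Regulatory Networks with In Silico Perturbation
Version: 0.1.0
Authors@R: person("grnperturb", "authors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds two-level gene regulatory networks (SNP and gene level)
    from variable-selection scores and a binary SNP-to-gene annotation mask,
    performs in silico node knockouts with automatic refitting of a pluggable
    variable-selection backend, and reports what changed between networks.
    Includes a reference spike-and-slab variational regression backend
    producing posterior inclusion probabilities, a minSNP univariate
    regression backend producing p-values, an exact model-enumeration oracle
    for testing, genotype preprocessing operators (family-mean imputation,
    minor-allele-frequency filtering, covariate residualization, intergenic
    grouping), a synthetic-data generator with linkage-disequilibrium and
    family structure, and JSON/GraphML network serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
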
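Package: seqimpower
Title: Power and Cost-Effective Design for Sequencing-and-Imputation GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates statistical power for genome-wide association studies
    in which a subset of participants is whole-genome sequenced and the rest
    are array-genotyped and imputed with a reference panel augmented by the
    sequenced participants. Power for a variant of given population frequency
    and relative risk is averaged over empirical per-variant imputation
    quality (r-squared, reference-panel minor allele count), with weights
    matching the empirical minor-allele-count distribution to the disease
    model and accounting for population-specific variants, and gated on
    imputability. Includes a synthetic imputation-quality generator and a
    Monte Carlo two-stage GWAS simulator used as validation oracles, and an
    exhaustive cost-constrained optimizer over designs (number sequenced,
    number imputed, genotyping array).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
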
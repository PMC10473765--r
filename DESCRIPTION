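Package: sexcongr
Title: Cross-Species Congruence of Volumetric Sex Differences in the Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing sex differences in regional brain volume
    between humans and mice across a set of homologous brain regions.
    Estimates standardized sex effects from subject-level volume tables with
    ordinary least squares on z-scored volumes (covarying for total tissue
    volume, age, and quality or strain covariates), applies
    Benjamini-Hochberg false-discovery control and Levene variance tests,
    and harmonizes multi-cohort data with an empirical-Bayes location-scale
    batch adjustment. Cross-species congruence is quantified with the
    percentage-bend robust correlation of paired effect sizes, a per-region
    anatomical sex-effect similarity score (the product of the two species'
    effect sizes), and a per-region transcriptional similarity computed from
    paired region-by-homologous-gene expression matrices, with gene-subset
    permutation nulls. Includes a built-in table of 60 published paired
    effect sizes, and synthetic-data generators with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    sva,
    car
Config/testthat/edition: 3
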
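Package: tivadjust
Title: TIV Adjustment and Validation of Group Differences in Regional Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates group (sex) differences in regional gray-matter
    volumes while removing total-intracranial-volume (TIV) scaling
    effects. Implements four TIV-adjustment procedures (proportion,
    power-corrected proportion, residuals, covariate regression),
    criterial-subsample constructions (TIV-matched pairing and
    TIV-calibrated single-sex splits), per-region difference statistics
    with effect sizes and their intuitive conversions (distribution
    overlap, common-language effect size), TIV-VOI regression
    diagnostics, multi-method concordance indices (free-marginal and
    Cohen's kappa, Kendall's W, Spearman matrices), replication scoring,
    and false-discovery-rate and family-wise multiplicity corrections.
    A synthetic cohort generator with power-law allometric structure
    supports simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, car, e1071, optparse
Config/testthat/edition: 3
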
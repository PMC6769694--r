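Package: mucinquant
Title: Quantification of Histochemical Mucin Staining in Brightfield Microscopy
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Digital image analysis of periodic acid-Schiff (PAS) and alcian
    blue (AB) histochemical reactions in brightfield microscopy of colorectal
    tissue. Implements two independent segmentation backends that report the
    stain area fraction A%: threshold segmentation in HSV color space
    (wraparound-aware hue intervals) and a seeded three-class Gaussian pixel
    classifier (reaction / tissue without reaction / background). Includes
    field-to-slide aggregation, the semi-quantitative immunoreactive score
    (IRS), a nonparametric statistics harness (Cronbach's alpha, Spearman,
    Wilcoxon signed-rank, Mann-Whitney, Kaplan-Meier with log-rank) with
    exact small-sample p-value branches, a synthetic stained-tissue and
    cohort generator with exact ground truth, and a command-line interface
    for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
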
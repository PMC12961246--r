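Package: divstab
Title: Diversity-Population Stability Analysis for Community Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the relationship between plant species
    diversity and the temporal stability of populations in repeatedly sampled
    permanent plots. Computes per-plot population stability (unweighted and
    abundance-weighted mean population coefficients of variation, with a
    detrended variant based on three-term local variance), average and
    cumulative species richness and temporal turnover; derives per-dataset
    sign-adjusted Pearson correlations between log-transformed diversity and
    stability metrics with Fisher-Z effect sizes; and synthesizes correlations
    across datasets with linear mixed-effects models (metric interaction,
    Satterthwaite degrees of freedom) and REML random-effects meta-regression,
    plus driver regressions with variance-inflation screening and a climate
    principal-component step. Includes a synthetic multi-dataset community
    generator with lognormal abundance hierarchies, Taylor power-law
    variance-mean scaling, temporal autocorrelation, species trends, and
    detection-threshold absences that induce occupancy-abundance coupling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    lmerTest,
    emmeans,
    metafor,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
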
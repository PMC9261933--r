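Package: causalPLS
Title: Latent-Treatment Causal Effect Estimation for Radiomics via Kernel Partial Least Squares
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the local causal effect of a latent tumor construct on a
    clinical outcome from radiomics feature tables. The latent treatment is
    inferred as the first-component score of a multivariate kernel partial
    least squares regression of the (standardized) radiomics features on the
    measured confounders; the effect is the slope of the working outcome on
    the unit-variance score, with nonparametric bootstrap percentile
    confidence intervals. Right-censored survival outcomes enter through
    null-model martingale residuals. Includes a NIPALS reference
    implementation, the Stone-Brooks continuum-regression direction family
    linking ordinary least squares, partial least squares and principal
    components regression, a first-principal-component regression baseline,
    and a synthetic-data generator for the latent-treatment causal diagram
    used in parameter-recovery, coverage and consistency experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    MASS,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, DimensionReduction, Survival
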
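Package: clustermaps
Title: High-Resolution Mapping of Household-Survey Indicators from
    Geolocated Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpolates cluster-level household-survey indicators
    (literacy, child stunting, modern-contraception use) to 1x1 km
    gridded surfaces with uncertainty. Implements DHS-style displaced
    cluster simulation with known ground truth, harmonization of raster
    covariates to a common metric grid, displacement-aware buffer
    covariate extraction (buffer means and Monte Carlo draws), covariate
    selection by iterative variance-inflation-factor filtering and
    jackknife sensitivity analysis, a hierarchical spatial
    Gaussian-process (Matern nu = 1) interpolator fitted by maximum
    marginal likelihood, a from-equations feed-forward neural network,
    trivial-mean and linear baselines, a validation suite (MSE, RMSE,
    MAE, pseudo-R2, bias, trivial-model MSE) with repeated random
    sub-sampling splits, gridded prediction surfaces with uncertainty
    summaries and zonal aggregation, and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'ann.R'
    'baselines.R'
    'clustermaps-package.R'
    'grid.R'
    'covariates.R'
    'gp.R'
    'mapping.R'
    'validation.R'
    'raster-io.R'
    'synthetic.R'
    'pipeline.R'
    'resample.R'
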
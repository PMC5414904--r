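#' @import methods
NULL

#' Planar metric grid specification
#'
#' Describes a regular raster grid in planar metre coordinates. Row 0 (R index
#' 1) is the top of the grid; pixel (r, c) covers the half-open square
#' \code{[originX + (c-1)*cellSize, originX + c*cellSize)} in x and
#' \code{(originY - r*cellSize, originY - (r-1)*cellSize]} in y, with
#' pixel-centre registration used for all sampling.
#'
#' @slot nRows,nCols integer, grid dimensions (>= 1).
#' @slot originX,originY numeric, top-left corner in metres.
#' @slot cellSize numeric, cell edge length in metres (> 0); 1000 for the
#'   canonical 1x1 km analysis grid.
#' @slot crsTag character, free-text tag for the planar CRS.
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer",
                 originX = "numeric", originY = "numeric",
                 cellSize = "numeric", crsTag = "character"),
  prototype(nRows = 1L, nCols = 1L, originX = 0, originY = 0,
            cellSize = 1000, crsTag = "planar-metres"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single integer >= 1")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Single named raster layer
#'
#' A named layer of values on a \linkS4class{GridSpec}. Missing cells are NA.
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot name non-empty layer name.
#' @slot values numeric matrix of dimension nRows x nCols; NA marks missing.
#' @export
setClass("RasterLayer",
  representation(grid = "GridSpec", name = "character", values = "matrix"))

setValidity("RasterLayer", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (nrow(object@values) != object@grid@nRows ||
      ncol(object@values) != object@grid@nCols)
    msg <- c(msg, "values dimensions must equal grid dimensions")
  if (length(msg)) msg else TRUE
})

#' Aligned stack of covariate layers
#'
#' An ordered list of \linkS4class{RasterLayer}s sharing one identical
#' \linkS4class{GridSpec}, with unique layer names.
#'
#' @slot grid the shared \linkS4class{GridSpec}.
#' @slot layers list of \linkS4class{RasterLayer}.
#' @export
setClass("CovariateStack",
  representation(grid = "GridSpec", layers = "list"))

setValidity("CovariateStack", function(object) {
  msg <- character()
  if (!all(vapply(object@layers, is, logical(1), "RasterLayer")))
    return("all layers must be RasterLayer objects")
  for (ly in object@layers) {
    if (!identical(ly@grid, object@grid)) {
      msg <- c(msg, sprintf("layer '%s' is not on the shared grid", ly@name))
      break
    }
  }
  nms <- vapply(object@layers, function(l) l@name, character(1))
  if (anyDuplicated(nms)) msg <- c(msg, "layer names must be unique")
  if (length(msg)) msg else TRUE
})

#' Survey cluster table
#'
#' A set of survey clusters with true and reported (displaced) locations,
#' urban/rural stratum and a binomial indicator outcome. Backed by a
#' data.frame with columns \code{id, true_x, true_y, x, y, stratum,
#' flagged_far, n_respondents, n_positive, indicator}; \code{x, y} are the
#' reported coordinates used by all modelling stages, the true coordinates
#' exist for evaluation only.
#'
#' Displacement caps (checked by validity): 2000 m for urban clusters, 5000 m
#' for rural, 10000 m for the flagged 1 percent far-displaced rural subset.
#'
#' @slot data the backing data.frame.
#' @export
setClass("ClusterSet", representation(data = "data.frame"))

.cluster_cols <- c("id", "true_x", "true_y", "x", "y", "stratum",
                   "flagged_far", "n_respondents", "n_positive", "indicator")

setValidity("ClusterSet", function(object) {
  d <- object@data
  miss <- setdiff(.cluster_cols, names(d))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  msg <- character()
  if (nrow(d)) {
    if (!all(d$stratum %in% c("urban", "rural")))
      msg <- c(msg, "stratum must be 'urban' or 'rural'")
    if (any(d$n_respondents < 1))
      msg <- c(msg, "n_respondents must be >= 1")
    bad <- which(d$n_positive < 0 | d$n_positive > d$n_respondents)
    if (length(bad))
      msg <- c(msg, sprintf("n_positive outside [0, n_respondents] at row %d",
                            bad[1]))
    dist <- sqrt((d$x - d$true_x)^2 + (d$y - d$true_y)^2)
    cap <- ifelse(d$stratum == "urban", 2000,
                  ifelse(d$flagged_far, 10000, 5000))
    over <- which(dist > cap + 1e-6)
    if (length(over))
      msg <- c(msg, sprintf("displacement exceeds stratum cap at row %d",
                            over[1]))
    if (any(d$flagged_far & d$stratum != "rural"))
      msg <- c(msg, "flagged_far is only defined for rural clusters")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic survey world
#'
#' Records every parameter of a simulated indicator surface: regression
#' coefficients on the covariate layers (intercept first), the Matern nu = 1
#' spatial residual's variance and range, the nugget reserved for
#' observation-level noise, the link used to map the linear predictor to a
#' proportion, and the realized latent proportion surface.
#'
#' @slot beta numeric vector, intercept + one coefficient per covariate.
#' @slot spatialVariance marginal variance of the spatial residual (>= 0).
#' @slot rangeParam practical range of the spatial residual in metres.
#' @slot nugget variance of uncorrelated site-level noise (>= 0).
#' @slot link "logit" or "identity" (identity is clamped to [0, 1]).
#' @slot latentSurface \linkS4class{RasterLayer} of true proportions.
#' @slot seed integer seed used for the realization.
#' @export
setClass("SyntheticTruth",
  representation(beta = "numeric", spatialVariance = "numeric",
                 rangeParam = "numeric", nugget = "numeric",
                 link = "character", latentSurface = "RasterLayer",
                 seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (object@spatialVariance < 0) msg <- c(msg, "spatialVariance must be >= 0")
  if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
  if (object@rangeParam <= 0) msg <- c(msg, "rangeParam must be > 0")
  if (!object@link %in% c("logit", "identity"))
    msg <- c(msg, "link must be 'logit' or 'identity'")
  v <- object@latentSurface@values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "latent surface values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cluster-by-covariate design matrix
#'
#' Covariate values extracted at clusters by displacement-aware buffer
#' extraction, z-score standardized column-wise with the centring/scaling
#' stored for later grid prediction. In replicate mode (Monte Carlo draws for
#' the neural-network path) cluster ids repeat once per draw.
#'
#' @slot clusterIds character, one id per row (repeated in replicate mode).
#' @slot covariateNames column names, in column order.
#' @slot values standardized numeric matrix, no missing values.
#' @slot coords matrix of reported cluster coordinates, one row per row of
#'   \code{values}.
#' @slot extractionMethod "buffer_mean" or "buffer_mc".
#' @slot bufferRadii named numeric, buffer radius in metres per stratum.
#' @slot mcDraws integer, Monte Carlo draws per cluster (0 for buffer_mean).
#' @slot center,scale named numeric, the standardization constants.
#' @export
setClass("DesignMatrix",
  representation(clusterIds = "character", covariateNames = "character",
                 values = "matrix", coords = "matrix",
                 extractionMethod = "character", bufferRadii = "numeric",
                 mcDraws = "integer", center = "numeric", scale = "numeric"))

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (anyNA(object@values)) msg <- c(msg, "design matrix must have no NA")
  if (ncol(object@values) != length(object@covariateNames))
    msg <- c(msg, "column count must match covariateNames")
  if (nrow(object@values) != length(object@clusterIds))
    msg <- c(msg, "row count must match clusterIds")
  if (nrow(object@coords) != nrow(object@values))
    msg <- c(msg, "coords must have one row per design row")
  if (!object@extractionMethod %in% c("buffer_mean", "buffer_mc"))
    msg <- c(msg, "extractionMethod must be 'buffer_mean' or 'buffer_mc'")
  if (length(msg)) msg else TRUE
})

#' Covariate selection report
#'
#' Traces both selection stages: variance-inflation-factor filtering (final
#' VIF table and removal order) and jackknife sensitivity analysis (mean
#' validation explained variance when each covariate is dropped).
#'
#' @slot vifTable named numeric, VIF per retained covariate (Inf marks exact
#'   collinearity).
#' @slot removedByVif character, covariates removed, in removal order.
#' @slot jackknifeScores named numeric, leave-covariate-out scores of the
#'   last jackknife round.
#' @slot baselineScore numeric, score of the full entering set.
#' @slot finalScore numeric, score of the selected set.
#' @slot finalCovariates character, the selected set.
#' @export
setClass("SelectionReport",
  representation(vifTable = "numeric", removedByVif = "character",
                 jackknifeScores = "numeric", baselineScore = "numeric",
                 finalScore = "numeric", finalCovariates = "character"))

#' Hierarchical spatial Gaussian-process interpolator
#'
#' Gaussian-likelihood spatial regression y(s) = X(s)'beta + v(s) + e(s) with
#' v a zero-mean stationary Matern nu = 1 Gaussian process and e iid
#' N(0, sigmaE2). Hyperparameters are fitted by maximum (profile) marginal
#' likelihood; beta is the generalized-least-squares solution at the optimum.
#'
#' @slot beta intercept + coefficients on standardized covariates.
#' @slot sigmaV2 marginal variance of the spatial field.
#' @slot rangeM practical range in metres (kappa = sqrt(8)/rangeM).
#' @slot alpha SPDE smoothness-control, fixed at 2 (nu = 1 in 2-D).
#' @slot sigmaE2 nugget variance.
#' @slot covariateNames,center,scale training-covariate standardization.
#' @slot fitState list with training coordinates, design, responses, the
#'   covariance Cholesky factor and precomputed solves used for prediction.
#' @slot logLik maximized log marginal likelihood.
#' @export
setClass("SpatialGPModel",
  representation(beta = "numeric", sigmaV2 = "numeric", rangeM = "numeric",
                 alpha = "numeric", sigmaE2 = "numeric",
                 covariateNames = "character", center = "numeric",
                 scale = "numeric", fitState = "list", logLik = "numeric"))

setValidity("SpatialGPModel", function(object) {
  msg <- character()
  if (object@sigmaV2 < 0) msg <- c(msg, "sigmaV2 must be >= 0")
  if (object@sigmaE2 <= 0) msg <- c(msg, "sigmaE2 must be > 0")
  if (object@rangeM <= 0) msg <- c(msg, "rangeM must be > 0")
  if (length(object@beta) != length(object@covariateNames) + 1L)
    msg <- c(msg, "beta length must be n_covariates + 1")
  if (length(msg)) msg else TRUE
})

#' Feed-forward neural network (single hidden layer)
#'
#' A from-equations feed-forward network: each node j receives the weighted
#' sum of incoming signals plus a bias, s_j = sum_i W_ij x_i + b_j, and emits
#' y = 1 / (1 + exp(-s_j)) (logistic activation at hidden and output nodes),
#' so the output is bounded in (0, 1) as a proportion must be.
#'
#' @slot layerSizes integer c(inputs, hidden, 1).
#' @slot weights list of two weight matrices (input->hidden, hidden->output).
#' @slot biases list of two bias vectors.
#' @slot activation "logistic".
#' @slot covariateNames,center,scale input standardization.
#' @export
setClass("AnnModel",
  representation(layerSizes = "integer", weights = "list", biases = "list",
                 activation = "character", covariateNames = "character",
                 center = "numeric", scale = "numeric"))

setValidity("AnnModel", function(object) {
  ls <- object@layerSizes
  msg <- character()
  if (length(ls) != 3L || ls[3] != 1L)
    msg <- c(msg, "layerSizes must be c(inputs, hidden, 1)")
  if (length(object@weights) == 2L) {
    if (!all(dim(object@weights[[1]]) == ls[1:2]))
      msg <- c(msg, "hidden weight matrix must be inputs x hidden")
    if (!all(dim(object@weights[[2]]) == c(ls[2], 1L)))
      msg <- c(msg, "output weight matrix must be hidden x 1")
  } else msg <- c(msg, "weights must hold two matrices")
  if (length(msg)) msg else TRUE
})

#' Ensemble of seeded neural-network refits
#'
#' Holds the restarts/bootstrap refits used to attach an uncertainty band to
#' neural-network predictions (mean and sd across members).
#'
#' @slot models list of \linkS4class{AnnModel}.
#' @export
setClass("AnnEnsemble", representation(models = "list"))

#' Trivial mean baseline
#' @slot mu the training mean, predicted everywhere.
#' @export
setClass("MeanModel", representation(mu = "numeric"))

#' Plain least-squares linear model on standardized covariates
#' @slot beta intercept + coefficients.
#' @slot covariateNames,center,scale input standardization.
#' @export
setClass("LinearModel",
  representation(beta = "numeric", covariateNames = "character",
                 center = "numeric", scale = "numeric"))

#' Validation metric suite for one model
#'
#' Houses the full metric set used to compare interpolators: mean squared
#' error, its root, mean absolute error, explained variance (pseudo-R2,
#' 1 - MSE/var(obs)), a sign-preserving bias parameter
#' (mean(pred) - mean(obs)) / sd(obs), and the trivial mean model's MSE
#' (the population variance of the observations), which anchors the
#' pseudo-R2 scale. Population (divide-by-n) variance throughout.
#'
#' @slot modelId identifier of the scored model.
#' @slot mse,rmse,mae,expVar,bias,mseMean the metrics (NA sentinels where
#'   var(obs) = 0 makes expVar/bias undefined).
#' @slot nEval number of evaluation pairs.
#' @export
setClass("ValidationReport",
  representation(modelId = "character", mse = "numeric", rmse = "numeric",
                 mae = "numeric", expVar = "numeric", bias = "numeric",
                 mseMean = "numeric", nEval = "integer"))

setValidity("ValidationReport", function(object) {
  msg <- character()
  if (object@mse < 0) msg <- c(msg, "mse must be >= 0")
  if (abs(object@rmse^2 - object@mse) > 1e-12 * max(1, object@mse))
    msg <- c(msg, "rmse^2 must equal mse")
  if (!is.na(object@expVar) && object@expVar > 1 + 1e-12)
    msg <- c(msg, "expVar cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' Gridded prediction surface with uncertainty
#'
#' Mean predicted proportion and its uncertainty (predictive standard
#' deviation, or the interdecile range 2.5631 * sd when configured), on one
#' shared grid.
#'
#' @slot mean \linkS4class{RasterLayer} of predicted proportions in [0, 1].
#' @slot sd \linkS4class{RasterLayer} of uncertainty values (>= 0).
#' @slot modelId,indicator identifiers.
#' @slot sdType "sd" or "interdecile".
#' @export
setClass("PredictionSurface",
  representation(mean = "RasterLayer", sd = "RasterLayer",
                 modelId = "character", indicator = "character",
                 sdType = "character"))

setValidity("PredictionSurface", function(object) {
  msg <- character()
  if (!identical(object@mean@grid, object@sd@grid))
    msg <- c(msg, "mean and sd layers must share one GridSpec")
  if (any(object@sd@values < 0, na.rm = TRUE))
    msg <- c(msg, "sd values must be >= 0")
  m <- object@mean@values
  if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "mean values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
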
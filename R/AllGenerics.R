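#' @include AllClasses.R
NULL

#' Grid of an object
#' @param x an object carrying a \linkS4class{GridSpec}.
#' @return the \linkS4class{GridSpec}.
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Raster values of an object
#' @param x a \linkS4class{RasterLayer} or similar.
#' @return numeric matrix.
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' Layer names of a stack
#' @param x a \linkS4class{CovariateStack}.
#' @return character vector.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Cluster table of a ClusterSet
#' @param x a \linkS4class{ClusterSet}.
#' @return data.frame.
#' @export
setGeneric("clusterData", function(x) standardGeneric("clusterData"))

#' Model prediction at new covariate rows
#'
#' Uniform prediction interface across the interpolators. Each model applies
#' its stored input standardization to \code{X} internally, so \code{X} is
#' always on the raw covariate scale with columns named as at training.
#'
#' @param object a fitted model.
#' @param X numeric matrix of raw covariate values (or NULL for the trivial
#'   mean baseline).
#' @param coords numeric matrix of planar coordinates, needed by spatial
#'   models.
#' @param ... model-specific options, e.g. \code{se = TRUE} to return a list
#'   with predictive standard deviations, \code{includeNugget} for the
#'   Gaussian-process predictive sd.
#' @return numeric vector of predicted proportions, or, with \code{se =
#'   TRUE}, \code{list(mean =, sd =)}.
#' @export
setGeneric("predictModel",
           function(object, X, coords = NULL, ...)
             standardGeneric("predictModel"))

#' @describeIn gridSpec grid of a raster layer
#' @export
setMethod("gridSpec", "RasterLayer", function(x) x@grid)
#' @describeIn gridSpec grid of a covariate stack
#' @export
setMethod("gridSpec", "CovariateStack", function(x) x@grid)
#' @describeIn gridSpec grid of a prediction surface
#' @export
setMethod("gridSpec", "PredictionSurface", function(x) x@mean@grid)

#' @describeIn rasterValues values matrix of a raster layer
#' @export
setMethod("rasterValues", "RasterLayer", function(x) x@values)

#' @describeIn layerNames names of the layers in order
#' @export
setMethod("layerNames", "CovariateStack",
          function(x) vapply(x@layers, function(l) l@name, character(1)))

#' @describeIn clusterData backing data.frame
#' @export
setMethod("clusterData", "ClusterSet", function(x) x@data)

#' Number of clusters / layers
#' @param x a \linkS4class{ClusterSet} or \linkS4class{CovariateStack}.
#' @return integer count.
#' @export
setMethod("length", "ClusterSet", function(x) nrow(x@data))
#' @rdname length-ClusterSet-method
#' @export
setMethod("length", "CovariateStack", function(x) length(x@layers))

#' Extract a layer from a stack by name or position
#' @param x a \linkS4class{CovariateStack}.
#' @param i layer name or index.
#' @return a \linkS4class{RasterLayer}.
#' @export
setMethod("[[", "CovariateStack", function(x, i) {
  if (is.character(i)) {
    k <- match(i, layerNames(x))
    if (is.na(k)) stop(sprintf("no layer named '%s'", i))
    i <- k
  }
  x@layers[[i]]
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g) [%s]\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY, object@crsTag))
})

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  cat(sprintf("RasterLayer '%s': %d x %d, %d missing\n", object@name,
              nrow(v), ncol(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                mean(v, na.rm = TRUE)))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack: %d layer(s) on %d x %d grid (%g m cells)\n",
              length(object@layers), object@grid@nRows, object@grid@nCols,
              object@grid@cellSize))
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
})

setMethod("show", "ClusterSet", function(object) {
  d <- object@data
  cat(sprintf("ClusterSet: %d cluster(s) (%d urban, %d rural, %d far-flagged)\n",
              nrow(d), sum(d$stratum == "urban"), sum(d$stratum == "rural"),
              sum(d$flagged_far)))
  if (nrow(d))
    cat(sprintf("  indicator '%s', pooled proportion %.3f\n", d$indicator[1],
                sum(d$n_positive) / sum(d$n_respondents)))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d row(s) x %d covariate(s), method %s\n",
              nrow(object@values), ncol(object@values),
              object@extractionMethod))
})

setMethod("show", "SpatialGPModel", function(object) {
  cat("Spatial Gaussian-process model (Matern nu = 1)\n")
  cat(sprintf("  sigma_v2 = %.4g, range = %.4g m, sigma_e2 = %.4g\n",
              object@sigmaV2, object@rangeM, object@sigmaE2))
  cat(sprintf("  beta: %s\n", paste(signif(object@beta, 4), collapse = ", ")))
  cat(sprintf("  log marginal likelihood: %.3f\n", object@logLik))
})

setMethod("show", "AnnModel", function(object) {
  cat(sprintf("Feed-forward ANN: %d-%d-%d, logistic activations\n",
              object@layerSizes[1], object@layerSizes[2],
              object@layerSizes[3]))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf(
    "ValidationReport [%s]: MSE %.4g RMSE %.4g MAE %.4g exp.var %.3f bias %.3f MSE(mean) %.4g (n=%d)\n",
    object@modelId, object@mse, object@rmse, object@mae, object@expVar,
    object@bias, object@mseMean, object@nEval))
})

setMethod("show", "PredictionSurface", function(object) {
  cat(sprintf("PredictionSurface [%s, %s]\n", object@modelId,
              object@indicator))
  show(object@mean)
  show(object@sd)
})

setMethod("show", "SelectionReport", function(object) {
  cat("Covariate SelectionReport\n")
  cat("  removed by VIF:",
      if (length(object@removedByVif)) paste(object@removedByVif,
                                             collapse = ", ") else "(none)",
      "\n")
  cat("  final set:", paste(object@finalCovariates, collapse = ", "), "\n")
})
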
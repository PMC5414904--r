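#' @include AllClasses.R grid.R gp.R ann.R baselines.R
NULL

# interdecile range of a Gaussian: q90 - q10 = 2 * qnorm(0.9) * sd
.IDR_FACTOR <- 2 * stats::qnorm(0.9)    # 2.5631...

#' Evaluate a fitted model over a covariate stack
#'
#' Produces the gridded prediction surface: the model is evaluated at every
#' cell centre where all required covariate layers are non-missing (cells
#' with any missing covariate stay missing), in a traversal-order-free way.
#' Uncertainty is the predictive standard deviation (spatial models:
#' conditional-Gaussian latent sd; network models: ensemble spread;
#' mean/linear baselines: 0), or the interdecile range 2.5631 * sd when
#' \code{sdType = "interdecile"}. Means are clamped to [0, 1].
#'
#' @param model a fitted model with a \code{predictModel} method.
#' @param stack a \linkS4class{CovariateStack} whose layer names cover the
#'   model's covariates (raw scale; the model standardizes internally).
#' @param modelId,indicator labels stored on the surface.
#' @param sdType "sd" or "interdecile".
#' @param includeNugget add the nugget to the spatial predictive variance
#'   (default FALSE: smooth latent-only uncertainty maps).
#' @return a \linkS4class{PredictionSurface}.
#' @export
predictSurface <- function(model, stack, modelId = class(model),
                           indicator = "indicator",
                           sdType = c("sd", "interdecile"),
                           includeNugget = FALSE) {
  sdType <- match.arg(sdType)
  grid <- stack@grid
  need <- if (is(model, "AnnEnsemble"))
    model@models[[1]]@covariateNames
  else if (.hasSlot(model, "covariateNames"))
    model@covariateNames else character()
  if (length(need)) {
    missing <- setdiff(need, layerNames(stack))
    if (length(missing))
      stop(sprintf("stack is missing required layer(s): %s",
                   paste(missing, collapse = ", ")))
  }
  nr <- grid@nRows; nc <- grid@nCols
  cells <- cbind(row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr))
  X <- if (length(need)) {
    vals <- stackValuesAt(stack, cells)[, need, drop = FALSE]
    vals
  } else NULL
  ok <- if (is.null(X)) rep(TRUE, nrow(cells)) else
    !apply(X, 1, anyNA)
  mu <- rep(NA_real_, nrow(cells)); sdv <- rep(NA_real_, nrow(cells))
  if (any(ok)) {
    ctr <- cellCenter(grid, cells[ok, 1], cells[ok, 2])
    Xok <- if (is.null(X)) NULL else X[ok, , drop = FALSE]
    pr <- if (is(model, "SpatialGPModel"))
      predictModel(model, Xok, coords = ctr, se = TRUE,
                   includeNugget = includeNugget)
    else if (is(model, "AnnEnsemble"))
      predictModel(model, Xok, se = TRUE)
    else list(mean = predictModel(model, Xok, coords = ctr,
                                  n = sum(ok)),
              sd = rep(0, sum(ok)))
    mu[ok] <- pmin(pmax(pr$mean, 0), 1)
    sdv[ok] <- pr$sd
  }
  if (sdType == "interdecile") sdv <- sdv * .IDR_FACTOR
  mMean <- matrix(NA_real_, nr, nc); mMean[cells] <- mu
  mSd <- matrix(NA_real_, nr, nc); mSd[cells] <- sdv
  new("PredictionSurface",
      mean = rasterLayerNew(grid, mMean, "mean_proportion"),
      sd = rasterLayerNew(grid, mSd,
                          if (sdType == "sd") "sd" else "interdecile"),
      modelId = modelId, indicator = indicator, sdType = sdType)
}

.hasSlot <- function(x, name) name %in% slotNames(class(x))

#' Fraction of pixels under uncertainty thresholds
#'
#' For each threshold t, the fraction of non-missing pixels of the
#' uncertainty layer with value < t — the map-level uncertainty summary
#' (e.g. "more than 73 percent of pixels with standard deviation below
#' 0.1"). Fractions are non-decreasing in t.
#'
#' @param surface a \linkS4class{PredictionSurface}.
#' @param thresholds numeric thresholds, sorted ascending.
#' @return data.frame with columns threshold and fraction.
#' @export
summarizeUncertainty <- function(surface, thresholds) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  v <- surface@sd@values
  v <- v[!is.na(v)]
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds, function(t) mean(v < t),
                               numeric(1)))
}

#' Aggregate a prediction surface to zones
#'
#' Per-zone (optionally weighted) mean of the mean layer and
#' root-mean-square of the uncertainty layer — the summary used to carry
#' pixel maps to administrative units. Zone label 0 and missing labels are
#' excluded.
#'
#' @param surface a \linkS4class{PredictionSurface}.
#' @param zones \linkS4class{RasterLayer} of integer zone labels on the same
#'   grid.
#' @param weights optional \linkS4class{RasterLayer} of non-negative weights
#'   (e.g. population) on the same grid.
#' @return data.frame with columns zone, mean, sd_rms, n_cells (empty if no
#'   labelled overlap).
#' @export
aggregateToUnits <- function(surface, zones, weights = NULL) {
  grid <- gridSpec(surface)
  if (!identical(zones@grid, grid)) stop("zones must be on the surface grid")
  if (!is.null(weights) && !identical(weights@grid, grid))
    stop("weights must be on the surface grid")
  z <- as.vector(zones@values)
  m <- as.vector(surface@mean@values)
  s <- as.vector(surface@sd@values)
  w <- if (is.null(weights)) rep(1, length(z)) else
    as.vector(weights@values)
  keep <- !is.na(z) & z != 0 & !is.na(m) & !is.na(w)
  if (!any(keep))
    return(data.frame(zone = integer(), mean = numeric(),
                      sd_rms = numeric(), n_cells = integer()))
  z <- z[keep]; m <- m[keep]; s <- s[keep]; w <- w[keep]
  zs <- sort(unique(z))
  do.call(rbind, lapply(zs, function(zz) {
    i <- z == zz
    data.frame(zone = as.integer(zz),
               mean = sum(w[i] * m[i]) / sum(w[i]),
               sd_rms = sqrt(sum(w[i] * s[i]^2, na.rm = TRUE) / sum(w[i])),
               n_cells = sum(i))
  }))
}

#' Write a prediction surface as paired ASCII grids
#'
#' Writes \code{<prefix>_mean.asc} and \code{<prefix>_sd.asc}.
#'
#' @param surface a \linkS4class{PredictionSurface}.
#' @param prefix path prefix.
#' @return invisibly, the two paths.
#' @export
writeSurface <- function(surface, prefix) {
  p1 <- paste0(prefix, "_mean.asc"); p2 <- paste0(prefix, "_sd.asc")
  writeRaster(surface@mean, p1)
  writeRaster(surface@sd, p2)
  invisible(c(p1, p2))
}
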
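#' @include AllClasses.R utils.R covariates.R
NULL

#' Matern nu = 1 covariance function
#'
#' C(d) = sigmaV2 * (kappa d) K1(kappa d) with kappa = sqrt(8) / rangeM, the
#' nu = 1 member of the Matern family under the practical-range convention
#' (correlation ~ 0.14 at d = rangeM; the field is the stationary solution
#' of the SPDE (kappa^2 - Laplacian) x = noise with smoothness alpha = 2 in
#' two dimensions). Continuous and monotone decreasing, C(0) = sigmaV2.
#'
#' @param d distance(s) in metres, >= 0 (vectorized).
#' @param sigmaV2 marginal variance.
#' @param rangeM practical range in metres.
#' @return covariance value(s), same shape as \code{d}.
#' @examples
#' maternCov(0, 2, 1e4)            # == 2
#' maternCov(1e4, 1, 1e4)          # ~ 0.14
#' @export
maternCov <- function(d, sigmaV2, rangeM) {
  if (any(d < 0)) stop("distance must be >= 0")
  kappa <- sqrt(8) / rangeM
  x <- kappa * d
  out <- sigmaV2 * x * besselK(x, 1)
  out[d == 0] <- sigmaV2
  # x*K1(x) underflows to NaN via 0*Inf only at x=0, handled above; at very
  # large x besselK underflows to 0, which is the correct limit
  out[is.nan(out)] <- 0
  if (!is.null(dim(d))) dim(out) <- dim(d)
  out
}

.distMat <- function(a, b = a) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Profile negative log marginal likelihood of y = X beta + v + e at given
# hyperparameters; beta profiled out by GLS. Cholesky-based.
# Returns list(nll, beta, cholU) or NULL if the covariance is not PD.
.gpProfile <- function(X, D, y, sigmaV2, rangeM, sigmaE2) {
  n <- length(y)
  Sigma <- maternCov(D, sigmaV2, rangeM)
  diag(Sigma) <- sigmaV2 + sigmaE2
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  # whiten: solve U' a = . (forward), then GLS via QR of whitened X
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qr_ <- qr(Xw)
  beta <- qr.coef(qr_, yw)
  beta[is.na(beta)] <- 0
  rw <- yw - Xw %*% beta
  nll <- 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(U))) + sum(rw^2))
  list(nll = nll, beta = as.numeric(beta), cholU = U)
}

#' Log marginal likelihood of the spatial Gaussian-process model
#'
#' Evaluates the Gaussian log marginal likelihood of y = X beta + v + e with
#' Matern nu = 1 spatial covariance, profiling beta out by generalized least
#' squares when it is not supplied. Cholesky-based; used both by the fitter
#' and as a checkable quantity.
#'
#' @param X design matrix including the intercept column.
#' @param coords n x 2 matrix of planar coordinates in metres.
#' @param y numeric response vector.
#' @param sigmaV2,rangeM,sigmaE2 hyperparameters.
#' @param beta optional fixed coefficients; default profiles by GLS.
#' @return log marginal likelihood (scalar).
#' @export
gpLogLik <- function(X, coords, y, sigmaV2, rangeM, sigmaE2, beta = NULL) {
  D <- .distMat(coords)
  if (is.null(beta)) {
    pr <- .gpProfile(X, D, y, sigmaV2, rangeM, sigmaE2)
    if (is.null(pr)) return(-Inf)
    return(-pr$nll)
  }
  n <- length(y)
  Sigma <- maternCov(D, sigmaV2, rangeM)
  diag(Sigma) <- sigmaV2 + sigmaE2
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  rw <- backsolve(U, y - X %*% beta, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(U))) + sum(rw^2))
}

#' Fit the hierarchical spatial Gaussian-process model
#'
#' Fits y(s) = X(s)'beta + v(s) + e(s) with Gaussian likelihood on cluster
#' proportions, v a Matern nu = 1 field and e iid noise. Hyperparameters
#' (sigmaV2, rangeM, sigmaE2) maximize the profile log marginal likelihood
#' by bounded multi-start L-BFGS-B over log parameters (empirical Bayes);
#' beta is the GLS solution at the optimum. Coordinates are the reported
#' (displaced) cluster locations.
#'
#' @param design a \linkS4class{DesignMatrix} (standardized values).
#' @param y numeric vector of cluster proportions, one per design row.
#' @param coords optional n x 2 coordinate matrix (default
#'   \code{design@coords}).
#' @param fixedHyper optional named vector c(sigmaV2=, rangeM=, sigmaE2=) to
#'   skip optimization (e.g. known truth).
#' @param nStarts number of optimization starts (default 3).
#' @param logitTransform fit on the logit scale with delta-method
#'   back-transform at prediction (default FALSE: Gaussian on proportions,
#'   matching the MSE-centric validation).
#' @return a \linkS4class{SpatialGPModel}.
#' @export
fitGP <- function(design, y, coords = NULL, fixedHyper = NULL, nStarts = 3L,
                  logitTransform = FALSE) {
  if (is.null(coords)) coords <- design@coords
  n <- length(y)
  if (n < 10) stop("need at least 10 clusters to fit the spatial model")
  stopifnot(nrow(coords) == n, nrow(design@values) == n)
  yfit <- if (logitTransform) logit(pmin(pmax(y, 1e-4), 1 - 1e-4)) else y
  X <- cbind(intercept = 1, design@values)
  D <- .distMat(coords)
  domain <- max(D)
  if (!is.null(fixedHyper)) {
    best <- c(log(fixedHyper[["sigmaV2"]] + 1e-12),
              log(fixedHyper[["rangeM"]]), log(fixedHyper[["sigmaE2"]]))
  } else {
    v0 <- popVar(yfit)
    starts <- list(c(log(0.5 * v0), log(domain / 4), log(0.5 * v0)),
                   c(log(0.1 * v0), log(domain / 10), log(0.9 * v0)),
                   c(log(1.0 * v0), log(domain / 2), log(0.1 * v0)),
                   c(log(0.05 * v0), log(domain / 20), log(0.5 * v0)))
    starts <- starts[seq_len(min(nStarts, length(starts)))]
    obj <- function(par) {
      pr <- .gpProfile(X, D, yfit, exp(par[1]), exp(par[2]), exp(par[3]))
      if (is.null(pr) || !is.finite(pr$nll)) 1e10 else pr$nll
    }
    lower <- c(log(v0 * 1e-6), log(domain * 1e-3), log(v0 * 1e-6))
    upper <- c(log(v0 * 1e3), log(domain * 1e2), log(v0 * 1e3))
    best <- NULL; bestVal <- Inf
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < bestVal) {
        bestVal <- fit$value; best <- fit$par
      }
    }
    if (is.null(best) || bestVal >= 1e10)
      stop("marginal likelihood non-finite at all starts; consider rescaling the response or coordinates")
  }
  sv <- exp(best[1]); rg <- exp(best[2]); se <- exp(best[3])
  pr <- .gpProfile(X, D, yfit, sv, rg, se)
  if (is.null(pr)) stop("covariance not positive definite at the optimum")
  resid <- yfit - X %*% pr$beta
  alphaVec <- backsolve(pr$cholU,
                        backsolve(pr$cholU, resid, transpose = TRUE))
  new("SpatialGPModel", beta = pr$beta, sigmaV2 = sv, rangeM = rg,
      alpha = 2, sigmaE2 = se, covariateNames = design@covariateNames,
      center = design@center, scale = design@scale,
      fitState = list(coords = coords, X = X, y = yfit, cholU = pr$cholU,
                      alpha = as.numeric(alphaVec),
                      logitTransform = logitTransform),
      logLik = -pr$nll)
}

#' @describeIn fitGP predictive mean (and sd) at new sites. \code{X} is on
#'   the raw covariate scale (the training standardization is applied
#'   internally); with \code{se = TRUE} a list with conditional-Gaussian
#'   predictive mean and sd is returned, sd latent-only by default
#'   (\code{includeNugget = TRUE} adds the nugget). Reported means are
#'   clamped to [0, 1].
#' @param object a fitted \linkS4class{SpatialGPModel}.
#' @param X new raw covariate matrix (columns as at training).
#' @param se logical, also return predictive standard deviations.
#' @param includeNugget add sigmaE2 to the predictive variance.
#' @param clamp clamp predicted means to [0, 1] (default TRUE).
#' @param ... unused.
#' @export
setMethod("predictModel", "SpatialGPModel",
function(object, X, coords = NULL, se = FALSE, includeNugget = FALSE,
         clamp = TRUE, ...) {
  st <- object@fitState
  if (is.null(coords)) stop("spatial prediction needs coordinates")
  X <- as.matrix(X)
  if (ncol(X) != length(object@covariateNames))
    stop(sprintf("expected %d covariate column(s), got %d",
                 length(object@covariateNames), ncol(X)))
  Xs <- standardizeColumns(X, object@center, object@scale)$values
  Xn <- cbind(1, Xs)
  mu <- as.numeric(Xn %*% object@beta)
  nNew <- nrow(Xn)
  nTr <- nrow(st$coords)
  sdv <- numeric(nNew)
  # chunked cross-covariance to bound memory on large grids
  chunk <- max(1L, floor(4e6 / nTr))
  for (i0 in seq(1, nNew, by = chunk)) {
    ii <- i0:min(nNew, i0 + chunk - 1)
    K <- maternCov(.distMat(coords[ii, , drop = FALSE], st$coords),
                   object@sigmaV2, object@rangeM)
    mu[ii] <- mu[ii] + as.numeric(K %*% st$alpha)
    if (se) {
      W <- backsolve(st$cholU, t(K), transpose = TRUE)
      v <- pmax(object@sigmaV2 - colSums(W * W), 0)
      if (includeNugget) v <- v + object@sigmaE2
      sdv[ii] <- sqrt(v)
    }
  }
  if (isTRUE(st$logitTransform)) {
    pm <- logistic(mu)
    if (se) sdv <- sdv * pm * (1 - pm)     # delta method
    mu <- pm
  }
  if (clamp) mu <- pmin(pmax(mu, 0), 1)
  if (se) list(mean = mu, sd = sdv) else mu
})
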
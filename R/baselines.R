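#' @include AllClasses.R utils.R
NULL

#' Trivial mean baseline
#'
#' Predicts the training mean everywhere. Its in-sample MSE equals the
#' population variance of the training response, which anchors the
#' pseudo-R2 scale (explained variance 0 by construction).
#'
#' @param y numeric training response.
#' @return a \linkS4class{MeanModel}.
#' @export
fitMeanBaseline <- function(y) new("MeanModel", mu = mean(y))

#' @describeIn fitMeanBaseline predict (constant) at new rows; \code{X} may
#'   be NULL, only its row count is used when given.
#' @param object fitted model.
#' @param X ignored except for its row count (NULL allowed with n = 1).
#' @param coords ignored.
#' @param n number of predictions when \code{X} is NULL.
#' @param ... unused.
#' @export
setMethod("predictModel", "MeanModel",
function(object, X, coords = NULL, n = NULL, ...) {
  k <- if (!is.null(X)) nrow(as.matrix(X)) else if (!is.null(n)) n else 1L
  rep(object@mu, k)
})

# OLS on a model-ready matrix (no re-standardization at predict time)
.fitLinearRaw <- function(X, y) {
  qr_ <- qr(cbind(1, X))
  beta <- qr.coef(qr_, y)
  beta[is.na(beta)] <- 0
  new("LinearModel", beta = as.numeric(beta),
      covariateNames = colnames(X) %||% paste0("x", seq_len(ncol(X))),
      center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plain least-squares linear model
#'
#' Ordinary least squares of the response on the standardized covariates —
#' the non-spatial, non-Bayesian reference interpolator.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param y numeric response, one per design row.
#' @return a \linkS4class{LinearModel}.
#' @export
fitLinear <- function(design, y) {
  m <- .fitLinearRaw(design@values, y)
  new("LinearModel", beta = m@beta, covariateNames = design@covariateNames,
      center = design@center, scale = design@scale)
}

#' @describeIn fitLinear predict at new raw covariate rows (training
#'   standardization applied internally).
#' @param object fitted model.
#' @param X raw covariate matrix.
#' @param coords ignored.
#' @param ... unused.
#' @export
setMethod("predictModel", "LinearModel",
function(object, X, coords = NULL, ...) {
  X <- as.matrix(X)
  Xs <- standardizeColumns(X, object@center, object@scale)$values
  as.numeric(cbind(1, Xs) %*% object@beta)
})

#' Recover raw covariate values from a standardized design matrix
#'
#' Inverts the stored z-score standardization, giving rows on the same scale
#' as the covariate stack — the scale every \code{predictModel} method
#' expects.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param rows optional row subset.
#' @return numeric matrix of raw covariate values.
#' @export
rawValues <- function(design, rows = NULL) {
  X <- design@values
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  sweep(sweep(X, 2, design@scale, "*"), 2, design@center, "+")
}
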
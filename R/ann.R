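#' @include AllClasses.R utils.R
NULL

# matrix forward pass: X (n x inputs, already on model input scale) ->
# list(H = hidden activations, out = outputs)
.annForwardMat <- function(weights, biases, X) {
  H <- logistic(sweep(X %*% weights[[1]], 2, biases[[1]], "+"))
  out <- logistic(as.numeric(H %*% weights[[2]]) + biases[[2]])
  list(H = H, out = out)
}

#' Deterministic forward pass of the feed-forward network
#'
#' Propagates one input vector through the network: each node j computes the
#' weighted sum of its incoming signals plus a bias, s_j = sum_i W_ij x_i +
#' b_j, and emits the logistic activation 1 / (1 + exp(-s_j)); information
#' moves in one direction only (no cycles). The input is taken on the
#' network's own input scale (no standardization applied), so hand-set
#' networks evaluate exactly as written.
#'
#' @param model an \linkS4class{AnnModel}.
#' @param x numeric vector of length \code{layerSizes[1]}.
#' @return predicted proportion in (0, 1).
#' @examples
#' m <- annModelNew(2, 2)   # zero weights
#' annForward(m, c(1, -1))  # 0.5
#' @export
annForward <- function(model, x) {
  if (length(x) != model@layerSizes[1])
    stop(sprintf("input length %d does not match %d network inputs",
                 length(x), model@layerSizes[1]))
  .annForwardMat(model@weights, model@biases, matrix(x, 1))$out
}

#' Construct an AnnModel with given (or zero) weights
#'
#' @param inputs,hidden layer sizes.
#' @param weights,biases optional list of two matrices / two vectors; zeros
#'   by default (output 0.5 everywhere).
#' @param covariateNames,center,scale input standardization metadata.
#' @return an \linkS4class{AnnModel}.
#' @export
annModelNew <- function(inputs, hidden, weights = NULL, biases = NULL,
                        covariateNames = character(inputs),
                        center = numeric(inputs) * 0,
                        scale = numeric(inputs) + 1) {
  if (is.null(weights))
    weights <- list(matrix(0, inputs, hidden), matrix(0, hidden, 1))
  if (is.null(biases)) biases <- list(numeric(hidden), 0)
  new("AnnModel", layerSizes = as.integer(c(inputs, hidden, 1L)),
      weights = weights, biases = biases, activation = "logistic",
      covariateNames = covariateNames, center = center, scale = scale)
}

# Analytic gradient of the mean-squared-error loss for the 1-hidden-layer
# logistic network. Returns list(W1, b1, W2, b2) gradients.
.annGradient <- function(weights, biases, X, y) {
  n <- nrow(X)
  fw <- .annForwardMat(weights, biases, X)
  out <- fw$out; H <- fw$H
  # dE/ds_out for E = mean((out - y)^2), logistic output
  dOut <- 2 / n * (out - y) * out * (1 - out)          # n vector
  gW2 <- t(H) %*% dOut                                  # hidden x 1
  gb2 <- sum(dOut)
  dH <- (dOut %*% t(weights[[2]])) * H * (1 - H)        # n x hidden
  gW1 <- t(X) %*% dH
  gb1 <- colSums(dH)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

.annLoss <- function(weights, biases, X, y)
  mean((.annForwardMat(weights, biases, X)$out - y)^2)

# one full training run; returns list(weights, biases, loss0, loss)
.annTrain <- function(X, y, hidden, lr, momentum, epochs) {
  inputs <- ncol(X)
  weights <- list(matrix(stats::runif(inputs * hidden, -0.5, 0.5), inputs,
                         hidden),
                  matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1))
  biases <- list(stats::runif(hidden, -0.5, 0.5), stats::runif(1, -0.5, 0.5))
  vel <- list(W1 = weights[[1]] * 0, b1 = biases[[1]] * 0,
              W2 = weights[[2]] * 0, b2 = 0)
  loss0 <- .annLoss(weights, biases, X, y)
  for (ep in seq_len(epochs)) {
    g <- .annGradient(weights, biases, X, y)
    vel$W1 <- momentum * vel$W1 - lr * g$W1
    vel$b1 <- momentum * vel$b1 - lr * g$b1
    vel$W2 <- momentum * vel$W2 - lr * g$W2
    vel$b2 <- momentum * vel$b2 - lr * g$b2
    weights[[1]] <- weights[[1]] + vel$W1
    biases[[1]] <- biases[[1]] + vel$b1
    weights[[2]] <- weights[[2]] + vel$W2
    biases[[2]] <- biases[[2]] + vel$b2
    if (!all(is.finite(weights[[1]])) || !all(is.finite(weights[[2]])))
      return(NULL)                                     # diverged
  }
  loss <- .annLoss(weights, biases, X, y)
  if (!is.finite(loss)) return(NULL)
  list(weights = weights, biases = biases, loss0 = loss0, loss = loss)
}

#' Train the feed-forward network
#'
#' Full-batch gradient descent with momentum on the mean squared error,
#' logistic activations throughout. The hidden size is chosen by repeated
#' random sub-sampling: for each candidate size, the training rows are split
#' 70/30 \code{nRepeats} times, the network is trained on the 70 percent and
#' scored on the held 30 percent, and the size with the lowest mean
#' validation MSE wins; the final network is the best of \code{nRestarts}
#' seeded restarts on all rows. Diverging restarts (non-finite loss) are
#' counted and skipped; if every restart diverges an error is raised.
#' Reproducible given the seed.
#'
#' @param design a \linkS4class{DesignMatrix} (standardized values; in
#'   Monte Carlo replicate mode the response must be repeated per draw).
#' @param y numeric vector of proportions, one per design row.
#' @param hiddenSizes candidate hidden-layer sizes (default c(2, 4, 8, 16)).
#' @param learningRate,momentum,epochs optimizer settings.
#' @param nRepeats random 70/30 sub-sampling repeats for tuning.
#' @param nRestarts random restarts of the final fit.
#' @param seed integer seed.
#' @return an \linkS4class{AnnModel}.
#' @export
fitAnn <- function(design, y, hiddenSizes = c(2L, 4L, 8L, 16L),
                   learningRate = 0.5, momentum = 0.9, epochs = 300L,
                   nRepeats = 10L, nRestarts = 3L, seed = 1L) {
  X <- design@values
  n <- nrow(X)
  if (n < 30) stop("need at least 30 rows to train the network")
  withr::with_seed(as.integer(seed), {
    hidden <- hiddenSizes[1]
    if (length(hiddenSizes) > 1) {
      scores <- vapply(hiddenSizes, function(h) {
        mean(vapply(seq_len(nRepeats), function(r) {
          tr <- sample.int(n, round(0.7 * n))
          te <- setdiff(seq_len(n), tr)
          ft <- .annTrain(X[tr, , drop = FALSE], y[tr], h, learningRate,
                          momentum, epochs)
          if (is.null(ft)) return(Inf)
          .annLoss(ft$weights, ft$biases, X[te, , drop = FALSE], y[te])
        }, numeric(1)))
      }, numeric(1))
      hidden <- hiddenSizes[which.min(scores)]
    }
    nDiverged <- 0
    best <- NULL; bestLoss <- Inf
    for (r in seq_len(nRestarts)) {
      ft <- .annTrain(X, y, hidden, learningRate, momentum, epochs)
      if (is.null(ft)) { nDiverged <- nDiverged + 1; next }
      if (ft$loss < bestLoss) { bestLoss <- ft$loss; best <- ft }
    }
    if (nDiverged > 0)
      message(sprintf("%d of %d restarts diverged", nDiverged, nRestarts))
    if (is.null(best)) stop("all training restarts diverged")
    annModelNew(ncol(X), hidden, best$weights, best$biases,
                covariateNames = design@covariateNames,
                center = design@center, scale = design@scale)
  })
}

#' Fit an ensemble of seeded network refits
#'
#' Refits \code{\link{fitAnn}} under different seeds (optionally on
#' bootstrap resamples) so predictions carry an ensemble spread; this is the
#' uncertainty attached to network surfaces, since the network itself is
#' deterministic.
#'
#' @inheritParams fitAnn
#' @param nMembers ensemble size.
#' @param bootstrap resample rows with replacement per member.
#' @param ... passed to \code{\link{fitAnn}}.
#' @return an \linkS4class{AnnEnsemble}.
#' @export
fitAnnEnsemble <- function(design, y, nMembers = 5L, bootstrap = FALSE,
                           seed = 1L, ...) {
  if (nMembers == 1)
    warning("ensemble of size 1: predictive sd will be 0 by convention")
  models <- lapply(seq_len(nMembers), function(k) {
    dk <- design; yk <- y
    if (bootstrap) {
      idx <- withr::with_seed(stageSeed(seed, paste0("boot", k)),
                              sample.int(length(y), replace = TRUE))
      dk <- subsetDesign(design, rows = idx); yk <- y[idx]
    }
    fitAnn(dk, yk, seed = stageSeed(seed, paste0("member", k)), ...)
  })
  new("AnnEnsemble", models = models)
}

#' @describeIn fitAnn predict with a single network; \code{X} raw covariate
#'   scale, standardized internally.
#' @param object fitted model.
#' @param X raw covariate matrix.
#' @param coords ignored (the network is non-spatial).
#' @param ... unused.
#' @export
setMethod("predictModel", "AnnModel",
function(object, X, coords = NULL, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object@layerSizes[1])
    stop(sprintf("expected %d input column(s), got %d",
                 object@layerSizes[1], ncol(X)))
  Xs <- standardizeColumns(X, object@center, object@scale)$values
  .annForwardMat(object@weights, object@biases, Xs)$out
})

#' @describeIn fitAnn predict with an ensemble; returns mean across members,
#'   or with \code{se = TRUE} a list with the across-member mean and sd
#'   (sd 0 for a single member).
#' @param se logical, also return across-member sd.
#' @export
setMethod("predictModel", "AnnEnsemble",
function(object, X, coords = NULL, se = FALSE, ...) {
  P <- vapply(object@models, function(m) predictModel(m, X),
              numeric(nrow(as.matrix(X))))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  mu <- rowMeans(P)
  if (!se) return(mu)
  sdv <- if (ncol(P) > 1) apply(P, 1, stats::sd) else rep(0, nrow(P))
  list(mean = mu, sd = sdv)
})
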
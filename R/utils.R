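#' @importFrom withr with_seed
#' @importFrom stats rnorm runif rbinom fft nextn optim sd quantile lm
NULL

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# Derive a per-stage 32-bit seed as a pure function of (master seed, stage
# name); stable across platforms, independent of earlier stages.
stageSeed <- function(masterSeed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(masterSeed) * 7919 + h) %% 2147480009)
}

# Column z-score standardization with stored constants; zero-variance
# columns scale by 1 to stay finite.
standardizeColumns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  list(values = Xs, center = center, scale = scale)
}

popVar <- function(x) mean((x - mean(x))^2)
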
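# Shared fixtures, all generated in code.

# Small synthetic world: stack + truth + displaced clusters.
makeWorld <- function(seed = 11, nRows = 40, nCols = 40, nFields = 3,
                      beta = NULL, spatialVariance = 0.3,
                      rangeM = 10000, nClusters = 150, respondents = 25,
                      link = "logit") {
  if (is.null(beta))
    beta <- c(-0.2, rep_len(c(0.8, -0.5, 0.3), nFields))
  grid <- gridSpecNew(nRows, nCols)
  stack <- genCovariateFields(grid, nFields, corrLength = 8000, seed = seed)
  truth <- genLatentSurface(stack, beta, spatialVariance, rangeM,
                            link = link, seed = seed + 1)
  urban <- urbanMaskFromLayer(stack[[1]])
  cl <- sampleClusters(truth, nClusters, urban, respondents,
                       seed = seed + 2)
  cl <- displaceClusters(cl, seed = seed + 3)
  list(grid = grid, stack = stack, truth = truth, urban = urban,
       clusters = cl)
}

# Build a DesignMatrix directly from a plain matrix (already model-ready:
# identity standardization), with coordinates.
makeDesign <- function(X, coords = NULL, ids = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  if (is.null(coords)) coords <- matrix(0, nrow(X), 2)
  if (is.null(ids)) ids <- sprintf("cl%04d", seq_len(nrow(X)))
  p <- ncol(X)
  new("DesignMatrix", clusterIds = ids, covariateNames = colnames(X),
      values = X, coords = coords, extractionMethod = "buffer_mean",
      bufferRadii = c(urban = 2000, rural = 5000), mcDraws = 0L,
      center = stats::setNames(rep(0, p), colnames(X)),
      scale = stats::setNames(rep(1, p), colnames(X)))
}

# Bare cluster table with reported == true coordinates (pre-displacement).
makeBareClusters <- function(n, stratum = "rural", seed = 1) {
  withr::with_seed(seed, {
    d <- data.frame(
      id = sprintf("cl%05d", seq_len(n)),
      true_x = runif(n, 0, 5e4), true_y = runif(n, 0, 5e4),
      stratum = rep(stratum, length.out = n), flagged_far = FALSE,
      n_respondents = 25L, n_positive = 10L, indicator = "ind",
      stringsAsFactors = FALSE)
    d$x <- d$true_x; d$y <- d$true_y
    new("ClusterSet", data = d[, clustermaps:::.cluster_cols])
  })
}

# Simulate a GP regression dataset at cluster level with exact Matern
# covariance (dense Cholesky): the reference generative model for
# parameter-recovery checks. Returns list(design, coords, y, beta, ...).
simGPData <- function(n, beta, sigmaV2, rangeM, sigmaE2, seed,
                      domain = 50000) {
  withr::with_seed(seed, {
    coords <- cbind(runif(n, 0, domain), runif(n, 0, domain))
    p <- length(beta) - 1
    X <- matrix(rnorm(n * p), n, p)
    D <- as.matrix(dist(coords))
    v <- if (sigmaV2 > 0) {
      S <- maternCov(D, sigmaV2, rangeM)
      diag(S) <- sigmaV2 + 1e-8
      as.numeric(t(chol(S)) %*% rnorm(n))
    } else numeric(n)
    y <- as.numeric(cbind(1, X) %*% beta) + v + rnorm(n, 0, sqrt(sigmaE2))
    list(design = makeDesign(X, coords), coords = coords, y = y,
         X = X, D = D, beta = beta)
  })
}
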
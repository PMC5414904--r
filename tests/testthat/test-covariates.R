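# Buffer extraction, design-matrix assembly, VIF filtering, jackknife
# covariate selection.

test_that("buffer mean honours constants, symmetry and stratum radii", {
  g <- gridSpecNew(60, 60)
  cst <- covariateStackNew(list(rasterLayerNew(g, 3.2, "c")))
  cl <- data.frame(id = "a", x = 30500, y = 30500, stratum = "urban")
  expect_equal(unname(bufferMean(cst, cl)), 3.2)

  # linear ramp f(x, y) = x / 1000: disc symmetry about the centre
  xy <- cellCenter(g, row(matrix(0, 60, 60)), col(matrix(0, 60, 60)))
  ramp <- covariateStackNew(list(
    rasterLayerNew(g, matrix(xy[, 1] / 1000, 60, 60), "ramp")))
  v <- bufferMean(ramp, cl)
  expect_lt(abs(v - 30.5), 1)             # one cell-width tolerance

  # rural buffer covers ~ (5/2)^2 more cells than urban
  nUrb <- nrow(clustermaps:::.cellsInDisc(g, 30500, 30500, 2000))
  nRur <- nrow(clustermaps:::.cellsInDisc(g, 30500, 30500, 5000))
  expect_lt(abs(nRur / nUrb - 25 / 4), 25 / 4 * 0.1)

  # layer order invariance
  two <- covariateStackNew(list(ramp[[1]], cst[[1]]))
  rev2 <- covariateStackNew(list(cst[[1]], ramp[[1]]))
  expect_equal(bufferMean(two, cl)[["ramp"]],
               bufferMean(rev2, cl)[["ramp"]])

  # empty buffer: nearest non-missing cell fallback
  far <- data.frame(id = "b", x = -1e5, y = -1e5, stratum = "urban")
  expect_equal(unname(bufferMean(cst, far)), 3.2)
})

test_that("Monte Carlo buffer draws converge to the buffer mean", {
  g <- gridSpecNew(60, 60)
  xy <- cellCenter(g, row(matrix(0, 60, 60)), col(matrix(0, 60, 60)))
  st <- covariateStackNew(list(
    rasterLayerNew(g, matrix(xy[, 1] / 1000, 60, 60), "ramp"),
    rasterLayerNew(g, 7, "const")))
  cl <- data.frame(id = "a", x = 30500, y = 30500, stratum = "rural")

  m <- bufferMonteCarlo(st, cl, nDraws = 2000, seed = 5)
  expect_true(all(m[, "const"] == 7))
  bm <- bufferMean(st, cl)[["ramp"]]
  se <- sd(m[, "ramp"]) / sqrt(2000)
  expect_lt(abs(mean(m[, "ramp"]) - bm), 2 * se + 0.05)
  expect_identical(m, bufferMonteCarlo(st, cl, nDraws = 2000, seed = 5))
})

test_that("design matrix has expected shape, standardization, modes", {
  w <- makeWorld(nClusters = 30, nRows = 30, nCols = 30, nFields = 2)
  dm <- buildDesignMatrix(w$stack, w$clusters)
  expect_equal(dim(dm@values), c(30L, 2L))
  expect_true(all(abs(colMeans(dm@values)) < 1e-9))
  expect_true(all(abs(apply(dm@values, 2, sd) - 1) < 1e-9))
  expect_equal(rawValues(dm),
               sweep(sweep(dm@values, 2, dm@scale, "*"), 2, dm@center, "+"))

  rep_ <- buildDesignMatrix(w$stack, w$clusters, method = "buffer_mc",
                            nDraws = 10, mcMode = "replicate", seed = 2)
  expect_equal(nrow(rep_@values), 300L)
  expect_equal(unname(table(rep_@clusterIds)[1]), 10L)

  avg <- buildDesignMatrix(w$stack, w$clusters, method = "buffer_mc",
                           nDraws = 10, mcMode = "average", seed = 2)
  expect_equal(nrow(avg@values), 30L)
})

test_that("VIF matches closed forms and flags exact collinearity", {
  # columns orthogonal to each other and to the intercept -> VIF 1
  set.seed(30)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200, 3))))[, 2:4]
  expect_equal(unname(computeVif(makeDesign(Q))), rep(1, 3),
               tolerance = 1e-10)

  # two columns with exact sample correlation 0.8 -> both VIF = 1/(1-0.64)
  set.seed(31)
  Z <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 2), 100, 2))))[, 2:3]
  X <- cbind(a = Z[, 1], b = 0.8 * Z[, 1] + sqrt(1 - 0.64) * Z[, 2])
  v <- computeVif(makeDesign(X))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)

  dup <- cbind(a = Z[, 1], b = Z[, 1])
  expect_true(all(is.infinite(computeVif(makeDesign(dup)))))
})

test_that("VIF agrees with an explicit normal-equations oracle", {
  set.seed(41)
  n <- 200
  L <- matrix(rnorm(25), 5, 5); L[upper.tri(L)] <- 0
  X <- matrix(rnorm(n * 5), n, 5) %*% t(L)
  colnames(X) <- paste0("c", 1:5)
  v <- computeVif(makeDesign(X))
  for (j in 1:5) {
    Z <- cbind(1, X[, -j])
    bh <- solve(t(Z) %*% Z, t(Z) %*% X[, j])       # normal equations
    res <- X[, j] - Z %*% bh
    r2 <- 1 - sum(res^2) / sum((X[, j] - mean(X[, j]))^2)
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("iterative VIF filter removes the smallest sufficient set", {
  set.seed(51)
  n <- 300
  Z <- matrix(rnorm(n * 3), n, 3)
  # c3 nearly duplicates c1; c2 independent: removing c3 (or c1) suffices
  X <- cbind(c1 = Z[, 1], c2 = Z[, 2], c3 = Z[, 1] + 0.1 * Z[, 3])
  fl <- vifFilter(makeDesign(X), threshold = 3)
  expect_lt(max(computeVif(fl$design)), 3)
  # brute force: smallest removal subset achieving all VIF < 3
  best <- Inf
  for (k in 0:2) for (rm in combn(3, k, simplify = FALSE)) {
    keep <- setdiff(1:3, rm)
    if (length(keep) == 0) next
    if (length(keep) == 1 || max(computeVif(X[, keep, drop = FALSE])) < 3)
      best <- min(best, k)
  }
  expect_equal(length(fl$report@removedByVif), best)

  # already-clean design: identity, empty removal list
  ok <- vifFilter(makeDesign(Z), threshold = 3)
  expect_identical(ok$report@removedByVif, character())
  expect_identical(ok$design@values, makeDesign(Z)@values)

  # duplicated column: exactly one of the pair removed, survivor finite
  dup <- cbind(a = Z[, 1], b = Z[, 1], c = Z[, 2])
  fd <- vifFilter(makeDesign(dup))
  expect_equal(length(fd$report@removedByVif), 1L)
  expect_true(all(is.finite(computeVif(fd$design))))
})

test_that("jackknife selection drops a pure-noise covariate", {
  removedNoise <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)          # x2 pure noise
    y <- 0.2 + 0.5 * x1 + rnorm(n, 0, 0.3)
    d <- makeDesign(cbind(signal = x1, noise = x2))
    sel <- jackknifeSelect(d, y, seed = s)
    if (!"noise" %in% sel@finalCovariates) removedNoise <- removedNoise + 1L
    # the selected set never scores below the full-set baseline minus the
    # per-deletion tolerance
    nRemoved <- 2 - length(sel@finalCovariates)
    expect_gte(sel@finalScore,
               sel@baselineScore - 0.005 * max(1, nRemoved) - 1e-12)
  }
  expect_gte(removedNoise, 9L)
})

test_that("jackknife keeps equally informative covariates and singletons", {
  set.seed(61)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 0.1 + X %*% c(0.6, 0.6, 0.6) + rnorm(n, 0, 0.2)
  sel <- jackknifeSelect(makeDesign(X), as.numeric(y), seed = 3)
  expect_setequal(sel@finalCovariates, c("a", "b", "c"))

  one <- jackknifeSelect(makeDesign(X[, 1, drop = FALSE]), as.numeric(y),
                         seed = 3)
  expect_identical(one@finalCovariates, "a")
})
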
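# Synthetic survey-world generators: covariate fields, latent surfaces,
# cluster sampling and DHS-style displacement.

test_that("covariate fields are seeded, standardized and autocorrelated", {
  g <- gridSpecNew(50, 50)
  a <- genCovariateFields(g, 1, corrLength = 5000, seed = 7)
  b <- genCovariateFields(g, 1, corrLength = 5000, seed = 7)
  expect_identical(rasterValues(a[[1]]), rasterValues(b[[1]]))

  st <- genCovariateFields(g, 3, corrLength = 5000, seed = 7)
  for (ly in st@layers) {
    expect_lt(abs(mean(rasterValues(ly))), 0.1)
    expect_lt(abs(sd(rasterValues(ly)) - 1), 0.15)
  }

  # correlation length far beyond the extent: lag-1 autocorrelation -> 1
  big <- genCovariateFields(g, 1, corrLength = 50 * 50000 * 100, seed = 3)
  v <- rasterValues(big[[1]])
  lag1 <- cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))
  expect_gt(lag1, 0.95)

  expect_error(genCovariateFields(g, 1, corrLength = -1, seed = 1),
               "corrLength")
  # degenerate 1x1 grid: a single draw, no error
  one <- genCovariateFields(gridSpecNew(1, 1), 1, corrLength = 1000,
                            seed = 2)
  expect_equal(dim(rasterValues(one[[1]])), c(1L, 1L))
})

test_that("latent surface honours link, coefficients and spatial variance", {
  g <- gridSpecNew(40, 40)
  st <- genCovariateFields(g, 2, corrLength = 6000, seed = 5)

  flat <- genLatentSurface(st, c(0, 0, 0), 0, 10000, "logit", seed = 1)
  expect_equal(unique(as.vector(rasterValues(flat@latentSurface))), 0.5)

  const <- genLatentSurface(st, c(0.3, 0, 0), 0, 10000, "identity",
                            seed = 1)
  expect_equal(unique(as.vector(rasterValues(const@latentSurface))), 0.3)

  expect_error(genLatentSurface(st, c(0, 0, 0), 0, 1e4, "probit", seed = 1),
               "unknown link")

  # with zero spatial variance and identity link the surface is an exact
  # affine function of the layers (machine precision)
  aff <- genLatentSurface(st, c(0.5, 0.04, -0.03), 0, 1e4, "identity",
                          seed = 2)
  manual <- 0.5 + 0.04 * rasterValues(st[[1]]) - 0.03 * rasterValues(st[[2]])
  expect_equal(rasterValues(aff@latentSurface), pmin(pmax(manual, 0), 1),
               tolerance = 1e-14)
})

test_that("simulated Matern residual has the requested variance", {
  g <- gridSpecNew(100, 100)
  st <- genCovariateFields(g, 1, corrLength = 8000, seed = 9)
  tr <- genLatentSurface(st, c(0, 0.5), 1, 10000, "logit", seed = 13)
  p <- rasterValues(tr@latentSurface)
  eta <- log(p / (1 - p))
  resid <- eta - (0 + 0.5 * rasterValues(st[[1]]))
  expect_lt(abs(var(as.vector(resid)) - 1), 0.25)
})

test_that("cluster sampling reproduces the latent proportions", {
  g <- gridSpecNew(30, 30)
  st <- genCovariateFields(g, 1, corrLength = 5000, seed = 2)
  urban <- urbanMaskFromLayer(st[[1]])

  ones <- genLatentSurface(st, c(1.5, 0), 0, 1e4, "identity", seed = 1)
  cl <- sampleClusters(ones, 50, urban, 10, seed = 4)
  d <- clusterData(cl)
  expect_true(all(d$n_positive == d$n_respondents))

  p04 <- genLatentSurface(st, c(0.4, 0), 0, 1e4, "identity", seed = 1)
  cl <- sampleClusters(p04, 400, urban, 25, seed = 8)
  d <- clusterData(cl)
  expect_lt(abs(sum(d$n_positive) / sum(d$n_respondents) - 0.4), 0.025)

  expect_identical(clusterData(sampleClusters(p04, 20, urban, 25, seed = 3)),
                   clusterData(sampleClusters(p04, 20, urban, 25, seed = 3)))

  badMask <- rasterLayerNew(gridSpecNew(10, 10), 0, "urban")
  expect_error(sampleClusters(p04, 5, badMask, 10, seed = 1), "grid")
})

test_that("displacement respects stratum caps and uniform-radius law", {
  urb <- makeBareClusters(1000, "urban", seed = 21)
  du <- clusterData(displaceClusters(urb, seed = 22))
  dist <- sqrt((du$x - du$true_x)^2 + (du$y - du$true_y)^2)
  expect_true(all(dist <= 2000))
  # P(max of 1000 Uniform[0,2000] <= 1900) = 0.95^1000 ~ 5e-23
  expect_gt(max(dist), 1900)
  # uniform-radius rule: mean ~ L/2 within 3 standard errors
  se <- 2000 / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(dist) - 1000), 3 * se)
  expect_false(any(du$flagged_far))

  rur <- makeBareClusters(1000, "rural", seed = 23)
  dr <- clusterData(displaceClusters(rur, seed = 24))
  expect_identical(sum(dr$flagged_far), 10L)  # exactly 1% of 1000
  dist <- sqrt((dr$x - dr$true_x)^2 + (dr$y - dr$true_y)^2)
  expect_true(all(dist[!dr$flagged_far] <= 5000))
  expect_true(all(dist[dr$flagged_far] <= 10000))

  # empty rural stratum: no flags, no error
  mix <- makeBareClusters(40, "urban", seed = 25)
  expect_identical(sum(clusterData(displaceClusters(mix, 1))$flagged_far), 0L)
  empty <- makeBareClusters(2, "rural", seed = 26)
  empty@data <- empty@data[0, ]
  expect_identical(length(displaceClusters(empty, 1)), 0L)

  # displacing twice is refused: reported coordinates already moved
  expect_error(displaceClusters(displaceClusters(rur, 1), 2), "displaced")
})

test_that("ClusterSet validity enforces count and displacement invariants", {
  d <- clusterData(makeBareClusters(3, "rural"))
  bad <- d; bad$n_positive[2] <- 99L
  expect_error(new("ClusterSet", data = bad), "n_positive")
  bad <- d; bad$x[1] <- bad$true_x[1] + 6000
  expect_error(new("ClusterSet", data = bad), "cap")
})
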
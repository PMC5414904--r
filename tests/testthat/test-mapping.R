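# Prediction surfaces, uncertainty summaries, zonal aggregation.

test_that("surfaces evaluate models at cell centres and respect missing", {
  w <- makeWorld(nClusters = 60, nRows = 25, nCols = 25, nFields = 2)
  d <- clusterData(w$clusters)
  dm <- buildDesignMatrix(w$stack, w$clusters)
  y <- (d$n_positive / d$n_respondents)[match(dm@clusterIds, d$id)]
  m <- fitGP(dm, y)
  surf <- predictSurface(m, w$stack, modelId = "gp")
  expect_s4_class(surf, "PredictionSurface")
  mv <- rasterValues(surf@mean)
  expect_true(all(mv >= 0 & mv <= 1, na.rm = TRUE))
  expect_true(all(rasterValues(surf@sd) >= 0, na.rm = TRUE))

  # missing covariate cells -> missing output
  st2 <- w$stack
  v <- rasterValues(st2[[1]]); v[1, 1] <- NA
  st2@layers[[1]] <- rasterLayerNew(w$grid, v, layerNames(w$stack)[1])
  surf2 <- predictSurface(m, st2, modelId = "gp")
  expect_true(is.na(rasterValues(surf2@mean)[1, 1]))

  # missing required layer is named
  sub <- covariateStackNew(w$stack@layers[1])
  expect_error(predictSurface(m, sub), layerNames(w$stack)[2])

  # interdecile mode scales the sd layer by 2 * qnorm(0.9)
  idr <- predictSurface(m, w$stack, modelId = "gp", sdType = "interdecile")
  expect_equal(rasterValues(idr@sd),
               rasterValues(surf@sd) * 2 * qnorm(0.9), tolerance = 1e-12)
})

test_that("uncertainty grows away from the data", {
  sim <- simGPData(60, beta = c(0.5, 0.1), sigmaV2 = 0.2, rangeM = 8000,
                   sigmaE2 = 0.05, seed = 3, domain = 20000)
  m <- fitGP(sim$design, sim$y,
             fixedHyper = c(sigmaV2 = 0.2, rangeM = 8000, sigmaE2 = 0.05))
  # training region vs a far extrapolation strip
  nearC <- cbind(runif(50, 0, 20000), runif(50, 0, 20000))
  farC <- cbind(runif(50, 1e5, 1.2e5), runif(50, 1e5, 1.2e5))
  Xn <- matrix(0, 50, 1)
  sdNear <- predictModel(m, Xn, coords = nearC, se = TRUE)$sd
  sdFar <- predictModel(m, Xn, coords = farC, se = TRUE)$sd
  expect_gt(mean(sdFar), mean(sdNear))
})

test_that("constant fit over a constant stack gives a constant surface", {
  set.seed(2)
  g <- gridSpecNew(10, 10)
  st <- covariateStackNew(list(rasterLayerNew(g, 0.7, "c")))
  y <- rep(0.42, 40) + rnorm(40, 0, 1e-6)
  d <- makeDesign(matrix(0.7, 40, 1, dimnames = list(NULL, "c")),
                  cbind(runif(40, 0, 1e4), runif(40, 0, 1e4)))
  lin <- fitLinear(d, y)
  surf <- predictSurface(lin, st, modelId = "linear")
  expect_equal(unique(round(as.vector(rasterValues(surf@mean)), 6)), 0.42)
})

test_that("uncertainty summary counts pixels under thresholds", {
  g <- gridSpecNew(2, 2)
  mk <- function(sd) new("PredictionSurface",
                         mean = rasterLayerNew(g, 0.5, "mean_proportion"),
                         sd = rasterLayerNew(g, matrix(sd, 2, 2), "sd"),
                         modelId = "m", indicator = "i", sdType = "sd")
  expect_equal(summarizeUncertainty(mk(0.05), 0.1)$fraction, 1)
  s <- mk(c(0.05, 0.15, 0.25, 0.05))
  expect_equal(summarizeUncertainty(s, c(0.1, 0.2))$fraction, c(0.5, 0.75))
  fr <- summarizeUncertainty(s, c(0.05, 0.1, 0.2, 0.3))$fraction
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(summarizeUncertainty(s, c(0.2, 0.1)), "ascending")
})

test_that("zonal aggregation matches hand arithmetic", {
  g <- gridSpecNew(2, 2)
  surf <- new("PredictionSurface",
              mean = rasterLayerNew(g, matrix(c(0.2, 0.2, 0.6, 0.6), 2, 2),
                                    "mean_proportion"),
              sd = rasterLayerNew(g, matrix(c(0.1, 0.1, 0.2, 0.2), 2, 2),
                                  "sd"),
              modelId = "m", indicator = "i", sdType = "sd")
  zones <- rasterLayerNew(g, matrix(c(1, 1, 2, 2), 2, 2), "zones")
  tab <- aggregateToUnits(surf, zones)
  expect_equal(tab$mean, c(0.2, 0.6))
  expect_equal(tab$sd_rms, c(0.1, 0.2))

  # single zone covering all -> global mean
  all1 <- rasterLayerNew(g, 1, "zones")
  expect_equal(aggregateToUnits(surf, all1)$mean,
               mean(rasterValues(surf@mean)))

  # population-weighted 4-cell worked example
  wts <- rasterLayerNew(g, matrix(c(1, 3, 2, 4), 2, 2), "pop")
  tw <- aggregateToUnits(surf, zones, wts)
  expect_equal(tw$mean, c((1 * 0.2 + 3 * 0.2) / 4,
                          (2 * 0.6 + 4 * 0.6) / 6))
  # uniform weights reproduce unweighted means
  u <- rasterLayerNew(g, 5, "u")
  expect_equal(aggregateToUnits(surf, zones, u)$mean, tab$mean,
               tolerance = 1e-12)

  # zone 0 excluded; no labelled overlap -> empty table
  z0 <- rasterLayerNew(g, 0, "zones")
  expect_equal(nrow(aggregateToUnits(surf, z0)), 0L)
})

test_that("surfaces round-trip through paired ASCII grids", {
  g <- gridSpecNew(5, 5)
  set.seed(1)
  surf <- new("PredictionSurface",
              mean = rasterLayerNew(g, matrix(runif(25), 5, 5),
                                    "mean_proportion"),
              sd = rasterLayerNew(g, matrix(runif(25, 0, 0.2), 5, 5), "sd"),
              modelId = "m", indicator = "i", sdType = "sd")
  pre <- tempfile()
  writeSurface(surf, pre)
  expect_identical(rasterValues(readRaster(paste0(pre, "_mean.asc"))),
                   rasterValues(surf@mean))
  expect_identical(rasterValues(readRaster(paste0(pre, "_sd.asc"))),
                   rasterValues(surf@sd))
})
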
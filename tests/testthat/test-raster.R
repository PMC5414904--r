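# Grid geometry, ASCII-grid raster I/O, cluster CSV I/O, resampling.

test_that("grid geometry round-trips cells and points", {
  g <- gridSpecNew(10, 20, originX = 1000, originY = 11000, cellSize = 1000)
  ctr <- cellCenter(g, c(1, 10), c(1, 20))
  expect_equal(ctr[1, ], c(x = 1500, y = 10500))
  expect_equal(ctr[2, ], c(x = 20500, y = 1500))
  cells <- xyToCell(g, ctr[, 1], ctr[, 2])
  expect_equal(cells[, "row"], c(1L, 10L))
  expect_equal(cells[, "col"], c(1L, 20L))
  expect_true(all(is.na(xyToCell(g, -5000, 5000))))
  expect_equal(xyToCellClamped(g, -5000, 5000), cbind(row = 7L, col = 1L))
})

test_that("ASCII grid write-then-read round-trips values and grid exactly", {
  g <- gridSpecNew(10, 10, originX = 12345.5, originY = 99999.25,
                   cellSize = 250)
  set.seed(4)
  v <- matrix(rnorm(100), 10, 10)
  v[3, 7] <- NA
  ly <- rasterLayerNew(g, v, "elevation")
  f <- tempfile(fileext = ".asc")
  writeRaster(ly, f)
  back <- readRaster(f)
  expect_identical(rasterValues(back), v)
  expect_equal(gridSpec(back)@originX, g@originX)
  expect_equal(gridSpec(back)@originY, g@originY)
  expect_equal(gridSpec(back)@cellSize, g@cellSize)
  expect_identical(gridSpec(back)@nRows, g@nRows)
  expect_true(is.na(rasterValues(back)[3, 7]))
})

test_that("malformed raster headers are reported by field name", {
  f <- tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize abc", "1 2", "3 4"), f)
  expect_error(readRaster(f), "cellsize")
  writeLines(c("ncols 2", "nrows 2", "cellsize 10", "1 2", "3 4"), f)
  expect_error(readRaster(f), "xllcorner")
  expect_error(readRaster(tempfile()), "no such file")
})

test_that("cluster CSV round-trips and rejects invalid rows", {
  w <- makeWorld(nClusters = 5, nRows = 20, nCols = 20)
  f <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".csv")
  writeClusters(w$clusters, f, truthPath = ft)
  back <- readClusters(f, truthPath = ft)
  expect_equal(clusterData(back), clusterData(w$clusters),
               tolerance = 1e-12)

  d <- read.csv(f)
  d$n_positive[3] <- d$n_respondents[3] + 5
  f2 <- tempfile(fileext = ".csv")
  write.csv(d, f2, row.names = FALSE)
  expect_error(readClusters(f2), "row 3")

  d2 <- read.csv(f)
  d2$stratum <- NULL
  write.csv(d2, f2, row.names = FALSE)
  expect_error(readClusters(f2), "stratum")
})

test_that("truth parameters round-trip through JSON", {
  w <- makeWorld(nClusters = 5, nRows = 15, nCols = 15)
  f <- tempfile(fileext = ".json")
  writeTruthJson(w$truth, f)
  tr <- readTruthJson(f)
  expect_equal(tr$beta, w$truth@beta)
  expect_equal(tr$range_m, w$truth@rangeParam)
  expect_identical(tr$link, w$truth@link)
})

test_that("resampling: identity, aggregation mean, constants", {
  g <- gridSpecNew(4, 4, cellSize = 500)
  set.seed(2)
  ly <- rasterLayerNew(g, matrix(rnorm(16), 4, 4), "f")
  expect_identical(rasterValues(resampleToGrid(ly, g, "nearest")),
                   rasterValues(ly))

  # 2x2 [[1,3],[5,7]] aggregated to one cell -> mean 4
  g2 <- gridSpecNew(2, 2, cellSize = 500)
  src <- rasterLayerNew(g2, matrix(c(1, 5, 3, 7), 2, 2), "f")
  tgt <- gridSpecNew(1, 1, originY = 1000, cellSize = 1000)
  expect_equal(as.vector(
    rasterValues(resampleToGrid(src, tgt, "mean_aggregate"))), 4)

  cst <- rasterLayerNew(g, 3.2, "c")
  for (m in c("nearest", "mean_aggregate", "bilinear")) {
    out <- resampleToGrid(cst, gridSpecNew(2, 2, originY = 2000,
                                           cellSize = 1000), m)
    expect_true(all(rasterValues(out) == 3.2), info = m)
  }

  dis <- gridSpecNew(4, 4, originX = 1e6, originY = 1e6, cellSize = 500)
  expect_error(resampleToGrid(ly, dis, "nearest"), "disjoint")
})

test_that("mean_aggregate conserves the global mean on nested grids", {
  fine <- gridSpecNew(8, 8, cellSize = 500)
  set.seed(9)
  ly <- rasterLayerNew(fine, matrix(rnorm(64), 8, 8), "f")
  coarse <- gridSpecNew(4, 4, originY = 4000, cellSize = 1000)
  agg <- resampleToGrid(ly, coarse, "mean_aggregate")
  expect_equal(mean(rasterValues(agg)), mean(rasterValues(ly)),
               tolerance = 1e-14)
})

test_that("bilinear reproduces a linear ramp away from edges and skips NA", {
  g <- gridSpecNew(10, 10, cellSize = 1000)
  xy <- cellCenter(g, row(matrix(0, 10, 10)), col(matrix(0, 10, 10)))
  ramp <- rasterLayerNew(g, matrix(xy[, 1] / 1000, 10, 10), "ramp")
  tgt <- gridSpecNew(5, 5, originX = 2000, originY = 8000, cellSize = 800)
  out <- resampleToGrid(ramp, tgt, "bilinear")
  ctr <- cellCenter(tgt, row(rasterValues(out)), col(rasterValues(out)))
  expect_equal(as.vector(rasterValues(out)), ctr[, 1] / 1000,
               tolerance = 1e-12)

  v <- rasterValues(ramp); v[, ] <- NA
  allna <- rasterLayerNew(g, v, "na")
  expect_true(all(is.na(rasterValues(resampleToGrid(allna, tgt,
                                                    "bilinear")))))
})
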
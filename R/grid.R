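#' @include AllClasses.R
NULL

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param originX,originY top-left corner in metres.
#' @param cellSize cell edge length in metres; 1000 gives the canonical
#'   1x1 km analysis grid.
#' @param crsTag free-text tag for the planar CRS.
#' @return a \linkS4class{GridSpec}.
#' @examples
#' gridSpecNew(50, 50, cellSize = 1000)
#' @export
gridSpecNew <- function(nRows, nCols, originX = 0, originY = nRows * cellSize,
                        cellSize = 1000, crsTag = "planar-metres") {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      originX = as.numeric(originX), originY = as.numeric(originY),
      cellSize = as.numeric(cellSize), crsTag = crsTag)
}

#' Construct a RasterLayer
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param values numeric matrix (nRows x nCols) or a single value recycled.
#' @param name layer name.
#' @return a \linkS4class{RasterLayer}.
#' @export
rasterLayerNew <- function(grid, values, name = "layer") {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  storage.mode(values) <- "double"
  new("RasterLayer", grid = grid, name = name, values = values)
}

#' Construct a CovariateStack
#'
#' @param layers list of \linkS4class{RasterLayer}s on one shared grid.
#' @return a \linkS4class{CovariateStack}.
#' @export
covariateStackNew <- function(layers) {
  stopifnot(length(layers) >= 1L)
  new("CovariateStack", grid = layers[[1]]@grid, layers = layers)
}

# ---- grid geometry -------------------------------------------------------
# Pixel-centre registration: cell (r, c), 1-based, has centre
#   x = originX + (c - 1/2) * cellSize,  y = originY - (r - 1/2) * cellSize.

#' Cell centre coordinates
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param rows,cols 1-based row/column indices (vectorized).
#' @return two-column matrix of (x, y) in metres.
#' @export
cellCenter <- function(grid, rows, cols) {
  rows <- as.vector(rows); cols <- as.vector(cols)
  cbind(x = grid@originX + (cols - 0.5) * grid@cellSize,
        y = grid@originY - (rows - 0.5) * grid@cellSize)
}

#' Cell index containing a point
#'
#' Half-open cell coverage: a point on a shared edge belongs to the cell to
#' its right/below-the-top convention, matching the grid definition. Points
#' outside the extent return NA indices.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param x,y planar coordinates in metres (vectorized).
#' @return two-column integer matrix (row, col), NA outside the extent.
#' @export
xyToCell <- function(grid, x, y) {
  col <- floor((x - grid@originX) / grid@cellSize) + 1
  row <- floor((grid@originY - y) / grid@cellSize) + 1
  # top edge belongs to row 1 (y = originY maps to row 0 + 1 after floor of 0)
  row[y == grid@originY] <- 1L
  bad <- row < 1 | row > grid@nRows | col < 1 | col > grid@nCols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Nearest in-extent cell for a point
#'
#' Like \code{\link{xyToCell}} but clamping out-of-extent points to the
#' nearest boundary cell instead of returning NA.
#'
#' @inheritParams xyToCell
#' @return two-column integer matrix (row, col).
#' @export
xyToCellClamped <- function(grid, x, y) {
  col <- floor((x - grid@originX) / grid@cellSize) + 1
  row <- floor((grid@originY - y) / grid@cellSize) + 1
  row[y == grid@originY] <- 1L
  cbind(row = as.integer(pmin(pmax(row, 1), grid@nRows)),
        col = as.integer(pmin(pmax(col, 1), grid@nCols)))
}

#' Extent of a grid
#' @param grid a \linkS4class{GridSpec}.
#' @return named numeric c(xmin, xmax, ymin, ymax).
#' @export
gridExtent <- function(grid) {
  c(xmin = grid@originX,
    xmax = grid@originX + grid@nCols * grid@cellSize,
    ymin = grid@originY - grid@nRows * grid@cellSize,
    ymax = grid@originY)
}

#' Stack values at given cells
#'
#' Reads every layer of a stack at (row, col) index pairs.
#'
#' @param stack a \linkS4class{CovariateStack}.
#' @param cells two-column (row, col) matrix.
#' @return numeric matrix, one column per layer, named.
#' @export
stackValuesAt <- function(stack, cells) {
  idx <- cbind(cells[, 1], cells[, 2])
  out <- vapply(stack@layers, function(l) l@values[idx],
                numeric(nrow(idx)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- layerNames(stack)
  out
}
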
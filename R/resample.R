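#' @include AllClasses.R grid.R
NULL

#' Resample a raster layer onto a target grid
#'
#' Harmonizes heterogeneous layers to a common analysis grid (canonically
#' 1x1 km). Three methods:
#' \describe{
#'   \item{nearest}{value of the source cell containing each target cell
#'     centre.}
#'   \item{mean_aggregate}{mean of all source cells whose centres fall inside
#'     each target cell (for aggregating finer grids).}
#'   \item{bilinear}{bilinear interpolation between the four surrounding
#'     source cell centres, ignoring missing neighbours by renormalizing
#'     weights; all neighbours missing gives a missing cell.}
#' }
#' Missing values propagate in all methods.
#'
#' @param layer source \linkS4class{RasterLayer}.
#' @param target target \linkS4class{GridSpec}; must overlap the source.
#' @param method "nearest", "mean_aggregate" or "bilinear".
#' @return a \linkS4class{RasterLayer} on \code{target}.
#' @export
resampleToGrid <- function(layer, target,
                           method = c("nearest", "mean_aggregate",
                                      "bilinear")) {
  method <- match.arg(method)
  src <- layer@grid
  es <- gridExtent(src); et <- gridExtent(target)
  if (es["xmin"] >= et["xmax"] || et["xmin"] >= es["xmax"] ||
      es["ymin"] >= et["ymax"] || et["ymin"] >= es["ymax"])
    stop("source and target extents are disjoint")
  nr <- target@nRows; nc <- target@nCols
  out <- matrix(NA_real_, nr, nc)
  if (method == "mean_aggregate") {
    # bin source cell centres into target cells
    sc <- cellCenter(src, row(layer@values), col(layer@values))
    cells <- xyToCell(target, sc[, 1], sc[, 2])
    keep <- !is.na(cells[, 1]) & !is.na(as.vector(layer@values))
    if (any(keep)) {
      idx <- (cells[keep, 2] - 1) * nr + cells[keep, 1]
      sums <- tapply(as.vector(layer@values)[keep], idx, sum)
      cnts <- tapply(rep(1, sum(keep)), idx, sum)
      out[as.integer(names(sums))] <- sums / cnts
    }
  } else {
    tc <- cellCenter(target, row(out), col(out))
    if (method == "nearest") {
      cells <- xyToCell(src, tc[, 1], tc[, 2])
      ok <- !is.na(cells[, 1])
      vals <- rep(NA_real_, nrow(tc))
      vals[ok] <- layer@values[cells[ok, , drop = FALSE]]
      out[] <- vals
    } else {                                    # bilinear
      # fractional position in source cell-centre coordinates
      gx <- (tc[, 1] - src@originX) / src@cellSize - 0.5
      gy <- (src@originY - tc[, 2]) / src@cellSize - 0.5
      c0 <- floor(gx); r0 <- floor(gy)
      fx <- gx - c0; fy <- gy - r0
      vals <- rep(NA_real_, nrow(tc))
      num <- rep(0, nrow(tc)); den <- rep(0, nrow(tc))
      for (dc in 0:1) for (dr in 0:1) {
        rr <- r0 + dr + 1; cc <- c0 + dc + 1
        w <- (if (dc == 0) 1 - fx else fx) * (if (dr == 0) 1 - fy else fy)
        inb <- rr >= 1 & rr <= src@nRows & cc >= 1 & cc <= src@nCols
        v <- rep(NA_real_, nrow(tc))
        v[inb] <- layer@values[cbind(rr[inb], cc[inb])]
        use <- !is.na(v) & w > 0
        num[use] <- num[use] + w[use] * v[use]
        den[use] <- den[use] + w[use]
      }
      vals[den > 0] <- num[den > 0] / den[den > 0]
      out[] <- vals
    }
  }
  rasterLayerNew(target, out, layer@name)
}
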
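#' @include AllClasses.R grid.R
NULL

#' Read a raster layer from an ESRI ASCII grid file
#'
#' Parses the standard six-field header (ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize, optional NODATA_value) followed by
#' space-separated values in row order, top row first. NODATA cells become
#' NA. A malformed or absent header field raises an error naming it.
#'
#' @param path file path.
#' @param name layer name for the result (default: file name sans extension).
#' @return a \linkS4class{RasterLayer}.
#' @export
readRaster <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  nHdr <- 0
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      val <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(val))
        stop(sprintf("malformed header field '%s': value '%s' is not numeric",
                     tok[1], tok[2]))
      hdr[[tolower(tok[1])]] <- val
      nHdr <- nHdr + 1
    } else break
  }
  for (f in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[f]])) stop(sprintf("missing header field '%s'", f))
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("missing header field 'xllcorner'")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("missing header field 'yllcorner'")
  if (hdr$cellsize <= 0) stop("malformed header field 'cellsize': must be > 0")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  body <- paste(lines[(nHdr + 1):length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  if (!is.null(hdr$nodata_value))
    vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nr, nc, byrow = TRUE)
  grid <- gridSpecNew(nr, nc, originX = xll, originY = yll + nr * cs,
                      cellSize = cs)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  rasterLayerNew(grid, m, name)
}

#' Write a raster layer as an ESRI ASCII grid file
#'
#' Full-precision decimal text; NA cells written as the NODATA value.
#' Write-then-read round-trips both values and the grid geometry exactly.
#'
#' @param layer a \linkS4class{RasterLayer}.
#' @param path output path.
#' @param nodata NODATA sentinel written for NA cells.
#' @return invisibly, the path.
#' @export
writeRaster <- function(layer, path, nodata = -9999) {
  g <- layer@grid
  hdr <- c(sprintf("ncols %d", g@nCols),
           sprintf("nrows %d", g@nRows),
           sprintf("xllcorner %.10g", g@originX),
           sprintf("yllcorner %.10g", g@originY - g@nRows * g@cellSize),
           sprintf("cellsize %.10g", g@cellSize),
           sprintf("NODATA_value %.10g", nodata))
  v <- layer@values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a cluster table as CSV
#'
#' Columns \code{id,x,y,stratum,flagged_far,n_respondents,n_positive,
#' indicator}, with x, y the reported (displaced) coordinates. True
#' coordinates, which exist for evaluation only, go to an optional companion
#' file with columns \code{id,true_x,true_y}.
#'
#' @param clusters a \linkS4class{ClusterSet}.
#' @param path output CSV path.
#' @param truthPath optional path for the true-coordinate companion file.
#' @return invisibly, the path.
#' @export
writeClusters <- function(clusters, path, truthPath = NULL) {
  d <- clusterData(clusters)
  out <- d[, c("id", "x", "y", "stratum", "flagged_far", "n_respondents",
               "n_positive", "indicator")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truthPath))
    utils::write.csv(d[, c("id", "true_x", "true_y")], truthPath,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cluster table from CSV
#'
#' Validates the dialect written by \code{\link{writeClusters}}: any missing
#' required column is reported by name, and a row with n_positive >
#' n_respondents is rejected with its row number. Observed proportions are
#' always recomputed from counts, never trusted from the file. Without a
#' companion truth file the true coordinates are set equal to the reported
#' ones (displacement unknown).
#'
#' @param path CSV path.
#' @param truthPath optional companion CSV with id,true_x,true_y.
#' @return a \linkS4class{ClusterSet}.
#' @export
readClusters <- function(path, truthPath = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "x", "y", "stratum", "n_respondents", "n_positive",
           "indicator")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- which(d$n_positive > d$n_respondents | d$n_positive < 0)
  if (length(bad))
    stop(sprintf("n_positive outside [0, n_respondents] at row %d", bad[1]))
  if (is.null(d$flagged_far)) d$flagged_far <- FALSE
  d$flagged_far <- as.logical(d$flagged_far)
  d$id <- as.character(d$id)
  if (!is.null(truthPath)) {
    tr <- utils::read.csv(truthPath, stringsAsFactors = FALSE)
    m <- match(d$id, as.character(tr$id))
    if (anyNA(m)) stop("truth file does not cover all cluster ids")
    d$true_x <- tr$true_x[m]; d$true_y <- tr$true_y[m]
  } else {
    d$true_x <- d$x; d$true_y <- d$y
  }
  new("ClusterSet", data = d[, .cluster_cols])
}

#' Write / read synthetic truth parameters as JSON
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path JSON path.
#' @return invisibly, the path.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(
    list(beta = truth@beta, spatial_variance = truth@spatialVariance,
         range_m = truth@rangeParam, nugget = truth@nugget,
         link = truth@link, seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJson
#' @return for \code{readTruthJson}, a named list of truth parameters.
#' @export
readTruthJson <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
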
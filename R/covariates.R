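#' @include AllClasses.R grid.R utils.R
NULL

.defaultBufferRadii <- c(urban = 2000, rural = 5000)

# cells of `grid` whose centres lie within `radius` of (x, y); returns a
# (row, col) matrix, possibly empty
.cellsInDisc <- function(grid, x, y, radius) {
  cs <- grid@cellSize
  cmin <- max(1L, floor((x - radius - grid@originX) / cs) + 1L)
  cmax <- min(grid@nCols, ceiling((x + radius - grid@originX) / cs))
  rmin <- max(1L, floor((grid@originY - y - radius) / cs) + 1L)
  rmax <- min(grid@nRows, ceiling((grid@originY - y + radius) / cs))
  if (cmin > cmax || rmin > rmax)
    return(cbind(row = integer(), col = integer()))
  rr <- rmin:rmax; cc <- cmin:cmax
  cells <- cbind(row = rep(rr, times = length(cc)),
                 col = rep(cc, each = length(rr)))
  ctr <- cellCenter(grid, cells[, 1], cells[, 2])
  cells[(ctr[, 1] - x)^2 + (ctr[, 2] - y)^2 <= radius^2, , drop = FALSE]
}

# nearest non-missing cell to (x, y) for one layer matrix, or NA
.nearestNonMissing <- function(grid, values, x, y) {
  ok <- which(!is.na(values))
  if (!length(ok)) return(NA_real_)
  rr <- ((ok - 1) %% grid@nRows) + 1
  cc <- ((ok - 1) %/% grid@nRows) + 1
  ctr <- cellCenter(grid, rr, cc)
  values[ok[which.min((ctr[, 1] - x)^2 + (ctr[, 2] - y)^2)]]
}

#' Buffer-mean covariate extraction at one cluster
#'
#' Displacement-aware extraction: for each layer, the mean over all cells
#' whose centres lie within the cluster's stratum radius (2 km urban, 5 km
#' rural by default) of the reported location, ignoring missing cells. If no
#' cell centre falls in the buffer the nearest non-missing cell value is
#' used. A layer with no usable value yields NA, flagging the cluster for
#' removal downstream.
#'
#' @param stack a \linkS4class{CovariateStack}.
#' @param cluster one-row data.frame (a row of \code{clusterData()}).
#' @param radii named buffer radii in metres per stratum.
#' @return named numeric vector, one value per layer.
#' @export
bufferMean <- function(stack, cluster, radii = .defaultBufferRadii) {
  grid <- stack@grid
  radius <- radii[[cluster$stratum]]
  cells <- .cellsInDisc(grid, cluster$x, cluster$y, radius)
  out <- vapply(stack@layers, function(ly) {
    if (nrow(cells)) {
      v <- ly@values[cells]
      if (any(!is.na(v))) return(mean(v, na.rm = TRUE))
    }
    .nearestNonMissing(grid, ly@values, cluster$x, cluster$y)
  }, numeric(1))
  names(out) <- layerNames(stack)
  out
}

#' Monte Carlo buffer extraction at one cluster
#'
#' Draws uniform points in the stratum-radius disc around the reported
#' location and reads each layer by nearest-cell lookup at each point — the
#' replicate-sample treatment of displacement used for nonlinear models.
#'
#' @inheritParams bufferMean
#' @param nDraws number of uniform draws in the disc (>= 1).
#' @param seed integer seed; row order is reproducible.
#' @return nDraws x nLayers matrix, columns named by layer.
#' @export
bufferMonteCarlo <- function(stack, cluster, nDraws, seed,
                             radii = .defaultBufferRadii) {
  stopifnot(nDraws >= 1)
  grid <- stack@grid
  radius <- radii[[cluster$stratum]]
  withr::with_seed(as.integer(seed), {
    r <- radius * sqrt(stats::runif(nDraws))   # uniform over the disc
    th <- stats::runif(nDraws, 0, 2 * pi)
    px <- cluster$x + r * cos(th)
    py <- cluster$y + r * sin(th)
    cells <- xyToCellClamped(grid, px, py)
    vals <- stackValuesAt(stack, cells)
    # missing lookups fall back to the nearest non-missing cell
    for (j in seq_len(ncol(vals))) {
      bad <- which(is.na(vals[, j]))
      for (k in bad)
        vals[k, j] <- .nearestNonMissing(grid, stack@layers[[j]]@values,
                                         px[k], py[k])
    }
    vals
  })
}

#' Build the cluster-by-covariate design matrix
#'
#' One standardized row per cluster from buffer means (method
#' "buffer_mean"), or from Monte Carlo draws averaged per cluster
#' (\code{mcMode = "average"}) or kept as replicate rows with the cluster id
#' repeated (\code{mcMode = "replicate"}, the neural-network path). Columns
#' are z-score standardized; the constants are stored for later grid
#' prediction. Clusters for which any layer fails extraction are dropped
#' (with a message).
#'
#' @param stack a \linkS4class{CovariateStack}.
#' @param clusters a \linkS4class{ClusterSet}.
#' @param method "buffer_mean" or "buffer_mc".
#' @param nDraws Monte Carlo draws per cluster (buffer_mc only).
#' @param mcMode "average" or "replicate" (buffer_mc only).
#' @param seed integer seed for the Monte Carlo draws.
#' @param radii named buffer radii in metres per stratum.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(stack, clusters,
                              method = c("buffer_mean", "buffer_mc"),
                              nDraws = 50L, mcMode = c("average", "replicate"),
                              seed = 1L, radii = .defaultBufferRadii) {
  method <- match.arg(method)
  mcMode <- match.arg(mcMode)
  d <- clusterData(clusters)
  if (!nrow(d)) stop("empty cluster set")
  nms <- layerNames(stack)
  rows <- list(); ids <- character(); coords <- list()
  for (i in seq_len(nrow(d))) {
    cl <- d[i, ]
    if (method == "buffer_mean") {
      v <- bufferMean(stack, cl, radii)
      if (anyNA(v)) { message(sprintf("dropping cluster %s: extraction failed",
                                      cl$id)); next }
      rows[[length(rows) + 1]] <- matrix(v, 1)
      ids <- c(ids, cl$id)
      coords[[length(coords) + 1]] <- cbind(cl$x, cl$y)
    } else {
      m <- bufferMonteCarlo(stack, cl, nDraws, stageSeed(seed, cl$id), radii)
      if (anyNA(m)) { message(sprintf("dropping cluster %s: extraction failed",
                                      cl$id)); next }
      if (mcMode == "average") {
        rows[[length(rows) + 1]] <- matrix(colMeans(m), 1)
        ids <- c(ids, cl$id)
        coords[[length(coords) + 1]] <- cbind(cl$x, cl$y)
      } else {
        rows[[length(rows) + 1]] <- m
        ids <- c(ids, rep(cl$id, nDraws))
        coords[[length(coords) + 1]] <-
          cbind(rep(cl$x, nDraws), rep(cl$y, nDraws))
      }
    }
  }
  if (!length(rows)) stop("no usable clusters after extraction")
  X <- do.call(rbind, rows)
  colnames(X) <- nms
  st <- standardizeColumns(X)
  new("DesignMatrix", clusterIds = ids, covariateNames = nms,
      values = st$values, coords = do.call(rbind, coords),
      extractionMethod = method, bufferRadii = radii,
      mcDraws = if (method == "buffer_mc") as.integer(nDraws) else 0L,
      center = st$center, scale = st$scale)
}

#' Variance inflation factors of a design matrix
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j comes from the least-squares
#' regression of column j on all other columns plus an intercept. Exact
#' collinearity is reported as +Inf.
#'
#' @param design a \linkS4class{DesignMatrix} or plain numeric matrix.
#' @return named numeric vector of VIFs.
#' @export
computeVif <- function(design) {
  X <- if (is(design, "DesignMatrix")) design@values else design
  p <- ncol(X)
  if (p < 2) { v <- rep(1, p); names(v) <- colnames(X); return(v) }
  out <- numeric(p)
  for (j in seq_len(p)) {
    yj <- X[, j]; Z <- cbind(1, X[, -j, drop = FALSE])
    qr_ <- qr(Z)
    res <- qr.resid(qr_, yj)
    sst <- sum((yj - mean(yj))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  out
}

#' Iterative VIF filtering
#'
#' Greedy multicollinearity filter: repeatedly removes the covariate with
#' the largest VIF (ties broken by column order), recomputing after each
#' removal, until all remaining VIFs fall below the threshold (default 3). A
#' single covariate always passes.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param threshold keep covariates with VIF strictly below this (> 1).
#' @return list with the filtered \code{design} and a
#'   \linkS4class{SelectionReport} (jackknife fields empty).
#' @export
vifFilter <- function(design, threshold = 3) {
  stopifnot(threshold > 1)
  keep <- seq_along(design@covariateNames)
  removed <- character()
  repeat {
    if (length(keep) <= 1) break
    v <- computeVif(design@values[, keep, drop = FALSE])
    if (max(v) < threshold) break
    worst <- which.max(v)          # first max wins on ties
    removed <- c(removed, design@covariateNames[keep[worst]])
    keep <- keep[-worst]
  }
  vif <- computeVif(design@values[, keep, drop = FALSE])
  filtered <- subsetDesign(design, cols = keep)
  rep <- new("SelectionReport", vifTable = vif, removedByVif = removed,
             jackknifeScores = numeric(), baselineScore = NA_real_,
             finalScore = NA_real_,
             finalCovariates = design@covariateNames[keep])
  list(design = filtered, report = rep)
}

#' Subset a design matrix by rows and/or columns
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param rows,cols index vectors (default: all).
#' @return a \linkS4class{DesignMatrix}.
#' @export
subsetDesign <- function(design, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(design@values))
  if (is.null(cols)) cols <- seq_len(ncol(design@values))
  new("DesignMatrix",
      clusterIds = design@clusterIds[rows],
      covariateNames = design@covariateNames[cols],
      values = design@values[rows, cols, drop = FALSE],
      coords = design@coords[rows, , drop = FALSE],
      extractionMethod = design@extractionMethod,
      bufferRadii = design@bufferRadii, mcDraws = design@mcDraws,
      center = design@center[cols], scale = design@scale[cols])
}

#' Jackknife covariate sensitivity selection
#'
#' Greedy backward leave-one-covariate-out selection on top of a
#' VIF-filtered design. The score of a covariate set is the mean validation
#' explained variance (pseudo-R2) over \code{nRepeats} random 70/30 splits,
#' fitted with the supplied model (plain linear by default). At each round,
#' every single-covariate deletion is rescored on the same splits; the best
#' deletion is applied whenever it does not reduce the score by more than
#' \code{tolerance} (so covariates contributing nothing are pruned even when
#' their removal is score-neutral), and the procedure repeats until every
#' remaining covariate's removal would cost more than the tolerance.
#' Deterministic given the seed. With fewer than two covariates the input is
#' returned unchanged.
#'
#' @param design a \linkS4class{DesignMatrix} (already VIF-filtered).
#' @param responses numeric vector of cluster proportions, one per row.
#' @param fitFun function(X, y) -> model with a \code{predictModel} method;
#'   default fits \code{\link{fitLinear}}.
#' @param nRepeats random 70/30 splits used for scoring (default 10).
#' @param seed integer seed.
#' @param tolerance minimum score improvement to accept a deletion.
#' @return a \linkS4class{SelectionReport} with \code{finalCovariates},
#'   baseline and leave-one-out scores of the final round.
#' @export
jackknifeSelect <- function(design, responses, fitFun = NULL, nRepeats = 10L,
                            seed = 1L, tolerance = 0.005) {
  if (is.null(fitFun))
    fitFun <- function(X, y) .fitLinearRaw(X, y)
  p0 <- length(design@covariateNames)
  if (p0 < 2)
    return(new("SelectionReport", vifTable = computeVif(design),
               removedByVif = character(), jackknifeScores = numeric(),
               baselineScore = NA_real_, finalScore = NA_real_,
               finalCovariates = design@covariateNames))
  n <- nrow(design@values)
  splits <- withr::with_seed(as.integer(seed), lapply(seq_len(nRepeats),
    function(i) sample.int(n, round(0.7 * n))))
  score <- function(cols) {
    mean(vapply(splits, function(tr) {
      te <- setdiff(seq_len(n), tr)
      Xtr <- design@values[tr, cols, drop = FALSE]
      Xte <- design@values[te, cols, drop = FALSE]
      m <- fitFun(Xtr, responses[tr])
      pr <- predictModel(m, Xte)
      vo <- popVar(responses[te])
      if (vo == 0) return(NA_real_)
      1 - mean((responses[te] - pr)^2) / vo
    }, numeric(1)), na.rm = TRUE)
  }
  keep <- seq_len(p0)
  base <- score(keep)
  current <- base
  jk <- numeric()
  repeat {
    if (length(keep) < 2) break
    dropScores <- vapply(seq_along(keep),
                         function(j) score(keep[-j]), numeric(1))
    names(dropScores) <- design@covariateNames[keep]
    jk <- dropScores
    best <- which.max(dropScores)
    if (dropScores[best] > current - tolerance) {
      keep <- keep[-best]
      current <- dropScores[best]
    } else break
  }
  new("SelectionReport", vifTable = computeVif(design),
      removedByVif = character(), jackknifeScores = jk,
      baselineScore = base, finalScore = current,
      finalCovariates = design@covariateNames[keep])
}

#' Write a design matrix as CSV / read it back
#'
#' First column is the cluster id; remaining columns are the standardized
#' covariate values.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeDesignCsv <- function(design, path) {
  df <- data.frame(cluster_id = design@clusterIds,
                   x = design@coords[, 1], y = design@coords[, 2],
                   design@values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a selection report as JSON
#' @param report a \linkS4class{SelectionReport}.
#' @param path JSON path.
#' @return invisibly, the path.
#' @export
writeSelectionJson <- function(report, path) {
  jsonlite::write_json(
    list(vif_table = as.list(report@vifTable),
         removed_by_vif = report@removedByVif,
         jackknife_scores = as.list(report@jackknifeScores),
         baseline_score = report@baselineScore,
         final_score = report@finalScore,
         final_covariates = report@finalCovariates),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
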
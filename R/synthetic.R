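#' @include AllClasses.R grid.R utils.R
NULL

# FFT convolution of a matrix with an isotropic kernel given as a function of
# distance in cells; wrap-around (torus) boundary, which is harmless for
# synthetic worlds and keeps the field stationary.
.fftSmooth <- function(noise, kernelFun) {
  nr <- nrow(noise); nc <- ncol(noise)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  d <- sqrt(outer(dr^2, dc^2, "+"))
  k <- kernelFun(d)
  Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) /
    (nr * nc)
}

#' Generate standardized Gaussian covariate fields
#'
#' Simulates stationary Gaussian random fields with isotropic Gaussian
#' correlation of the given length by Gaussian-kernel filtering of white
#' noise (spectral convolution), then standardizes each layer to sample mean
#' 0 and sample sd 1 — emulating a suite of assembled covariate grids.
#' Optionally appends deterministic distance-to-random-points layers
#' (standardized), mimicking accessibility/distance covariates.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param nFields number of random fields (>= 1).
#' @param corrLength correlation length in metres (> 0).
#' @param seed integer seed; output is bit-reproducible.
#' @param nDistanceFields number of extra distance-to-point layers.
#' @param names optional layer names (default cov1, cov2, ...).
#' @return a \linkS4class{CovariateStack}.
#' @examples
#' st <- genCovariateFields(gridSpecNew(30, 30), 2, corrLength = 5000, seed = 1)
#' layerNames(st)
#' @export
genCovariateFields <- function(grid, nFields, corrLength, seed,
                               nDistanceFields = 0, names = NULL) {
  stopifnot(nFields >= 1)
  if (corrLength <= 0) stop("corrLength must be > 0")
  nr <- grid@nRows; nc <- grid@nCols
  # Gaussian kernel sd ell/sqrt(2) (in cells) so the smoothed field has
  # correlation exp(-d^2 / (2 ell^2)) at distance d.
  s <- corrLength / grid@cellSize / sqrt(2)
  layers <- withr::with_seed(as.integer(seed), {
    out <- vector("list", nFields + nDistanceFields)
    for (j in seq_len(nFields)) {
      z <- matrix(stats::rnorm(nr * nc), nr, nc)
      f <- if (nr == 1L && nc == 1L) z else
        .fftSmooth(z, function(d) exp(-d^2 / (2 * s^2)))
      f <- (f - mean(f)) / max(stats::sd(f), .Machine$double.eps)
      if (nr * nc == 1L) f <- z     # single-cell grid: a single draw
      out[[j]] <- f
    }
    if (nDistanceFields > 0) {
      ext <- gridExtent(grid)
      cc <- cellCenter(grid, row(out[[1]]), col(out[[1]]))
      for (j in seq_len(nDistanceFields)) {
        px <- stats::runif(1, ext["xmin"], ext["xmax"])
        py <- stats::runif(1, ext["ymin"], ext["ymax"])
        d <- matrix(sqrt((cc[, 1] - px)^2 + (cc[, 2] - py)^2), nr, nc)
        sdd <- stats::sd(d)
        out[[nFields + j]] <-
          if (is.finite(sdd) && sdd > 0) (d - mean(d)) / sdd else d - mean(d)
      }
    }
    out
  })
  if (is.null(names))
    names <- paste0("cov", seq_along(layers))
  covariateStackNew(Map(function(v, nm) rasterLayerNew(grid, v, nm),
                        layers, names))
}

# Simulate a zero-mean Matern nu = 1 Gaussian field on a grid by 2-D
# circulant embedding (FFT of the covariance kernel on an enlarged torus,
# negative eigenvalues clamped to zero). Returns an nr x nc matrix with
# marginal variance ~ sigma2.
.simMaternField <- function(grid, sigma2, rangeM) {
  nr <- grid@nRows; nc <- grid@nCols
  if (sigma2 <= 0) return(matrix(0, nr, nc))
  M <- stats::nextn(2 * nr, 2); N <- stats::nextn(2 * nc, 2)
  dr <- pmin(0:(M - 1), M - 0:(M - 1)) * grid@cellSize
  dc <- pmin(0:(N - 1), N - 0:(N - 1)) * grid@cellSize
  d <- sqrt(outer(dr^2, dc^2, "+"))
  C <- maternCov(d, sigma2, rangeM)
  lam <- Re(stats::fft(C))
  lam[lam < 0] <- 0
  eps <- matrix(complex(real = stats::rnorm(M * N),
                        imaginary = stats::rnorm(M * N)), M, N)
  # Re part of FFT(sqrt(lam) * complex white noise)/sqrt(MN) has covariance C
  f <- stats::fft(sqrt(lam) * eps) / sqrt(M * N)
  Re(f)[seq_len(nr), seq_len(nc)]
}

#' Generate a latent indicator surface with spatial residual
#'
#' Builds the true proportion surface p(s) = g^-1(beta0 + sum_i beta_i
#' cov_i(s) + v(s)), where v is a zero-mean stationary Matern nu = 1 Gaussian
#' field with the given marginal variance and practical range, and g is the
#' logit (default) or identity link; identity-linked values are clamped to
#' [0, 1]. All parameters are recorded in the returned truth object.
#'
#' @param stack a \linkS4class{CovariateStack} of covariate layers.
#' @param beta numeric vector, intercept first, one coefficient per layer.
#' @param spatialVariance marginal variance of v (>= 0; 0 disables it).
#' @param rangeParam practical range of v in metres.
#' @param link "logit" or "identity".
#' @param seed integer seed.
#' @param nugget observation-level noise variance recorded for reference.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
genLatentSurface <- function(stack, beta, spatialVariance, rangeParam,
                             link = "logit", seed = 1L, nugget = 0) {
  if (!link %in% c("logit", "identity"))
    stop(sprintf("unknown link '%s' (use 'logit' or 'identity')", link))
  if (length(beta) != length(stack@layers) + 1L)
    stop("beta must have length n_layers + 1 (intercept first)")
  grid <- stack@grid
  eta <- matrix(beta[1], grid@nRows, grid@nCols)
  for (j in seq_along(stack@layers))
    eta <- eta + beta[j + 1] * stack@layers[[j]]@values
  v <- withr::with_seed(as.integer(seed),
                        .simMaternField(grid, spatialVariance, rangeParam))
  eta <- eta + v
  p <- if (link == "logit") logistic(eta) else pmin(pmax(eta, 0), 1)
  new("SyntheticTruth", beta = as.numeric(beta),
      spatialVariance = as.numeric(spatialVariance),
      rangeParam = as.numeric(rangeParam), nugget = as.numeric(nugget),
      link = link, seed = as.integer(seed),
      latentSurface = rasterLayerNew(grid, p, "latent_proportion"))
}

#' Default urban mask from an urbanization covariate
#'
#' The urban/rural status of real survey clusters comes from national census
#' geography, which has no synthetic counterpart; by default the top quartile
#' of a designated urbanization layer is declared urban.
#'
#' @param layer a \linkS4class{RasterLayer} acting as urbanization score.
#' @param quantile cells above this quantile are urban (default 0.75).
#' @return a 0/1 \linkS4class{RasterLayer} named "urban".
#' @export
urbanMaskFromLayer <- function(layer, quantile = 0.75) {
  thr <- stats::quantile(layer@values, quantile, na.rm = TRUE, names = FALSE)
  rasterLayerNew(layer@grid, (layer@values > thr) * 1, "urban")
}

#' Sample survey clusters from a synthetic truth
#'
#' Cluster true locations are drawn uniformly over the non-missing cells of
#' the latent surface (a uniform point inside the chosen cell); the stratum
#' comes from the urban mask at that cell; the outcome count is
#' Binomial(respondents, p(true cell)). Reported coordinates start equal to
#' the true ones — displacement is a separate step
#' (\code{\link{displaceClusters}}).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nClusters number of clusters (>= 1).
#' @param urbanMask 0/1 \linkS4class{RasterLayer} on the same grid.
#' @param respondentsPerCluster respondents sampled in each cluster (>= 1).
#' @param seed integer seed.
#' @param indicator indicator name recorded on every cluster.
#' @return a \linkS4class{ClusterSet}.
#' @export
sampleClusters <- function(truth, nClusters, urbanMask,
                           respondentsPerCluster, seed,
                           indicator = "indicator") {
  stopifnot(nClusters >= 1, respondentsPerCluster >= 1)
  surf <- truth@latentSurface
  grid <- surf@grid
  if (!identical(urbanMask@grid, grid))
    stop("urbanMask grid does not match the truth surface grid")
  ok <- which(!is.na(surf@values))
  if (!length(ok)) stop("latent surface has no non-missing cells")
  d <- withr::with_seed(as.integer(seed), {
    cells <- ok[sample.int(length(ok), nClusters, replace = TRUE)]
    rr <- ((cells - 1) %% grid@nRows) + 1
    cc <- ((cells - 1) %/% grid@nRows) + 1
    # uniform point inside the chosen cell
    x <- grid@originX + (cc - 1 + stats::runif(nClusters)) * grid@cellSize
    y <- grid@originY - (rr - 1 + stats::runif(nClusters)) * grid@cellSize
    p <- surf@values[cbind(rr, cc)]
    urb <- urbanMask@values[cbind(rr, cc)]
    data.frame(
      id = sprintf("cl%04d", seq_len(nClusters)),
      true_x = x, true_y = y, x = x, y = y,
      stratum = ifelse(!is.na(urb) & urb > 0, "urban", "rural"),
      flagged_far = FALSE,
      n_respondents = as.integer(respondentsPerCluster),
      n_positive = stats::rbinom(nClusters, respondentsPerCluster, p),
      indicator = indicator,
      stringsAsFactors = FALSE)
  })
  new("ClusterSet", data = d)
}

#' Displace cluster coordinates DHS-style
#'
#' Applies the anonymity displacement used for released survey cluster
#' coordinates: each reported location is moved by a uniform angle and a
#' radius drawn Uniform[0, L], with L = 2000 m for urban clusters and 5000 m
#' for rural ones; a simple random 1 percent of the rural clusters (count
#' rounded to the nearest integer) is flagged and displaced with L =
#' 10000 m. True coordinates are preserved for evaluation only.
#'
#' @param clusters a \linkS4class{ClusterSet} with reported == true
#'   coordinates.
#' @param seed integer seed.
#' @return a \linkS4class{ClusterSet} with displaced reported coordinates and
#'   \code{flagged_far} set on the far-displaced rural subset.
#' @export
displaceClusters <- function(clusters, seed) {
  d <- clusterData(clusters)
  if (!nrow(d)) return(clusters)
  if (any(d$x != d$true_x | d$y != d$true_y))
    stop("clusters appear already displaced (reported != true coordinates)")
  d <- withr::with_seed(as.integer(seed), {
    rural <- which(d$stratum == "rural")
    nFar <- max(0L, as.integer(round(0.01 * length(rural))))
    far <- if (nFar > 0) sample(rural, nFar) else integer()
    d$flagged_far <- FALSE
    d$flagged_far[far] <- TRUE
    L <- ifelse(d$stratum == "urban", 2000,
                ifelse(d$flagged_far, 10000, 5000))
    theta <- stats::runif(nrow(d), 0, 2 * pi)
    r <- stats::runif(nrow(d), 0, L)
    d$x <- d$true_x + r * cos(theta)
    d$y <- d$true_y + r * sin(theta)
    d
  })
  new("ClusterSet", data = d)
}
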
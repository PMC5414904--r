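#' @include AllClasses.R synthetic.R raster-io.R covariates.R gp.R ann.R
#' @include baselines.R validation.R mapping.R
NULL

#' Default configuration for the bundled synthetic demo
#'
#' A complete synthetic country at desk scale: a 60 x 60 km area on the
#' 1x1 km analysis grid, four spatially autocorrelated covariate fields
#' (10 km correlation length) plus one distance-to-point accessibility
#' layer, a logit-linked latent indicator surface with a Matern nu = 1
#' spatial residual (variance 0.3 on the logit scale, 15 km practical
#' range), 400 clusters of 25 respondents each, urban stratum from the top
#' quartile of the first covariate (standing in for census urbanization),
#' and DHS-style displacement. Any entry can be overridden.
#'
#' @param overrides named list merged over the defaults (nested lists merge
#'   one level deep).
#' @return a nested configuration list.
#' @export
demoConfig <- function(overrides = list()) {
  cfg <- list(
    indicator = "female_literacy",
    seed = 2026L,
    output_dir = NULL,
    simulate = list(
      n_rows = 60L, n_cols = 60L, cell_size = 1000,
      n_fields = 4L, n_distance_fields = 1L, corr_length = 10000,
      beta = c(-0.5, 0.8, -0.6, 0.4, 0.3, 0),
      spatial_variance = 0.3, range_m = 15000, link = "logit",
      n_clusters = 400L, respondents = 25L, urban_quantile = 0.75),
    extraction = list(method = "buffer_mean", mc_draws = 30L,
                      mc_mode = "average"),
    selection = list(vif_threshold = 3, jackknife = FALSE,
                     n_repeats = 10L),
    split = list(scheme = "train_test_70_30", n_repeats = 10L,
                 large_threshold = 2000L),
    models = c("mean", "linear", "gp", "ann"),
    gp = list(n_starts = 3L),
    ann = list(hidden_sizes = c(4L, 8L), epochs = 300L,
               learning_rate = 0.5, momentum = 0.9, n_repeats = 3L,
               n_restarts = 2L, ensemble = 3L))
  for (k in names(overrides)) {
    if (is.list(overrides[[k]]) && is.list(cfg[[k]]))
      cfg[[k]] <- utils::modifyList(cfg[[k]], overrides[[k]])
    else cfg[[k]] <- overrides[[k]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror \code{\link{demoConfig}}; missing keys take the demo
#' defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readConfig <- function(path) demoConfig(yaml::read_yaml(path))

#' Simulate and write a complete synthetic country
#'
#' Runs the synthetic-survey generator under the configuration and writes
#' every artifact to a dataset directory: covariate layers (ASCII grids),
#' the urban mask, the true latent surface, truth parameters (JSON), and
#' the displaced cluster CSV with its true-coordinate companion.
#'
#' @param config configuration list (see \code{\link{demoConfig}}).
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (stack, urbanMask,
#'   truth, clusters) and the directory.
#' @export
simulateDemo <- function(config = demoConfig(), dir = tempfile("demo")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$simulate
  seed <- config$seed
  grid <- gridSpecNew(sc$n_rows, sc$n_cols, cellSize = sc$cell_size)
  stack <- genCovariateFields(grid, sc$n_fields, sc$corr_length,
                              seed = stageSeed(seed, "covariates"),
                              nDistanceFields = sc$n_distance_fields)
  truth <- genLatentSurface(stack, sc$beta, sc$spatial_variance, sc$range_m,
                            link = sc$link,
                            seed = stageSeed(seed, "latent"))
  urban <- urbanMaskFromLayer(stack[[1]], sc$urban_quantile)
  clusters <- sampleClusters(truth, sc$n_clusters, urban, sc$respondents,
                             seed = stageSeed(seed, "clusters"),
                             indicator = config$indicator)
  clusters <- displaceClusters(clusters, seed = stageSeed(seed, "displace"))
  for (ly in stack@layers)
    writeRaster(ly, file.path(dir, paste0(ly@name, ".asc")))
  writeRaster(urban, file.path(dir, "urban_mask.asc"))
  writeRaster(truth@latentSurface, file.path(dir, "true_surface.asc"))
  writeTruthJson(truth, file.path(dir, "truth.json"))
  writeClusters(clusters, file.path(dir, "clusters.csv"),
                truthPath = file.path(dir, "clusters_true_xy.csv"))
  invisible(list(stack = stack, urbanMask = urban, truth = truth,
                 clusters = clusters, dir = dir))
}

.fitOne <- function(kind, design, y, coords, config, seed) {
  switch(kind,
    mean = fitMeanBaseline(y),
    linear = fitLinear(design, y),
    gp = fitGP(design, y, coords = coords, nStarts = config$gp$n_starts),
    ann = {
      a <- config$ann
      fitAnnEnsemble(design, y, nMembers = a$ensemble,
                     seed = stageSeed(seed, "ann"),
                     hiddenSizes = a$hidden_sizes, epochs = a$epochs,
                     learningRate = a$learning_rate, momentum = a$momentum,
                     nRepeats = a$n_repeats, nRestarts = a$n_restarts)
    },
    stop(sprintf("unknown model kind '%s'", kind)))
}

.predictOne <- function(model, X, coords) {
  if (is(model, "SpatialGPModel")) predictModel(model, X, coords = coords)
  else if (is(model, "MeanModel")) predictModel(model, NULL, n = nrow(X))
  else predictModel(model, X)
}

.log <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> extract -> select -> fit ->
#' validate -> predict -> report under one master seed, validating each
#' stage's inputs against the class invariants before running. Per-stage
#' seeds are a pure function of (master seed, stage name), so reruns with
#' the same configuration are bit-reproducible. Artifacts written to the
#' run directory: the dataset (when simulated), the design matrix, the
#' selection report, per-model validation reports and surfaces, the
#' comparison table (CSV + JSON) and a machine-readable run manifest.
#'
#' @param config configuration list (see \code{\link{demoConfig}}); set
#'   \code{config$output_dir} or pass \code{dir}.
#' @param dir run directory (default from config, else a tempdir).
#' @return invisibly, a list with the comparison table, the reports, the
#'   fitted models, the surfaces, the best model id and the run directory.
#' @export
runPipeline <- function(config = demoConfig(), dir = NULL) {
  if (is.null(dir)) dir <- config$output_dir
  if (is.null(dir)) dir <- tempfile("run")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stopifnot(length(seed) == 1, is.finite(seed))

  # -- data stage: simulate or load ---------------------------------------
  if (!is.null(config$simulate)) {
    .log("simulate", "generating synthetic dataset")
    sim <- simulateDemo(config, file.path(dir, "dataset"))
    stack <- sim$stack; clusters <- sim$clusters
  } else {
    .log("load", "reading rasters from %s", config$paths$rasters)
    files <- sort(list.files(config$paths$rasters, "\\.asc$",
                             full.names = TRUE))
    files <- files[!grepl("urban_mask|true_surface", files)]
    stack <- covariateStackNew(lapply(files, readRaster))
    clusters <- readClusters(config$paths$clusters)
  }
  validObject(stack); validObject(clusters)
  d <- clusterData(clusters)
  if (!nrow(d)) stop("stage extract: empty cluster set")

  # -- extraction ----------------------------------------------------------
  .log("extract", "%s extraction at %d clusters", config$extraction$method,
       nrow(d))
  design <- buildDesignMatrix(stack, clusters,
                              method = config$extraction$method,
                              nDraws = config$extraction$mc_draws,
                              mcMode = config$extraction$mc_mode,
                              seed = stageSeed(seed, "extract"))
  validObject(design)
  y <- (d$n_positive / d$n_respondents)[match(design@clusterIds, d$id)]
  writeDesignCsv(design, file.path(dir, "design_matrix.csv"))

  # -- covariate selection -------------------------------------------------
  .log("select", "VIF filter at threshold %g", config$selection$vif_threshold)
  vf <- vifFilter(design, config$selection$vif_threshold)
  design <- vf$design
  report <- vf$report
  if (isTRUE(config$selection$jackknife)) {
    .log("select", "jackknife sensitivity over %d covariates",
         length(design@covariateNames))
    jk <- jackknifeSelect(design, y, nRepeats = config$selection$n_repeats,
                          seed = stageSeed(seed, "jackknife"))
    keep <- match(jk@finalCovariates, design@covariateNames)
    design <- subsetDesign(design, cols = keep)
    report <- new("SelectionReport", vifTable = jk@vifTable,
                  removedByVif = vf$report@removedByVif,
                  jackknifeScores = jk@jackknifeScores,
                  baselineScore = jk@baselineScore,
                  finalScore = jk@finalScore,
                  finalCovariates = jk@finalCovariates)
  }
  writeSelectionJson(report, file.path(dir, "selection_report.json"))

  # -- split ---------------------------------------------------------------
  n <- nrow(design@values)
  scheme <- config$split$scheme
  if (n > config$split$large_threshold) scheme <- "train_valid_test_60_20_20"
  sp <- splitData(n, scheme, nRepeats = 1L,
                  seed = stageSeed(seed, "split"))[[1]]
  .log("split", "%s: %s", scheme,
       paste(vapply(sp, length, integer(1)), collapse = "/"))

  # -- fit + validate ------------------------------------------------------
  tr <- sp$train; te <- sp$test
  Xraw <- rawValues(design)
  reports <- list(); models <- list()
  for (kind in config$models) {
    .log("fit", "model '%s' on %d training rows", kind, length(tr))
    dtr <- subsetDesign(design, rows = tr)
    m <- .fitOne(kind, dtr, y[tr], design@coords[tr, , drop = FALSE],
                 config, seed)
    pr <- .predictOne(m, Xraw[te, , drop = FALSE],
                      design@coords[te, , drop = FALSE])
    rep_ <- computeMetrics(y[te], pr, modelId = kind)
    validObject(rep_)
    models[[kind]] <- m
    reports[[kind]] <- rep_
    .log("validate", "'%s': exp.var %.3f rmse %.4f", kind, rep_@expVar,
         rep_@rmse)
  }

  # -- report + predict ----------------------------------------------------
  table <- compareModels(reports, label = "synthetic",
                         parameter = config$indicator)
  writeComparison(table, file.path(dir, "comparison.csv"),
                  file.path(dir, "comparison.json"))
  best <- selectBest(reports)
  .log("report", "best model: %s", best)
  surfaces <- list()
  for (kind in intersect(c("gp", "ann"), names(models))) {
    .log("predict", "surface for '%s'", kind)
    surf <- predictSurface(models[[kind]], stack, modelId = kind,
                           indicator = config$indicator)
    validObject(surf)
    surfaces[[kind]] <- surf
    writeSurface(surf, file.path(dir, paste0("surface_", kind)))
  }
  manifest <- list(config = config, scheme = scheme,
                   stage_seeds = sapply(c("covariates", "latent", "clusters",
                                          "displace", "extract", "jackknife",
                                          "split", "ann"),
                                        function(s) stageSeed(seed, s)),
                   n_design_rows = n, best_model = best,
                   package_version = as.character(
                     utils::packageVersion("clustermaps")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(list(table = table, reports = reports, models = models,
                 surfaces = surfaces, best = best, design = design,
                 responses = y, split = sp, dir = dir))
}

#' Serialize a fitted model to JSON (+ CSV sidecar)
#'
#' Coefficients, hyperparameters and input scalings go to
#' \code{<prefix>.json}; spatial models also write their training state
#' (coordinates, whitened residual solve) to \code{<prefix>_state.csv} so a
#' reader can rebuild predictions. Format field "clustermaps-model/1".
#'
#' @param model a fitted model.
#' @param prefix output path prefix.
#' @return invisibly, the JSON path.
#' @export
saveModelJson <- function(model, prefix) {
  path <- paste0(prefix, ".json")
  base <- list(format = "clustermaps-model/1", class = class(model)[1])
  if (is(model, "SpatialGPModel")) {
    st <- model@fitState
    utils::write.csv(data.frame(x = st$coords[, 1], y = st$coords[, 2],
                                alpha = st$alpha, y_obs = st$y),
                     paste0(prefix, "_state.csv"), row.names = FALSE)
    base <- c(base, list(beta = model@beta, sigma_v2 = model@sigmaV2,
                         range_m = model@rangeM, sigma_e2 = model@sigmaE2,
                         alpha = model@alpha,
                         covariates = model@covariateNames,
                         center = model@center, scale = model@scale,
                         log_lik = model@logLik))
  } else if (is(model, "AnnModel")) {
    base <- c(base, list(layer_sizes = model@layerSizes,
                         w1 = model@weights[[1]], w2 = model@weights[[2]],
                         b1 = model@biases[[1]], b2 = model@biases[[2]],
                         covariates = model@covariateNames,
                         center = model@center, scale = model@scale))
  } else if (is(model, "LinearModel")) {
    base <- c(base, list(beta = model@beta,
                         covariates = model@covariateNames,
                         center = model@center, scale = model@scale))
  } else if (is(model, "MeanModel")) {
    base <- c(base, list(mu = model@mu))
  }
  jsonlite::write_json(base, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
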
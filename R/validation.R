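#' @include AllClasses.R utils.R
NULL

#' Explained variance (pseudo-R2) from MSE and observed variance
#'
#' The validation pseudo-R2: 1 - MSE / var(obs), where var(obs) is the
#' population variance of the observed data — equivalently 1 - MSE /
#' MSE(trivial mean model). Reaches 1 only for a perfect predictor and is 0
#' for the trivial mean model evaluated in-sample.
#'
#' @param mse mean squared error of the model.
#' @param varObs population variance of the observations (the trivial
#'   model's MSE).
#' @return explained variance (<= 1), NA if \code{varObs} is 0.
#' @examples
#' pseudoR2(0.016, 0.065)   # 0.7538...
#' @export
pseudoR2 <- function(mse, varObs) {
  ifelse(varObs > 0, 1 - mse / varObs, NA_real_)
}

#' Validation metric suite for one model's predictions
#'
#' Computes the complete comparison-metric set on an evaluation subset:
#' MSE, RMSE, MAE, explained variance 1 - MSE/var(obs), the sign-preserving
#' bias (mean(pred) - mean(obs)) / sd(obs), and the trivial mean model's MSE
#' (= population variance of obs, evaluated in-sample on the same subset).
#' Population (divide-by-n) variance throughout, which makes the
#' trivial-model identity exp_var = 0 exact. Zero observed variance leaves
#' expVar and bias as NA sentinels (flagged with a warning).
#'
#' @param obs,pred numeric vectors of equal length >= 2 (proportions).
#' @param modelId label recorded in the report.
#' @return a \linkS4class{ValidationReport}.
#' @examples
#' computeMetrics(c(.2, .4, .6, .8), c(.3, .5, .7, .9))
#' @export
computeMetrics <- function(obs, pred, modelId = "model") {
  if (length(obs) != length(pred))
    stop(sprintf("length mismatch: %d observed vs %d predicted",
                 length(obs), length(pred)))
  if (length(obs) < 2) stop("need at least 2 evaluation pairs")
  err <- pred - obs
  mse <- mean(err^2)
  vo <- popVar(obs)
  if (vo == 0) {
    warning("observed values are all identical: expVar and bias undefined")
    ev <- NA_real_; bias <- NA_real_
  } else {
    ev <- 1 - mse / vo
    bias <- (mean(pred) - mean(obs)) / sqrt(vo)
  }
  new("ValidationReport", modelId = modelId, mse = mse, rmse = sqrt(mse),
      mae = mean(abs(err)), expVar = ev, bias = bias, mseMean = vo,
      nEval = length(obs))
}

#' Reproducible random data splits
#'
#' Disjoint exhaustive random partitions per repeat: 70/30 train/test, or
#' 60/20/20 train/validation/test (the scheme used for large cluster sets).
#'
#' @param n number of records (or a vector whose length is used).
#' @param scheme "train_test_70_30" or "train_valid_test_60_20_20".
#' @param nRepeats number of repeated partitions.
#' @param seed integer seed.
#' @return list of length \code{nRepeats}; each element a named list of
#'   index vectors (\code{train}, \code{test}, and \code{valid} for the
#'   three-way scheme).
#' @export
splitData <- function(n, scheme = c("train_test_70_30",
                                    "train_valid_test_60_20_20"),
                      nRepeats = 1L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (length(n) > 1) n <- length(n)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nRepeats), function(r) {
      idx <- sample.int(n)
      if (scheme == "train_test_70_30") {
        k <- round(0.7 * n)
        if (k < 1 || k >= n) stop("too few records for a 70/30 split")
        list(train = sort(idx[1:k]), test = sort(idx[(k + 1):n]))
      } else {
        k1 <- round(0.6 * n); k2 <- round(0.2 * n)
        if (k1 < 1 || k2 < 1 || k1 + 2 * k2 > n + 1 || n - k1 - k2 < 1)
          stop("too few records for a 60/20/20 split")
        list(train = sort(idx[1:k1]),
             valid = sort(idx[(k1 + 1):(k1 + k2)]),
             test = sort(idx[(k1 + k2 + 1):n]))
      }
    })
  })
}

#' Comparison table across validation reports
#'
#' Mirrors the published comparison-table layout: one row per model with
#' MSE, RMSE, MAE, explained variance and the trivial-model MSE, full
#' precision retained (round only for presentation).
#'
#' @param reports list of \linkS4class{ValidationReport}s.
#' @param label optional dataset label column (country/indicator).
#' @param parameter optional modelled-parameter label column.
#' @return data.frame with columns label, parameter, model, mse, rmse, mae,
#'   exp_var, bias, mse_mean, n_eval.
#' @export
compareModels <- function(reports, label = "", parameter = "") {
  stopifnot(length(reports) >= 1)
  do.call(rbind, lapply(reports, function(r) data.frame(
    label = label, parameter = parameter, model = r@modelId, mse = r@mse,
    rmse = r@rmse, mae = r@mae, exp_var = r@expVar, bias = r@bias,
    mse_mean = r@mseMean, n_eval = r@nEval, stringsAsFactors = FALSE)))
}

#' Select the best model from validation reports
#'
#' Deterministic selection rule: highest explained variance, ties broken by
#' lower RMSE, then lower MAE, then report order.
#'
#' @param reports list of \linkS4class{ValidationReport}s.
#' @return the winning \code{modelId}.
#' @export
selectBest <- function(reports) {
  stopifnot(length(reports) >= 1)
  ev <- vapply(reports, function(r)
    if (is.na(r@expVar)) -Inf else r@expVar, numeric(1))
  rmse <- vapply(reports, function(r) r@rmse, numeric(1))
  mae <- vapply(reports, function(r) r@mae, numeric(1))
  ord <- order(-ev, rmse, mae)
  reports[[ord[1]]]@modelId
}

#' Write a comparison table as CSV and JSON
#'
#' @param table data.frame from \code{\link{compareModels}}.
#' @param csvPath,jsonPath output paths (either may be NULL).
#' @return invisibly, the table.
#' @export
writeComparison <- function(table, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(table, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(table, jsonPath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(table)
}
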
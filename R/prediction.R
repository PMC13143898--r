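# Trait prediction from digital traits: four regressors under repeated
# k-fold cross-validation, regression metrics, RF feature importance and
# the RMSE-gap comparison rule.

#' Prediction configuration
#'
#' Hyperparameters are frozen here rather than inherited from library
#' defaults: RF uses 100 trees, variance split criterion, minimum node size
#' 1, unlimited depth, bootstrapping; the MLP has one hidden layer of 100
#' ReLU units trained by Adam; SVR uses the radial basis kernel
#' exp(-d(xi,xj)^2 / (2 l^2)) with length scale set from the feature
#' variance; AdaBoost boosts depth-3 regression trees under the linear
#' loss.
#'
#' @param model one of \code{"rf"}, \code{"svr"}, \code{"mlp"},
#'   \code{"adaboost"}.
#' @param k number of CV folds (>= 2).
#' @param repetitions number of CV repetitions.
#' @param seed integer seed for fold assignment and model fitting.
#' @param normalizeTarget min-max normalize the target before CV so RMSE is
#'   scale-free (makes the 0.1 RMSE-gap rule meaningful).
#' @param pooled also compute metrics on pooled out-of-fold predictions.
#' @return list of class \code{"predictionConfig"}.
#' @export
predictionConfig <- function(model = c("rf", "svr", "mlp", "adaboost"),
                             k = 4L, repetitions = 100L, seed = 1L,
                             normalizeTarget = TRUE, pooled = FALSE) {
  model <- match.arg(model)
  if (k < 2) stop("k must be >= 2")
  if (repetitions < 1) stop("repetitions must be >= 1")
  structure(list(model = model, k = as.integer(k),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), normalizeTarget = normalizeTarget,
                 pooled = pooled), class = "predictionConfig")
}

fitRegressor <- function(x, y, model, seed = 1L) {
  x <- as.matrix(x)
  switch(model,
    rf = withSeed(seed,
      randomForest::randomForest(x, y, ntree = 100L, nodesize = 1L,
                                 mtry = ncol(x), replace = TRUE)),
    svr = e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                     gamma = 1 / (ncol(x) * max(var(as.vector(x)), 1e-8)),
                     cost = 1, epsilon = 0.1),
    mlp = mlpFit(x, y, seed = seed),
    adaboost = adaboostFit(x, y, seed = seed),
    stop("unknown model '", model, "'"))
}

#' Regression metrics
#'
#' RMSE = sqrt(mean((y - yhat)^2)); R^2 = 1 - SSres/SStot; r = Pearson
#' correlation (NA when either vector is constant).
#'
#' @param y ground-truth values (non-constant, length >= 2).
#' @param yhat predictions of the same length.
#' @return named vector (rmse, r2, r).
#' @export
regressionMetrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant y: R^2 undefined")
  rmse <- sqrt(mean((y - yhat)^2))
  r2 <- 1 - sum((y - yhat)^2) / sst
  r <- if (length(y) >= 3 && popSd(yhat) > 0) pearsonCorrelation(y, yhat)
       else NA_real_
  c(rmse = rmse, r2 = r2, r = r)
}

#' Repeated k-fold cross-validation of one regressor
#'
#' Each repetition partitions the samples into k folds; every sample is
#' predicted out-of-fold exactly once per repetition, giving k x
#' repetitions train/validation splits (400 under the defaults).  Metrics
#' are computed per validation fold and averaged across splits.
#'
#' @param features samples x features matrix (no missing values).
#' @param target numeric response.
#' @param config a \code{\link{predictionConfig}}.
#' @return list of class \code{"cvResult"}: \code{perSplit} data.frame,
#'   \code{metrics} (mean rmse/r2/r over splits), \code{oof} matrix of
#'   out-of-fold predictions (samples x repetitions), \code{pooled}
#'   metrics when requested, and the config.
#' @export
runRepeatedCv <- function(features, target, config = predictionConfig()) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < config$k) stop("fewer samples than folds")
  if (n < 2 * config$k)
    warning("fewer than 2k samples: folds are very small")
  if (anyNA(x) || anyNA(target)) stop("missing values not allowed")
  y <- if (config$normalizeTarget) {
    v <- minmaxVec(target)
    if (is.null(v)) stop("constant target")
    v
  } else target
  perSplit <- NULL
  oof <- matrix(NA_real_, n, config$repetitions)
  for (rep in seq_len(config$repetitions)) {
    folds <- withSeed(childSeed(config$seed, rep),
                      sample(rep_len(seq_len(config$k), n)))
    for (fold in seq_len(config$k)) {
      val <- folds == fold
      fit <- fitRegressor(x[!val, , drop = FALSE], y[!val], config$model,
                          seed = childSeed(config$seed, rep * 1000L + fold))
      pred <- as.vector(predict(fit, x[val, , drop = FALSE]))
      oof[val, rep] <- pred
      m <- tryCatch(regressionMetrics(y[val], pred),
                    error = function(e) c(rmse = NA, r2 = NA, r = NA))
      perSplit <- rbind(perSplit,
                        data.frame(rep = rep, fold = fold, rmse = m["rmse"],
                                   r2 = m["r2"], r = m["r"],
                                   row.names = NULL))
    }
  }
  metrics <- c(rmse = mean(perSplit$rmse, na.rm = TRUE),
               r2 = mean(perSplit$r2, na.rm = TRUE),
               r = mean(perSplit$r, na.rm = TRUE))
  res <- list(perSplit = perSplit, metrics = metrics, oof = oof,
              config = config)
  if (config$pooled)
    res$pooled <- regressionMetrics(rep(y, config$repetitions),
                                    as.vector(oof))
  structure(res, class = "cvResult")
}

#' Random-forest feature importance with threshold selection
#'
#' Impurity-based importances from a 100-tree random forest, normalized to
#' sum 1; features whose importance strictly exceeds \code{threshold} are
#' selected.
#'
#' @param features samples x features matrix.
#' @param target numeric response (non-constant).
#' @param threshold selection threshold on the normalized importance
#'   (default 0.1).
#' @param seed integer seed.
#' @return list with \code{importance} (named, sums to 1) and
#'   \code{selected} (character).
#' @export
rfFeatureImportance <- function(features, target, threshold = 0.1,
                                seed = 1L) {
  x <- as.matrix(features)
  if (popSd(target) == 0) stop("constant target")
  fit <- withSeed(seed,
    randomForest::randomForest(x, target, ntree = 100L, nodesize = 1L,
                               mtry = ncol(x), importance = FALSE))
  imp <- fit$importance[, "IncNodePurity"]
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  names(imp) <- colnames(x)
  list(importance = imp, selected = names(imp)[imp > threshold])
}

#' Flag flights whose models differ materially in RMSE
#'
#' Among CV results sharing a flight key, the flight is flagged when the
#' spread of mean RMSEs across models exceeds \code{gap} (0.1 on
#' normalized targets); the rule is applied to flights that are accurately
#' predicted (some model with mean r > \code{rThreshold}).
#'
#' @param results data.frame with columns \code{flight}, \code{model},
#'   \code{rmse} and \code{r} (mean per flight x model).
#' @param gap RMSE-difference threshold.
#' @param rThreshold accuracy eligibility threshold.
#' @return data.frame per flight: nModels, gap, eligible, flagged.
#' @export
rmseGapFlags <- function(results, gap = 0.1, rThreshold = 0.75) {
  stopifnot(all(c("flight", "model", "rmse") %in% names(results)))
  out <- NULL
  for (fl in unique(results$flight)) {
    d <- results[results$flight == fl, ]
    spread <- if (nrow(d) >= 2) max(d$rmse) - min(d$rmse) else NA_real_
    eligible <- if ("r" %in% names(d)) any(d$r > rThreshold, na.rm = TRUE)
                else TRUE
    out <- rbind(out, data.frame(
      flight = fl, nModels = nrow(d), gap = spread, eligible = eligible,
      flagged = isTRUE(eligible && is.finite(spread) && spread > gap)))
  }
  out
}
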
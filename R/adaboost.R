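# AdaBoost.R2 regression with shallow regression-tree base learners and the
# linear loss for reweighting; prediction by the weighted median of the
# ensemble.

adaboostFit <- function(x, y, nEstimators = 50L, maxDepth = 3L, seed = 1L) {
  x <- as.data.frame(x)
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list()
  beta <- numeric(0)
  withSeed(seed, {
    for (m in seq_len(nEstimators)) {
      fit <- rpart::rpart(y ~ ., data = cbind(x, y = y), weights = w * n,
                          control = rpart::rpart.control(
                            maxdepth = maxDepth, cp = 0, minsplit = 2,
                            minbucket = 1, xval = 0))
      pred <- predict(fit, x)
      err <- abs(y - pred)
      emax <- max(err)
      if (emax <= 0) {            # perfect fit: keep it with full weight
        learners[[length(learners) + 1L]] <- fit
        beta <- c(beta, 1e-10)
        break
      }
      loss <- err / emax          # linear loss
      ebar <- sum(w * loss)
      if (ebar >= 0.5) break
      b <- ebar / (1 - ebar)
      learners[[length(learners) + 1L]] <- fit
      beta <- c(beta, b)
      w <- w * b^(1 - loss)
      w <- w / sum(w)
    }
  })
  if (!length(learners)) {        # fall back to a single tree
    learners <- list(rpart::rpart(y ~ ., data = cbind(x, y = y),
                                  control = rpart::rpart.control(
                                    maxdepth = maxDepth, cp = 0, xval = 0)))
    beta <- 0.5
  }
  structure(list(learners = learners, beta = beta), class = "uavAdaboost")
}

#' @export
predict.uavAdaboost <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  preds <- vapply(object$learners, function(f) predict(f, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  wts <- log(1 / pmax(object$beta, 1e-12))
  apply(preds, 1L, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1L]]   # weighted median
  })
}
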
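# Repeated cross-validation, the four regressors, metrics, Scott-Knott
# grouping, RF importances and the RMSE-gap rule.

linearData <- function(n = 60, p = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    list(x = x, y = 2 * x[, 1] + rnorm(n, 0, 0.1))
  })
}

test_that("regression metrics follow their definitions", {
  y <- c(0, 0, 1, 1)
  expect_equal(regressionMetrics(y, y)[["rmse"]], 0)
  expect_equal(regressionMetrics(y, y)[["r2"]], 1)
  expect_equal(regressionMetrics(y, rep(mean(y), 4))[["r2"]], 0)
  m <- regressionMetrics(y, c(0, 0, 0, 1))
  expect_equal(m[["rmse"]], 0.5)
  expect_equal(m[["r2"]], 0)
  expect_error(regressionMetrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(regressionMetrics(1:3, 1:2), "mismatch")
})

test_that("repeated CV produces k x repetitions splits and is seeded", {
  d <- linearData(n = 24)
  cfg <- predictionConfig("rf", k = 4, repetitions = 5, seed = 3)
  cv <- runRepeatedCv(d$x, d$y, cfg)
  expect_equal(nrow(cv$perSplit), 20)
  # every sample predicted exactly once per repetition
  expect_true(all(colSums(!is.na(cv$oof)) == 24))
  expect_true(all(rowSums(!is.na(cv$oof)) == 5))
  cv2 <- runRepeatedCv(d$x, d$y, cfg)
  expect_identical(cv$metrics, cv2$metrics)
  expect_error(runRepeatedCv(d$x[1:3, ], d$y[1:3], cfg), "fewer samples")
  expect_true(all(cv$perSplit$r2 <= 1, na.rm = TRUE))
  expect_true(all(cv$perSplit$rmse >= 0, na.rm = TRUE))
})

test_that("all four regressors recover a linear signal", {
  d <- linearData(n = 80)
  for (model in c("rf", "svr", "mlp", "adaboost")) {
    cv <- runRepeatedCv(d$x, d$y,
                        predictionConfig(model, repetitions = 2, seed = 5))
    expect_gt(cv$metrics[["r"]], 0.8)
  }
})

test_that("random forests track an exact linear target closely", {
  x <- withr::with_seed(7, matrix(rnorm(200 * 4), 200, 4,
                                  dimnames = list(NULL, paste0("f", 1:4))))
  y <- 2 * x[, 1]            # exact linear function of one feature
  cv <- runRepeatedCv(x, y,
                      predictionConfig("rf", repetitions = 3, seed = 11))
  expect_gte(cv$metrics[["r"]], 0.95)
  # r^2 approximates R^2 for near-affine predictions
  expect_lt(abs(cv$metrics[["r"]]^2 - cv$metrics[["r2"]]), 0.15)
})

test_that("Scott-Knott agrees with the exhaustive-partition oracle", {
  withr::with_seed(13, {
    for (i in 1:30) {
      k <- sample(2:8, 1)
      means <- rnorm(k, 0, sample(c(0.5, 2), 1))
      names(means) <- paste0("m", seq_len(k))
      s2 <- runif(1, 0.01, 1)
      df <- sample(5:40, 1)
      expect_equal(scottKnottGroups(means, s2, df),
                   skOracle(means, s2, df))
    }
  })
})

test_that("Scott-Knott handles degenerate and clear-cut inputs", {
  expect_equal(unname(scottKnottGroups(c(a = 2, b = 2, c = 2), 1, 10)),
               c(1L, 1L, 1L))
  expect_equal(unname(scottKnottGroups(c(solo = 5), 1, 10)), 1L)
  g <- scottKnottGroups(c(a = 1.0, b = 1.1, c = 5.0, d = 5.2),
                        s2 = 0.01, df = 10)
  expect_equal(unname(g), c(2L, 2L, 1L, 1L))   # labels respect ordering
  expect_error(scottKnottGroups(c(1, NA), 1, 10), "finite")
  # Tukey alternative groups obvious separations the same way
  tg <- tukeyGroups(c(a = 1.0, b = 1.1, c = 5.0, d = 5.2), s2 = 0.01,
                    df = 10)
  expect_equal(unname(tg), c(2L, 2L, 1L, 1L))
})

test_that("RF importances are normalized and find the signal feature", {
  withr::with_seed(17, {
    x <- matrix(rnorm(500 * 20), 500, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    y <- x[, 7] + rnorm(500, 0, 0.05)
  })
  imp <- rfFeatureImportance(x, y, seed = 2)
  expect_equal(sum(imp$importance), 1)
  expect_equal(names(which.max(imp$importance)), "f7")
  expect_true("f7" %in% imp$selected)
  expect_error(rfFeatureImportance(x, rep(1, 500)), "constant")
  # all-noise: no feature stably exceeds the threshold across seeds
  withr::with_seed(18, {
    xn <- matrix(rnorm(200 * 20), 200, 20,
                 dimnames = list(NULL, paste0("f", 1:20)))
    yn <- rnorm(200)
  })
  hits <- sapply(1:3, function(s)
    rfFeatureImportance(xn, yn, seed = s)$importance > 0.1)
  expect_true(all(rowSums(hits) < 3))
})

test_that("the RMSE-gap rule flags material model differences", {
  res <- data.frame(flight = c("A", "A", "B", "B", "C", "C"),
                    model = rep(c("rf", "svr"), 3),
                    rmse = c(0.30, 0.30, 0.30, 0.42, 0.30, 0.35),
                    r = rep(0.9, 6))
  fl <- rmseGapFlags(res)
  expect_equal(fl$flagged, c(FALSE, TRUE, FALSE))
  # ineligible flights (r below threshold) are never flagged
  res$r <- 0.2
  expect_true(all(!rmseGapFlags(res)$flagged))
  # single model per flight cannot be flagged
  one <- rmseGapFlags(data.frame(flight = "A", model = "rf", rmse = 0.3,
                                 r = 0.9))
  expect_false(one$flagged)
})
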
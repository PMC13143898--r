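# Vegetation indices, distribution statistics, GLCM texture and the
# assembled feature table.

test_that("vegetation indices evaluate to their closed forms", {
  px <- function(r, g, b) {
    a <- array(0, c(1, 1, 3)); a[1, 1, ] <- c(r, g, b); a
  }
  m1 <- matrix(1, 1, 1)
  expect_equal(computeViMap(px(50, 100, 50), m1, "GCC")[1, 1], 0.5)
  expect_equal(computeViMap(px(0, 255, 0), m1, "NGRDI")[1, 1], 1)
  expect_equal(computeViMap(px(100, 100, 100), m1, "VARI")[1, 1], 0)
  expect_equal(computeViMap(px(100, 100, 100), m1, "TGI")[1, 1],
               100 - 39 - 61)
  expect_error(computeViMap(px(1, 1, 1), m1, "NDVI"), "unknown")
  # guarded division invalidates the pixel
  expect_true(is.na(computeViMap(px(0, 0, 0), m1, "GCC")[1, 1]))
  expect_true(is.na(computeViMap(px(100, 100, 0), m1, "WI")[1, 1]))
  # background pixels are never populated
  v <- computeViMap(px(50, 100, 50), matrix(0, 1, 1), "GCC")
  expect_true(is.na(v[1, 1]))
})

test_that("distribution summaries follow the stated conventions", {
  s <- summarizeDistribution(c(1, 2, 3, 4))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["q25"]], 1.75)   # linear-interpolation quantiles
  expect_equal(s[["q50"]], 2.5)
  expect_equal(s[["stdev"]], sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_equal(summarizeDistribution(c(-3, 0, 3))[["skewness"]], 0)
  expect_warning(cst <- summarizeDistribution(rep(2, 5)), "degenerate")
  expect_equal(cst[["stdev"]], 0)
  expect_equal(cst[["skewness"]], 0)
  expect_equal(cst[["kurtosis"]], 0)
  expect_error(summarizeDistribution(numeric(0)), "no valid")
})

test_that("plant pixels are counted from the mask", {
  expect_equal(countPlantPixels(matrix(0, 10, 10)), 0L)
  expect_equal(countPlantPixels(matrix(1, 10, 10)), 100L)
  im <- renderPlotImage(4, 1, renderParams(canvas = 48), seed = 2)
  expect_equal(countPlantPixels(im), sum(plantMask(im)))
})

test_that("GLCM matches a brute-force pixel-pair oracle", {
  for (s in 1:3) {
    g <- randomGray(s, 16, 16, 8)
    for (d in c(1L, 5L, 10L)) for (a in c(0, 45, 90, 135)) {
      M <- computeGlcm(g, glcmConfig(d, a, levels = 8))
      expect_equal(M, bruteGlcm(g, d, a, 8), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
  # background exclusion is pairwise
  g <- randomGray(9, 8, 8, 4)
  g[3, ] <- NA
  M <- computeGlcm(g, glcmConfig(1, 90, levels = 4))
  expect_equal(M, bruteGlcm(g, 1, 90, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GLCM handles degenerate inputs per contract", {
  cst <- matrix(1L, 6, 6)
  M <- computeGlcm(cst, glcmConfig(1, 0, levels = 4))
  expect_equal(sum(M != 0), 1L)
  expect_equal(M[1, 1], 1)
  allNA <- matrix(NA_integer_, 6, 6)
  expect_error(computeGlcm(allNA, glcmConfig(1, 0, levels = 4)),
               "no valid")
  expect_equal(sum(computeGlcm(randomGray(1, 8, 8, 4),
                               glcmConfig(5, 45, levels = 4))), 1)
})

test_that("Haralick descriptors evaluate known matrices exactly", {
  cb <- outer(1:8, 1:8, function(i, j) ((i + j) %% 2) + 1L)
  M <- computeGlcm(cb, glcmConfig(1, 0, levels = 2))
  h <- haralickDescriptors(M)
  expect_equal(h[["entropy"]], 1)
  expect_equal(h[["ASM"]], 0.5)
  expect_equal(h[["contrast"]], 1)
  expect_equal(h[["correlation"]], -1)
  cstM <- computeGlcm(matrix(1L, 5, 5), glcmConfig(1, 0, levels = 2))
  hc <- haralickDescriptors(cstM)
  expect_equal(hc[["ASM"]], 1)
  expect_equal(hc[["entropy"]], 0)
  expect_equal(hc[["contrast"]], 0)
  expect_equal(hc[["homogeneity"]], 1)
  expect_error(haralickDescriptors(matrix(1, 2, 2)), "normalized")
  # oracle agreement on random images
  for (s in 4:6) {
    M <- computeGlcm(randomGray(s), glcmConfig(1, 45, levels = 8))
    expect_equal(haralickDescriptors(M), bruteHaralick(M),
                 tolerance = 1e-12)
  }
})

test_that("GLCM entropy is extreme for noise and constant images", {
  ent <- function(g) haralickDescriptors(
    computeGlcm(g, glcmConfig(1, 0, levels = 8)))[["entropy"]]
  eNoise <- vapply(1:5, function(s) ent(randomGray(s, 24, 24, 8)),
                   numeric(1))
  expect_true(all(eNoise > 5))          # close to the 6-bit maximum
  expect_equal(ent(matrix(3L, 24, 24)), 0)
  # smoother images sit strictly between
  smooth <- matrix(rep(rep(1:8, each = 3), 24)[1:(24 * 24)], 24, 24)
  expect_lt(ent(smooth), min(eNoise))
})

test_that("feature cardinality is conserved across configurations", {
  for (canvas in c(32, 48)) {
    im <- renderPlotImage(5, 1, renderParams(canvas = canvas,
                                             areaGain = 0.05), seed = 3)
    full <- extractFeatureTable(list(p = im))
    expect_equal(nrow(full), 14 * 7 + 12 * 6 + 1)
    expect_equal(sum(SummarizedExperiment::rowData(full)$group == "vi"), 98)
    expect_equal(sum(SummarizedExperiment::rowData(full)$group == "glcm"),
                 72)
  }
  im <- renderPlotImage(5, 1, renderParams(canvas = 32, areaGain = 0.05),
                        seed = 3)
  viOnly <- extractFeatureTable(list(p = im), extractionConfig(
    glcmDistances = integer(0), pixelCount = FALSE))
  expect_equal(nrow(viOnly), 98)
  glcmOnly <- extractFeatureTable(list(p = im), extractionConfig(
    vis = character(0), pixelCount = FALSE))
  expect_equal(nrow(glcmOnly), 72)
})

test_that("failed plots are flagged, not dropped", {
  good <- renderPlotImage(5, 1, renderParams(canvas = 32, areaGain = 0.05),
                          seed = 3)
  bare <- renderPlotImage(0, 1, renderParams(canvas = 32), seed = 4)
  expect_warning(ft <- extractFeatureTable(list(g = good, b = bare)),
                 "flagged")
  expect_equal(ncol(ft), 2)
  expect_equal(SummarizedExperiment::colData(ft)$failed, c(FALSE, TRUE))
  expect_equal(SummarizedExperiment::assay(ft, "raw")["n_pixels", "b"], 0)
})

test_that("min-max normalization maps to [0, 1] and is idempotent", {
  expect_equal(minmaxNormalize(matrix(c(1, 3, 5), 3, 1,
                                      dimnames = list(NULL, "x")))[, 1],
               c(0, 0.5, 1))
  expect_warning(z <- minmaxNormalize(matrix(2, 3, 1)), "constant")
  expect_true(all(z == 0))
  m <- matrix(withr::with_seed(1, rnorm(30)), 10, 3)
  n1 <- minmaxNormalize(m)
  expect_equal(apply(n1, 2, min), rep(0, 3))
  expect_equal(apply(n1, 2, max), rep(1, 3))
  expect_equal(minmaxNormalize(n1), n1)
  expect_error(minmaxNormalize(data.frame(a = letters[1:3])),
               "non-numeric")
})
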
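# Synthetic field generator: design construction, trait simulation,
# rendering and camera geometry.

test_that("augmented designs have the canonical trial layout", {
  d <- makeDesign(5, c("S12", "Miyagui", "Mombaca"), 42, seed = 3)
  expect_equal(nPlots(d), 225)
  expect_equal(length(entryNames(d)), 213)
  expect_equal(nBlocks(d), 5)

  d1 <- makeDesign(1, "chk", 0, seed = 1)
  expect_equal(nPlots(d1), 1)

  d2 <- makeDesign(2, c("c1", "c2"), 3, seed = 9)
  df <- designTable(d2)
  expect_equal(nrow(df), 10)
  for (b in 1:2)
    expect_true(all(c("c1", "c2") %in% df$entry[df$block == b]))
  prog <- df[df$role == "progeny", ]
  expect_equal(anyDuplicated(prog$entry), 0L)
})

test_that("duplicate progeny labels are a design error", {
  expect_error(makeDesign(2, "c", 2,
                          progenyLabels = c("p1", "p1", "p2", "p3")),
               "duplicate progeny")
  expect_error(makeDesign(1, "c", 1, progenyLabels = "c"), "duplicate")
})

test_that("design invariants hold across many random seeds", {
  for (s in 1:100) {
    d <- makeDesign(3, c("A", "B"), 4, seed = s)
    expect_true(validObject(d))
    df <- designTable(d)
    expect_equal(nrow(df), 3 * 6)
    for (b in 1:3) {
      inb <- df[df$block == b, ]
      expect_equal(sum(inb$role == "check"), 2)
      expect_equal(sum(inb$role == "progeny"), 4)
    }
  }
})

test_that("trait simulation follows the stated variance model", {
  d <- makeDesign(2, "chk", 5, seed = 1)
  # all variances 0, no fixed effects -> every record equals mu
  sp <- list(Y = varianceSpec(mu = 7, sigma2G = 0, sigma2GH = 0,
                              sigma2B = 0, sigma2E = 0,
                              harvestEffects = 0))
  tt <- simulateTraits(d, sp, nHarvests = 2, seed = 5)
  expect_true(all(tt$Y == 7))

  # same seed -> identical table
  t1 <- simulateTraits(d, nHarvests = 3, seed = 11)
  t2 <- simulateTraits(d, nHarvests = 3, seed = 11)
  expect_identical(t1, t2)
  expect_error(simulateTraits(d, nHarvests = 0), "nHarvests")
})

test_that("genetic effects are drawn at the requested variance", {
  d <- makeDesign(1, "chk", 10000, seed = 2)
  sp <- list(Y = varianceSpec(mu = 0, sigma2G = 1, sigma2E = 0.01))
  tt <- simulateTraits(d, sp, nHarvests = 1, seed = 3)
  g <- attr(tt, "geneticEffects")$Y
  expect_equal(length(g), 10000)
  expect_lt(abs(var(g) - 1), 0.05)
})

test_that("TDMY is the sum of its dry-matter components", {
  d <- makeDesign(3, c("A", "B"), 10, seed = 4)
  tt <- simulateTraits(d, nHarvests = 2, seed = 6)
  expect_equal(tt$TDMY, (tt$LDMY + tt$SDMY + tt$DMP) / 1000)
  expect_true(all(tt$LDMY >= 0 & tt$SDMY >= 0 & tt$DMP >= 0 &
                    tt$GMY >= 0))
})

test_that("rendering responds monotonically to biomass and vigor", {
  rp <- renderParams(canvas = 48, areaGain = 0.02)
  # biomass 0 -> soil only
  expect_equal(sum(plantMask(renderPlotImage(0, 1, rp, seed = 1))), 0)
  # determinism
  a <- renderPlotImage(3, 1, rp, seed = 7)
  b <- renderPlotImage(3, 1, rp, seed = 7)
  expect_identical(rgbArray(a), rgbArray(b))
  expect_identical(plantMask(a), plantMask(b))
  # strictly increasing mask areas over a biomass grid
  areas <- vapply(c(1, 2, 4, 8), function(bm)
    sum(plantMask(renderPlotImage(bm, 1, rp, seed = 5))), numeric(1))
  expect_true(all(diff(areas) > 0))
  # within-plant texture variance non-decreasing in biomass
  tvar <- vapply(c(1, 4, 16), function(bm) {
    im <- renderPlotImage(bm, 1, renderParams(canvas = 48, areaGain = 0.03,
                                              textureGain = 0.3), seed = 5)
    g <- rgbArray(im)[, , 2][plantMask(im) == 1]
    var(g)
  }, numeric(1))
  expect_true(all(diff(tvar) > -1e-9))
  # mean green chromaticity of plant pixels non-decreasing in vigor
  gcc <- vapply(c(0.25, 0.5, 1, 2, 4), function(v) {
    im <- renderPlotImage(4, v, rp, seed = 5)
    px <- plantMask(im) == 1
    r <- rgbArray(im)
    mean(r[, , 2][px] / (r[, , 1][px] + r[, , 2][px] + r[, , 3][px]))
  }, numeric(1))
  expect_true(all(diff(gcc) > 0))
})

test_that("area links mask size to yield across a plot batch", {
  d <- makeDesign(5, c("A", "B", "C"), 40, seed = 21)
  tt <- simulateTraits(d, nHarvests = 1, seed = 22)
  rp <- renderParams(canvas = 48, areaGain = 0.02)
  n <- vapply(seq_len(nrow(tt)), function(i)
    sum(plantMask(renderPlotImage(tt$biomass[i], tt$vigor[i], rp,
                                  seed = 3000 + i))), numeric(1))
  expect_gt(cor(n, tt$GMY), 0.8)
})

test_that("GSD resampling is area-weighted block averaging", {
  rp <- renderParams(canvas = 48)
  im <- renderPlotImage(4, 1, rp, seed = 2)
  # factor 1 -> unchanged
  expect_identical(resampleGsd(im, gsd(im)), im)
  # integer factor -> exact block means
  arr <- array(withr::with_seed(1, runif(100 * 100 * 3, 0, 255)),
               c(100, 100, 3))
  pi0 <- PlotImage(arr, meta = list(gsd = 0.5))
  dn <- resampleGsd(pi0, 1.0)
  expect_equal(dim(rgbArray(dn))[1:2], c(50L, 50L))
  expect_equal(rgbArray(dn)[1, 1, 1],
               mean(arr[1:2, 1:2, 1]), tolerance = 1e-12)
  expect_equal(rgbArray(dn)[50, 50, 3],
               mean(arr[99:100, 99:100, 3]), tolerance = 1e-12)
  expect_equal(gsd(dn), 1.0)
  # constant image stays constant at any factor
  cst <- PlotImage(array(77, c(60, 60, 3)), meta = list(gsd = 0.27))
  out <- resampleGsd(cst, 0.9)
  expect_true(all(abs(rgbArray(out) - 77) < 1e-9))
  # no upsampling
  expect_error(resampleGsd(pi0, 0.25), "no upsampling")
  # mask majority vote keeps sizes consistent
  m <- matrix(0, 100, 100); m[1:40, 1:40] <- 1
  pm <- PlotImage(arr, m, meta = list(gsd = 0.5))
  md <- plantMask(resampleGsd(pm, 1.0))
  expect_equal(sum(md), 400)
})

test_that("pinhole GSD reproduces the four flight altitudes", {
  expect_equal(round(computeGsd(10, 13.2, 8.8, 5472), 2), 0.27)
  expect_equal(round(computeGsd(18), 1), 0.5)
  expect_equal(round(computeGsd(35), 1), 1.0)
  expect_equal(round(computeGsd(55), 1), 1.5)
  expect_equal(computeGsd(20), 2 * computeGsd(10))
  expect_error(computeGsd(-5), "> 0")
  expect_error(computeGsd(10, focalLength = 0), "> 0")
})

test_that("synthetic experiments round-trip to disk", {
  d <- makeDesign(1, "c", 2, seed = 1)
  tt <- simulateTraits(d, nHarvests = 1, seed = 2)
  im <- renderPlotImage(3, 1, renderParams(canvas = 32), seed = 1,
                        meta = list(entry = "c", environment = "E1",
                                    dap = 100))
  dir <- withr::local_tempdir()
  man <- writeSyntheticExperiment(dir, d, tt, list(c = im), seed = 1)
  expect_true(file.exists(file.path(dir, "design.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  png <- grep("png$", man$files, value = TRUE)
  expect_length(png, 2)   # image + mask
  back <- png::readPNG(file.path(dir, png[1]))
  expect_equal(round(back * 255), rgbArray(im), ignore_attr = TRUE)
})
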
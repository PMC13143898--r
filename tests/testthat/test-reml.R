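# REML variance components, BLUPs/BLUEs, PEV, Wald and LRT, and the
# heritability estimators.

balancedOneWay <- function(g, r, sG = 1, sE = 1, seed = 1) {
  withr::with_seed(seed, {
    d <- expand.grid(geno = factor(seq_len(g)), rep = seq_len(r))
    d$y <- rnorm(g, 0, sqrt(sG))[d$geno] + rnorm(g * r, 0, sqrt(sE))
    d
  })
}

test_that("REML equals ANOVA closed forms on balanced one-way data", {
  for (s in 1:5) {
    g <- withr::with_seed(s, sample(15:40, 1))
    r <- withr::with_seed(s + 100, sample(3:6, 1))
    d <- balancedOneWay(g, r, sG = 1.5, seed = s)
    a <- anova(aov(y ~ geno, d))
    sgHat <- (a[1, 3] - a[2, 3]) / r
    if (sgHat <= 0) next   # interior estimates only
    fit <- fitLmmReml(d, "y", random = "geno")
    expect_lt(abs(varComp(fit)[["geno"]] - sgHat), 1e-6)
    expect_lt(abs(varComp(fit)[["residual"]] - a[2, 3]), 1e-6)
    expect_true(fit@converged)
  }
})

test_that("REML matches lme4 on the augmented progeny model", {
  skip_if_not_installed("lme4")
  d <- balancedOneWay(30, 4, sG = 2, seed = 9)
  fit <- fitLmmReml(d, "y", random = "geno")
  lf <- lme4::lmer(y ~ (1 | geno), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(varComp(fit)[["geno"]], vc$vcov[1], tolerance = 1e-5)
  expect_equal(varComp(fit)[["residual"]], vc$vcov[2], tolerance = 1e-5)
  expect_equal(unname(blups(fit)),
               lme4::ranef(lf)$geno[, 1], tolerance = 1e-5)
})

test_that("pure-noise responses drive the genetic variance to the boundary", {
  ests <- vapply(21:26, function(s) {
    d <- balancedOneWay(25, 3, sG = 0, sE = 1, seed = s)
    fit <- suppressWarnings(fitLmmReml(d, "y", random = "geno",
                                       computePev = FALSE))
    varComp(fit)[["geno"]]
  }, numeric(1))
  expect_true(any(ests == 0))   # exact boundary where the signal vanishes
  expect_true(all(ests < 0.2))  # never far from it
})

test_that("BLUPs shrink towards zero relative to fixed estimates", {
  d <- balancedOneWay(20, 4, sG = 1, sE = 2, seed = 5)
  fit <- fitLmmReml(d, "y", random = "geno")
  fx <- coef(lm(y ~ 0 + geno, d)) - mean(d$y)
  bl <- blups(fit)
  expect_true(all(abs(bl) <= abs(fx) + 1e-8))
  expect_lt(abs(mean(bl)), 0.05)
})

test_that("the progeny term covers only progeny rows in augmented data", {
  dn <- makeDesign(3, c("A", "B"), 12, seed = 31)
  sp <- list(Y = varianceSpec(mu = 10, sigma2G = 1, sigma2B = 0.4,
                              sigma2E = 1, harvestEffects = c(-1, 1)))
  tt <- prepareAugmented(simulateTraits(dn, sp, nHarvests = 2, seed = 32),
                         checkNames(dn))
  fit <- fitLmmReml(tt, "Y", fixed = ~ checkF + harvestF,
                    random = c("progenyF", "blockF:harvestF"))
  expect_equal(length(blups(fit)), 36)          # progenies only
  expect_true(all(c("checkFA", "checkFB") %in% names(blues(fit))))
  expect_true(all(varComp(fit) >= 0))
  expect_equal(dim(pevMatrix(fit)), c(36L, 36L))
})

test_that("PEV matches an independent dense-algebra derivation", {
  d <- balancedOneWay(12, 3, sG = 2, sE = 1, seed = 41)
  fit <- fitLmmReml(d, "y", random = "geno")
  # oracle: PEV = G - G Z' P Z G with P = Vi - Vi X (X'Vi X)^-1 X' Vi
  sG <- varComp(fit)[["geno"]]; sE <- varComp(fit)[["residual"]]
  Z <- model.matrix(~ 0 + geno, d)
  X <- matrix(1, nrow(d), 1)
  V <- sG * Z %*% t(Z) + sE * diag(nrow(d))
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  G <- sG * diag(12)
  pevOracle <- G - G %*% t(Z) %*% P %*% Z %*% G
  expect_equal(unname(pevMatrix(fit)), pevOracle, tolerance = 1e-6)
  # Cullis heritability from the same PEV, via its definition
  q <- 12
  vdOff <- sum(outer(diag(pevOracle), diag(pevOracle), "+") -
                 2 * pevOracle) / (q * q - q)
  expect_equal(cullisH2(fit), 1 - vdOff / (2 * sG), tolerance = 1e-8)
})

test_that("Cullis heritability behaves at its algebraic limits", {
  mk <- function(pev, sG) {
    new("LmmFit", response = "y", components = c(geno = sG, residual = 1),
        componentSE = c(geno = NA_real_, residual = NA_real_),
        fixedCoef = numeric(0), vcovFixed = matrix(0, 0, 0),
        assign = integer(0), termLabels = character(0),
        blup = list(geno = numeric(3)), pev = pev, progenyTerm = "geno",
        logRestrictedLik = 0, converged = TRUE, nobs = 3L,
        X = matrix(0, 0, 0), y = numeric(0), Zlist = list(),
        boundary = c(FALSE, FALSE))
  }
  # PEV -> 0 (infinite replication): HC2 -> 1
  expect_equal(cullisH2(mk(matrix(0, 3, 3), sG = 1)), 1)
  # v_delta = 2 sG: HC2 = 0
  expect_equal(cullisH2(mk(diag(1, 3), sG = 1)), 0)
  expect_error(cullisH2(mk(diag(1, 3), sG = 0)), "undefined")
  # HC2 >= H2 on fitted balanced data where both are defined
  d <- balancedOneWay(20, 4, sG = 1.5, sE = 1, seed = 55)
  fit <- fitLmmReml(d, "y", random = "geno")
  h2 <- broadSenseH2(fit, basis = "entry-mean", nRep = 4)
  expect_gte(cullisH2(fit), as.numeric(h2))
})

test_that("broad-sense heritability uses the stated bases", {
  expect_equal(as.numeric(broadSenseH2(c(G = 1, E = 1), basis = "plot")),
               0.5)
  expect_equal(as.numeric(broadSenseH2(c(G = 0, E = 1), basis = "plot")),
               0)
  h <- broadSenseH2(c(G = 1, GH = 0.4, E = 1), basis = "entry-mean",
                    nHarvests = 4)
  expect_equal(as.numeric(h), 1 / (1 + 0.1 + 0.25), tolerance = 1e-12)
  expect_equal(attr(h, "basis"), "entry-mean")
  expect_error(broadSenseH2(c(G = 0, E = 0), basis = "plot"), "undefined")
})

test_that("Wald F equals classical ANOVA F without random terms", {
  withr::with_seed(61, {
    d <- expand.grid(trt = factor(1:4), rep = 1:6)
    d$y <- c(0, 0.5, 1, 1.5)[d$trt] + rnorm(24)
  })
  fit <- fitLmmReml(d, "y", fixed = ~ trt)
  w <- waldFixedEffects(fit)
  a <- anova(aov(y ~ trt, d))
  expect_equal(w$F[w$term == "trt"], a[1, 4], tolerance = 1e-8)
  expect_equal(w$p[w$term == "trt"], a[1, 5], tolerance = 1e-8)
})

test_that("Wald tests reject huge effects and hold the null level", {
  # power sanity: an enormous harvest effect
  dn <- makeDesign(2, "A", 15, seed = 71)
  sp <- list(Y = varianceSpec(mu = 10, sigma2G = 0.5, sigma2E = 1,
                              harvestEffects = c(0, 50)))
  tt <- prepareAugmented(simulateTraits(dn, sp, nHarvests = 2, seed = 72),
                         checkNames(dn))
  fit <- fitLmmReml(tt, "Y", fixed = ~ checkF + harvestF,
                    random = "progenyF")
  w <- waldFixedEffects(fit)
  expect_lt(w$p[w$term == "harvestF"], 1e-10)
  # type-I error near the nominal level under a null harvest effect
  rej <- vapply(1:150, function(s) {
    d2 <- withr::with_seed(s, {
      d <- expand.grid(geno = factor(1:20), harvest = factor(1:3))
      d$y <- rnorm(20, 0, 1)[d$geno] + rnorm(60)
      d
    })
    f <- suppressWarnings(fitLmmReml(d2, "y", fixed = ~ harvest,
                                     random = "geno",
                                     computePev = FALSE))
    waldFixedEffects(f)$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("the variance-component LRT uses the boundary mixture", {
  d <- balancedOneWay(25, 4, sG = 2, sE = 1, seed = 81)
  full <- fitLmmReml(d, "y", fixed = ~ 1, random = "geno")
  red <- fitLmmReml(d, "y", fixed = ~ 1)
  lrt <- lrtRandomEffect(full, red)
  expect_equal(lrt$term, "geno")
  expect_gt(lrt$statistic, 0)
  expect_lt(lrt$p, 0.001)
  # identical models: statistic 0, p 1
  same <- lrtRandomEffect(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # null truth: statistic mostly near zero
  stats0 <- vapply(1:30, function(s) {
    d0 <- balancedOneWay(15, 3, sG = 0, sE = 1, seed = 500 + s)
    f1 <- suppressWarnings(fitLmmReml(d0, "y", random = "geno",
                                      computePev = FALSE))
    f0 <- fitLmmReml(d0, "y")
    lrtRandomEffect(f1, f0)$statistic
  }, numeric(1))
  expect_gt(mean(stats0 < qchisq(0.95, 1)), 0.8)
})

test_that("model errors are reported with diagnostics", {
  d <- balancedOneWay(10, 2, seed = 91)
  d$alias <- d$geno
  expect_error(fitLmmReml(d, "y", fixed = ~ geno + alias), "aliased")
  d$one <- factor("x")
  expect_error(fitLmmReml(d, "y", random = "one"), "at least 2 levels")
  expect_error(lrtRandomEffect(
    fitLmmReml(d, "y", random = "geno"),
    fitLmmReml(d, "y", fixed = ~ rep)), "nested|fixed")
})
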
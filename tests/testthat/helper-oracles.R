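# Independent oracles and small fixture builders used across the suite.
# Oracle code is deliberately written as naive loops / direct formulas,
# sharing no code path with the package implementation.

# Brute-force GLCM: enumerate every pixel pair explicitly.
bruteGlcm <- function(gray, d, a, levels) {
  ang <- a * pi / 180
  dr <- -round(d * sin(ang)); dc <- round(d * cos(ang))
  M <- matrix(0, levels, levels)
  H <- nrow(gray); W <- ncol(gray)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 >= 1 && i2 <= H && j2 >= 1 && j2 <= W &&
        !is.na(gray[i, j]) && !is.na(gray[i2, j2])) {
      M[gray[i, j], gray[i2, j2]] <- M[gray[i, j], gray[i2, j2]] + 1
      M[gray[i2, j2], gray[i, j]] <- M[gray[i2, j2], gray[i, j]] + 1
    }
  }
  M / sum(M)
}

# Direct-formula Haralick descriptors with explicit double loops.
bruteHaralick <- function(P) {
  L <- nrow(P)
  asm <- ent <- con <- hom <- 0
  mi <- mj <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    asm <- asm + p^2
    if (p > 0) ent <- ent - p * log2(p)
    con <- con + (i - j)^2 * p
    hom <- hom + p / (1 + (i - j)^2)
    mi <- mi + (i - 1) * p
    mj <- mj + (j - 1) * p
  }
  vi <- vj <- cv <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    vi <- vi + ((i - 1) - mi)^2 * p
    vj <- vj + ((j - 1) - mj)^2 * p
    cv <- cv + ((i - 1) - mi) * ((j - 1) - mj) * p
  }
  s <- sqrt(vi * vj)
  c(ASM = asm, entropy = ent, contrast = con, homogeneity = hom,
    variance = vi, correlation = if (s == 0) 0 else cv / s)
}

# Scott-Knott oracle: independent recursion that evaluates every ordered
# split by explicit group-mean arithmetic.
skOracle <- function(means, s2, df, alpha = 0.05) {
  nm <- names(means)
  rec <- function(idx, nextLab, labs) {
    k <- length(idx)
    if (k < 2) {
      labs[idx] <- nextLab
      return(list(labs = labs, nextLab = nextLab + 1L))
    }
    m <- means[idx]
    best <- -Inf; bestS <- 1L
    for (s in 1:(k - 1)) {
      g1 <- m[1:s]; g2 <- m[(s + 1):k]
      gm <- mean(m)
      b <- s * (mean(g1) - gm)^2 + (k - s) * (mean(g2) - gm)^2
      if (b > best) { best <- b; bestS <- s }
    }
    sig02 <- (sum((m - mean(m))^2) + df * s2) / (k + df)
    lam <- pi / (2 * (pi - 2)) * best / sig02
    if (sig02 > 0 && lam > qchisq(1 - alpha, k / (pi - 2))) {
      r1 <- rec(idx[1:bestS], nextLab, labs)
      rec(idx[(bestS + 1):k], r1$nextLab, r1$labs)
    } else {
      labs[idx] <- nextLab
      list(labs = labs, nextLab = nextLab + 1L)
    }
  }
  o <- order(means, decreasing = TRUE)
  res <- rec(o, 1L, integer(length(means)))
  setNames(res$labs, nm)
}

# Small rendered plot batch with its ground truth.
renderBatch <- function(n, seed = 1, canvas = 48, areaGain = 0.02,
                        textureGain = 0.3, biomass = NULL, vigor = NULL) {
  rp <- renderParams(canvas = canvas, areaGain = areaGain,
                     textureGain = textureGain)
  if (is.null(biomass))
    biomass <- withr::with_seed(seed, pmax(rnorm(n, 4, 1.2), 0))
  if (is.null(vigor))
    vigor <- withr::with_seed(seed + 1, pmax(rnorm(n, 1, 0.3), 0))
  imgs <- lapply(seq_len(n), function(i)
    renderPlotImage(biomass[i], vigor[i], rp, seed = seed * 1000 + i))
  list(images = imgs, biomass = biomass, vigor = vigor,
       trueN = vapply(imgs, function(im) sum(plantMask(im)), numeric(1)))
}

# Random quantized image with full mask, for texture oracles.
randomGray <- function(seed, H = 16, W = 16, levels = 8) {
  withr::with_seed(seed,
    matrix(sample.int(levels, H * W, replace = TRUE), H, W))
}
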
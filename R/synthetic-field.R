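# Synthetic field-trial generator: augmented block designs, conventional
# traits drawn under the genetic-evaluation variance structure, and rendered
# plot images whose projected area, canopy texture and greenness follow
# latent biomass and vigor scores.

#' Build an augmented block design
#'
#' Lays out one environment of an augmented block trial: every block contains
#' the same replicated check genotypes plus a disjoint set of unreplicated
#' progenies, so total plots = \code{nBlocks * (length(checks) +
#' progeniesPerBlock)}.  Plot order within the field is randomized
#' reproducibly from \code{seed}.
#'
#' @param nBlocks number of blocks (>= 1).
#' @param checks character vector of check genotype labels (non-empty).
#' @param progeniesPerBlock number of progenies per block.
#' @param seed integer seed controlling the randomized plot order.
#' @param environment environment label.
#' @param progenyLabels optional vector of \code{nBlocks *
#'   progeniesPerBlock} globally unique progeny labels; autogenerated when
#'   \code{NULL}.
#' @return A \linkS4class{FieldDesign}.
#' @examples
#' d <- makeDesign(5, c("S12", "Miyagui", "Mombaca"), 42, seed = 1)
#' nPlots(d)   # 225
#' @export
makeDesign <- function(nBlocks, checks, progeniesPerBlock, seed = 1L,
                       environment = "ENV1", progenyLabels = NULL) {
  stopifnot(nBlocks >= 1, length(checks) >= 1, progeniesPerBlock >= 0)
  checks <- as.character(checks)
  if (anyDuplicated(checks)) stop("check labels must be unique")
  nProg <- nBlocks * progeniesPerBlock
  if (is.null(progenyLabels)) {
    progenyLabels <- if (nProg)
      sprintf("P%03d", seq_len(nProg)) else character(0)
  }
  progenyLabels <- as.character(progenyLabels)
  if (length(progenyLabels) != nProg)
    stop("need ", nProg, " progeny labels, got ", length(progenyLabels))
  if (anyDuplicated(progenyLabels) || any(progenyLabels %in% checks))
    stop("duplicate progeny label across blocks")
  rows <- do.call(rbind, lapply(seq_len(nBlocks), function(b) {
    prog <- progenyLabels[seq_len(progeniesPerBlock) +
                            (b - 1L) * progeniesPerBlock]
    data.frame(block = b,
               entry = c(checks, prog),
               role = rep(c("check", "progeny"),
                          c(length(checks), progeniesPerBlock)),
               stringsAsFactors = FALSE)
  }))
  rows <- withSeed(seed, {
    # randomize plot order within each block
    do.call(rbind, lapply(split(rows, rows$block),
                          function(d) d[sample.int(nrow(d)), ]))
  })
  rows$plot <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  new("FieldDesign", plots = rows[, c("plot", "block", "entry", "role")],
      checks = checks, environment = environment)
}

#' Variance specification for one simulated trait
#'
#' Collects the mean, the variance components of the trait model (genotype,
#' genotype-by-harvest, block-within-harvest, residual) and the fixed harvest
#' and check effects used by \code{\link{simulateTraits}}.
#'
#' @param mu trait mean.
#' @param sigma2G genetic (progeny) variance.
#' @param sigma2GH genotype-by-harvest interaction variance.
#' @param sigma2B block(-within-harvest) variance.
#' @param sigma2E residual variance.
#' @param harvestEffects fixed effect per harvest (recycled/truncated to the
#'   number of harvests; default 0).
#' @param checkEffects named fixed effect per check (default 0).
#' @return A list of class \code{"varianceSpec"}.
#' @export
varianceSpec <- function(mu, sigma2G, sigma2GH = 0, sigma2B = 0, sigma2E,
                         harvestEffects = 0, checkEffects = numeric(0)) {
  v <- c(sigma2G, sigma2GH, sigma2B, sigma2E)
  if (any(!is.finite(v)) || any(v < 0)) stop("all variances must be >= 0")
  structure(list(mu = mu, sigma2G = sigma2G, sigma2GH = sigma2GH,
                 sigma2B = sigma2B, sigma2E = sigma2E,
                 harvestEffects = harvestEffects,
                 checkEffects = checkEffects),
            class = "varianceSpec")
}

#' Default trait variance specifications
#'
#' Realistic per-trait means and variance components for a tropical forage
#' single-plant trial: canopy height in cm, green matter yield in kg/plant,
#' leaf/stem/dead dry components in g/plant.
#'
#' @return Named list of \code{\link{varianceSpec}} objects for CH, GMY,
#'   LDMY, SDMY and DMP.
#' @export
defaultTraitSpecs <- function() {
  list(
    CH   = varianceSpec(mu = 80,  sigma2G = 36,   sigma2GH = 4,
                        sigma2B = 9,    sigma2E = 64,
                        harvestEffects = c(-5, 0, 5, 8)),
    GMY  = varianceSpec(mu = 4,   sigma2G = 0.9,  sigma2GH = 0.05,
                        sigma2B = 0.15, sigma2E = 0.5,
                        harvestEffects = c(-0.5, 0, 0.5, 0.8)),
    LDMY = varianceSpec(mu = 420, sigma2G = 8100, sigma2GH = 400,
                        sigma2B = 900,  sigma2E = 4900,
                        harvestEffects = c(-40, 0, 40, 60)),
    SDMY = varianceSpec(mu = 260, sigma2G = 3600, sigma2GH = 250,
                        sigma2B = 600,  sigma2E = 3600,
                        harvestEffects = c(-25, 0, 25, 40)),
    DMP  = varianceSpec(mu = 90,  sigma2G = 400,  sigma2GH = 60,
                        sigma2B = 100,  sigma2E = 400,
                        harvestEffects = c(-10, 0, 10, 15)))
}

#' Simulate conventional traits on a field design
#'
#' Draws each record as mu + check/harvest fixed effects + G + GH + B + e
#' with G ~ N(0, sigma2G), GH ~ N(0, sigma2GH), B ~ N(0, sigma2B) (block
#' within harvest) and e ~ N(0, sigma2E).  Genetic effects of the different
#' traits share a latent merit score with pairwise correlation
#' \code{geneticCor}, so yield traits rank genotypes consistently.  Negative
#' values are truncated at 0 and TDMY is computed as
#' (LDMY + SDMY + DMP) / 1000 (components in g/plant, total in kg/plant).
#' Latent per-plot \code{biomass} (the GMY record) and per-entry
#' \code{vigor} scores are appended for image rendering.
#'
#' @param design a \linkS4class{FieldDesign}.
#' @param specs named list of \code{\link{varianceSpec}} objects; defaults to
#'   \code{\link{defaultTraitSpecs}()}.
#' @param nHarvests number of harvests (>= 1).
#' @param seed integer seed; identical seeds give identical tables.
#' @param geneticCor pairwise genetic correlation of the simulated traits.
#' @return data.frame keyed by (entry, harvest, block) with trait columns,
#'   TDMY, biomass and vigor.  The true per-entry genetic effects are
#'   attached as \code{attr(, "geneticEffects")} (progenies) and the true
#'   block-within-harvest effects as \code{attr(, "blockEffects")}.
#' @export
simulateTraits <- function(design, specs = defaultTraitSpecs(),
                           nHarvests = 4L, seed = 1L, geneticCor = 0.8) {
  if (nHarvests < 1) stop("nHarvests must be >= 1")
  stopifnot(is(design, "FieldDesign"))
  df <- designTable(design)
  entries <- entryNames(design)
  progenies <- unique(df$entry[df$role == "progeny"])
  blocks <- sort(unique(df$block))
  traits <- names(specs)
  withSeed(seed, {
    u <- stats::setNames(rnorm(length(entries)), entries)  # shared merit
    vigor <- stats::setNames(pmax(rnorm(length(entries), 1, 0.3), 0), entries)
    g <- lapply(specs, function(sp) {
      e <- rnorm(length(entries))
      stats::setNames(sqrt(sp$sigma2G) *
        (sqrt(geneticCor) * u + sqrt(1 - geneticCor) * e), entries)
    })
    gh <- lapply(specs, function(sp)
      matrix(rnorm(length(entries) * nHarvests, 0, sqrt(sp$sigma2GH)),
             length(entries), nHarvests, dimnames = list(entries, NULL)))
    bh <- lapply(specs, function(sp)
      matrix(rnorm(length(blocks) * nHarvests, 0, sqrt(sp$sigma2B)),
             length(blocks), nHarvests, dimnames = list(blocks, NULL)))
    out <- do.call(rbind, lapply(seq_len(nHarvests), function(h) {
      d <- df
      d$harvest <- h
      d
    }))
    for (tr in traits) {
      sp <- specs[[tr]]
      he <- rep_len(sp$harvestEffects, nHarvests)
      ce <- sp$checkEffects
      fx <- numeric(nrow(out))
      isC <- out$role == "check"
      if (length(ce)) {
        idx <- match(out$entry[isC], names(ce))
        fx[isC] <- ifelse(is.na(idx), 0, ce[idx])
      }
      val <- sp$mu + fx + he[out$harvest] +
        g[[tr]][out$entry] +
        gh[[tr]][cbind(match(out$entry, entries), out$harvest)] +
        bh[[tr]][cbind(match(out$block, blocks), out$harvest)] +
        rnorm(nrow(out), 0, sqrt(sp$sigma2E))
      out[[tr]] <- pmax(val, 0)
    }
    if (all(c("LDMY", "SDMY", "DMP") %in% traits))
      out$TDMY <- (out$LDMY + out$SDMY + out$DMP) / 1000
    if ("GMY" %in% traits) out$biomass <- out$GMY
    out$vigor <- vigor[out$entry]
    rownames(out) <- NULL
    gEff <- lapply(g, function(x) x[progenies])
    out <- out[, c("plot", "block", "entry", "role", "harvest", traits,
                   intersect(c("TDMY", "biomass", "vigor"), names(out)))]
    attr(out, "geneticEffects") <- gEff
    attr(out, "blockEffects") <- bh
    out
  })
}

#' Rendering parameters for synthetic plot images
#'
#' Controls how latent biomass and vigor are turned into pixels: biomass sets
#' the projected plant area (area gain) and the canopy texture complexity
#' (texture-frequency gain); vigor sets the green chromaticity of the plant
#' pixels.  Soil is brown Gaussian noise; the plant footprint is the top-area
#' region of a field of overlapping elliptical tussock lobes.
#'
#' @param canvas image height/width in pixels (>= 32).
#' @param soilColor mean soil RGB.
#' @param soilNoiseSd additive per-channel soil noise sd (8-bit units).
#' @param soilShadingSd sd of the multiplicative soil shading field shared
#'   by all channels (surface roughness / micro-shadows); shading scales
#'   R, G and B together, so soil chromaticity stays brown.
#' @param hueGain greenness gain: plant green channel = 60 + hueGain *
#'   vigor/(1+vigor).
#' @param textureGain texture-frequency gain linking biomass to the fraction
#'   of high-frequency canopy texture.
#' @param textureAmp base texture amplitude (8-bit units).
#' @param areaGain canvas fraction of plant pixels per unit biomass.
#' @param areaJitterSd lognormal-style jitter on the rendered area.
#' @param illumination global illumination multiplier for a flight.
#' @param nativeGsd native ground sampling distance (cm/pixel).
#' @return list of class \code{"renderParams"}.
#' @export
renderParams <- function(canvas = c(256L, 256L), soilColor = c(120, 90, 70),
                         soilNoiseSd = 2.5, soilShadingSd = 0.08,
                         hueGain = 120, textureGain = 0.15,
                         textureAmp = 14, areaGain = 0.05,
                         areaJitterSd = 0.05, illumination = 1,
                         nativeGsd = 0.27) {
  canvas <- rep_len(as.integer(canvas), 2L)
  if (any(canvas < 32L)) stop("canvas must be at least 32 x 32 pixels")
  if (min(hueGain, textureGain, textureAmp, areaGain, areaJitterSd) < 0)
    stop("gains must be >= 0")
  structure(list(canvas = canvas, soilColor = soilColor,
                 soilNoiseSd = soilNoiseSd, soilShadingSd = soilShadingSd,
                 hueGain = hueGain,
                 textureGain = textureGain, textureAmp = textureAmp,
                 areaGain = areaGain, areaJitterSd = areaJitterSd,
                 illumination = illumination, nativeGsd = nativeGsd),
            class = "renderParams")
}

# moving-average blur with a square window, edge-padded by replication
blurMat <- function(m, w) {
  if (w <= 1L) return(m)
  k <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  smooth1 <- function(x) {
    xp <- c(rep(x[1L], pad), x, rep(x[length(x)], w - 1L - pad))
    stats::filter(xp, k, sides = 1)[w:(length(x) + w - 1L)]
  }
  m <- apply(m, 2L, smooth1)
  t(apply(t(m), 2L, smooth1))
}

#' Render a synthetic plot image
#'
#' Draws soil, then places a plant whose mask area grows with
#' \code{biomass}, whose within-canopy texture complexity and variance grow
#' with \code{biomass}, and whose mean green chromaticity grows with
#' \code{vigor}.  The exact ground-truth mask is attached.  Texture is
#' applied as a per-pixel luminance factor common to all channels, so
#' chromaticity carries the vigor signal while texture carries the biomass
#' signal.
#'
#' @param biomass latent biomass score (>= 0); 0 gives a soil-only image.
#' @param vigor latent vigor score (>= 0).
#' @param params a \code{\link{renderParams}} list.
#' @param seed integer seed; same inputs and seed give bit-identical images.
#' @param meta extra metadata stored on the image.
#' @return A \linkS4class{PlotImage} with ground-truth mask.
#' @export
renderPlotImage <- function(biomass, vigor, params = renderParams(),
                            seed = 1L, meta = list()) {
  stopifnot(biomass >= 0, vigor >= 0)
  H <- params$canvas[1L]; W <- params$canvas[2L]
  withSeed(seed, {
    il <- params$illumination
    shade <- 1 + params$soilShadingSd * blurMat(matrix(rnorm(H * W), H, W), 3L)
    soil <- array(0, c(H, W, 3L))
    for (c3 in 1:3)
      soil[, , c3] <- params$soilColor[c3] * il * shade +
        rnorm(H * W, 0, params$soilNoiseSd)
    jitter <- max(0.2, 1 + params$areaJitterSd * rnorm(1L))
    n <- min(round(params$areaGain * biomass * jitter * H * W),
             round(0.85 * H * W))
    mask <- matrix(0, H, W)
    img <- soil
    if (biomass > 0 && n >= 1) {
      # canopy potential: elliptical tussock lobes around the plot centre
      nl <- 6L
      cy <- H / 2 + rnorm(nl, 0, H / 10)
      cx <- W / 2 + rnorm(nl, 0, W / 10)
      ry <- runif(nl, H / 8, H / 3.5)
      rx <- runif(nl, W / 8, W / 3.5)
      th <- runif(nl, 0, pi)
      yy <- matrix(seq_len(H), H, W)
      xx <- matrix(seq_len(W), H, W, byrow = TRUE)
      phi <- matrix(0, H, W)
      for (i in seq_len(nl)) {
        dy <- yy - cy[i]; dx <- xx - cx[i]
        u <- cos(th[i]) * dx + sin(th[i]) * dy
        v <- -sin(th[i]) * dx + cos(th[i]) * dy
        phi <- phi + exp(-((u / rx[i])^2 + (v / ry[i])^2))
      }
      phi <- phi + 0.10 * blurMat(matrix(rnorm(H * W), H, W), 5L)
      mask[order(phi, decreasing = TRUE)[seq_len(n)]] <- 1
      # plant base colour: vigor drives green chromaticity
      gamma <- vigor / (1 + vigor)
      base <- c(70, 60 + params$hueGain * gamma, 55)
      # texture: biomass shifts weight from a smooth to a white field and
      # raises the amplitude, so both complexity and variance grow
      lam <- params$textureGain * biomass / (1 + params$textureGain * biomass)
      sm <- blurMat(matrix(rnorm(H * W), H, W), 5L)
      sm <- sm / max(stats::sd(as.vector(sm)), 1e-9)
      wn <- matrix(rnorm(H * W), H, W)
      amp <- params$textureAmp * (1 + 0.25 * lam) /
        sqrt((1 - lam)^2 + lam^2)
      tex <- amp * ((1 - lam) * sm + lam * wn)
      fac <- pmin(pmax(1 + tex / 130, 0.5), 1.5)
      idx <- mask == 1
      px <- matrix(0, sum(idx), 3L)
      for (c3 in 1:3) px[, c3] <- base[c3] * il * fac[idx]
      # keep chromaticity exact when clipping highlights
      over <- pmax(apply(px, 1L, max), 255) / 255
      px <- px / over
      for (c3 in 1:3) {
        ch <- img[, , c3]
        ch[idx] <- px[, c3]
        img[, , c3] <- ch
      }
    }
    img <- round(pmin(pmax(img, 0), 255))
    PlotImage(img, mask, c(list(gsd = params$nativeGsd), meta))
  })
}

#' Downsample a plot image to a coarser ground sampling distance
#'
#' Area-weighted block averaging by the factor \code{targetGsd /
#' nativeGsd}; the mask is downsampled by majority vote (ties go to
#' background).  Upsampling is refused.
#'
#' @param image a \linkS4class{PlotImage} whose metadata carries \code{gsd}.
#' @param targetGsd target GSD in cm/pixel (>= native GSD).
#' @return A \linkS4class{PlotImage} at the new GSD.
#' @export
resampleGsd <- function(image, targetGsd) {
  stopifnot(is(image, "PlotImage"))
  native <- gsd(image)
  if (is.na(native)) stop("image metadata carries no GSD")
  f <- targetGsd / native
  if (f < 1 - 1e-9) stop("target GSD below native GSD: no upsampling")
  if (abs(f - 1) < 1e-9) return(image)
  d <- dim(rgbArray(image))
  Hout <- floor(d[1L] / f); Wout <- floor(d[2L] / f)
  if (Hout < 1 || Wout < 1) stop("target GSD too coarse for this image")
  wmat <- function(nout, f, nin) {
    Wm <- matrix(0, nout, nin)
    for (i in seq_len(nout)) {
      a <- (i - 1) * f; b <- i * f
      j <- floor(a):min(ceiling(b) - 1, nin - 1)
      ov <- pmin(b, j + 1) - pmax(a, j)
      Wm[i, j + 1] <- ov / f
    }
    Wm
  }
  Wr <- wmat(Hout, f, d[1L]); Wc <- wmat(Wout, f, d[2L])
  out <- array(0, c(Hout, Wout, 3L))
  for (c3 in 1:3) out[, , c3] <- Wr %*% rgbArray(image)[, , c3] %*% t(Wc)
  out <- pmin(pmax(out, 0), 255)
  m <- NULL
  if (hasMask(image)) {
    mm <- Wr %*% plantMask(image) %*% t(Wc)
    m <- (mm > 0.5) + 0
  }
  meta <- imageMeta(image)
  meta$gsd <- targetGsd
  PlotImage(out, m, meta)
}

#' Ground sampling distance from the pinhole camera model
#'
#' GSD (cm/pixel) = sensor width (mm) x flight height (m) x 100 /
#' (focal length (mm) x image width (px)), assuming a nadir view.
#' Defaults are the DJI Phantom 4 Pro intrinsics (1" sensor, 13.2 mm wide,
#' 8.8 mm focal length, 5472 px across).
#'
#' @param flightHeight flight altitude above ground in m.
#' @param sensorWidth sensor width in mm.
#' @param focalLength focal length in mm.
#' @param imageWidth image width in pixels.
#' @return GSD in cm/pixel.
#' @examples
#' round(computeGsd(10), 2)   # 0.27
#' round(computeGsd(55), 1)   # 1.5
#' @export
computeGsd <- function(flightHeight, sensorWidth = 13.2, focalLength = 8.8,
                       imageWidth = 5472) {
  v <- c(flightHeight, sensorWidth, focalLength, imageWidth)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all camera-geometry inputs must be > 0")
  sensorWidth * flightHeight * 100 / (focalLength * imageWidth)
}

#' Write a synthetic experiment to disk
#'
#' Writes \code{design.csv}, \code{traits.csv}, 8-bit RGB plot images and
#' single-channel masks as PNG (named \code{{env}_{dap}_{gsd}_{entry}.png}),
#' plus a \code{manifest.json} listing every file and the seeds used.
#'
#' @param dir output directory (created if needed).
#' @param design a \linkS4class{FieldDesign}.
#' @param traits table from \code{\link{simulateTraits}}.
#' @param images named list of \linkS4class{PlotImage} objects (optional).
#' @param seed seed recorded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
writeSyntheticExperiment <- function(dir, design, traits, images = list(),
                                     seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  dPath <- file.path(dir, "design.csv")
  write.csv(designTable(design), dPath, row.names = FALSE)
  files <- c(files, "design.csv")
  tPath <- file.path(dir, "traits.csv")
  write.csv(traits, tPath, row.names = FALSE)
  files <- c(files, "traits.csv")
  for (nm in names(images)) {
    im <- images[[nm]]
    meta <- imageMeta(im)
    stem <- sprintf("%s_%s_%s_%s",
                    meta$environment %||% "ENV", meta$dap %||% 0,
                    meta$gsd %||% "NA", meta$entry %||% nm)
    png::writePNG(rgbArray(im) / 255, file.path(dir, paste0(stem, ".png")))
    files <- c(files, paste0(stem, ".png"))
    if (hasMask(im)) {
      png::writePNG(plantMask(im),
                    file.path(dir, paste0(stem, "_mask.png")))
      files <- c(files, paste0(stem, "_mask.png"))
    }
  }
  manifest <- list(files = files, seed = seed,
                   environment = design@environment,
                   nPlots = nPlots(design))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
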
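# Per-plot digital-trait extraction: distribution statistics over VI maps,
# Haralick descriptors over GLCMs, plant pixel count; assembly into a
# FeatureTable and min-max normalization.

#' Seven summary statistics of a distribution
#'
#' Mean, 25th/50th/75th percentiles (linear-interpolation convention),
#' population standard deviation, moment-based skewness and excess
#' kurtosis.  Degenerate inputs (zero spread) get skewness and kurtosis 0
#' with a warning.
#'
#' @param values numeric vector; NAs are dropped; at least one value must
#'   remain.
#' @return named numeric vector: mean, q25, q50, q75, stdev, skewness,
#'   kurtosis.
#' @export
summarizeDistribution <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no valid values to summarize")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- popSd(values)
  if (s == 0) {
    warning("degenerate distribution (zero spread): skewness/kurtosis set to 0")
    sk <- 0; ku <- 0
  } else {
    z <- values - mean(values)
    sk <- mean(z^3) / s^3
    ku <- mean(z^4) / s^4 - 3
  }
  c(mean = mean(values), q25 = q[1L], q50 = q[2L], q75 = q[3L],
    stdev = s, skewness = sk, kurtosis = ku)
}

#' Count plant pixels in a mask
#'
#' The structural biomass proxy (\code{n_pixels}).
#'
#' @param mask 0/1 matrix or a \linkS4class{PlotImage} with mask.
#' @return integer count of mask = 1 pixels.
#' @export
countPlantPixels <- function(mask) {
  if (is(mask, "PlotImage")) mask <- plantMask(mask)
  as.integer(sum(mask == 1))
}

#' Extraction configuration
#'
#' The full configuration (all defaults) yields 171 features per plot:
#' 14 VIs x 7 statistics + 12 GLCMs (3 distances x 4 angles) x 6 Haralick
#' descriptors + the plant pixel count.
#'
#' @param vis vegetation-index names (subset of the registry).
#' @param registry VI registry; see \code{\link{viRegistry}}.
#' @param glcmDistances GLCM offset distances in pixels.
#' @param glcmAngles GLCM offset angles in degrees.
#' @param glcmLevels gray levels for quantization.
#' @param descriptors Haralick descriptor names.
#' @param pixelCount include \code{n_pixels}.
#' @return list of class \code{"extractionConfig"}.
#' @export
extractionConfig <- function(vis = names(viRegistry()),
                             registry = viRegistry(),
                             glcmDistances = c(1L, 5L, 10L),
                             glcmAngles = c(0, 45, 90, 135),
                             glcmLevels = 32L,
                             descriptors = c("ASM", "entropy", "contrast",
                                             "homogeneity", "variance",
                                             "correlation"),
                             pixelCount = TRUE) {
  stopifnot(all(vis %in% names(registry)))
  structure(list(vis = vis, registry = registry,
                 glcmDistances = as.integer(glcmDistances),
                 glcmAngles = glcmAngles, glcmLevels = as.integer(glcmLevels),
                 descriptors = descriptors, pixelCount = pixelCount),
            class = "extractionConfig")
}

featureCatalog <- function(config) {
  stats7 <- c("mean", "q25", "q50", "q75", "stdev", "skewness", "kurtosis")
  out <- data.frame(feature = character(0), group = character(0),
                    vi = character(0), stat = character(0),
                    descriptor = character(0), distance = integer(0),
                    angle = numeric(0), stringsAsFactors = FALSE)
  for (vi in config$vis)
    out <- rbind(out, data.frame(feature = paste(vi, stats7, sep = "_"),
                                 group = "vi", vi = vi, stat = stats7,
                                 descriptor = NA, distance = NA, angle = NA))
  for (d in config$glcmDistances) for (a in config$glcmAngles)
    out <- rbind(out, data.frame(
      feature = sprintf("%s_d%d_a%d", config$descriptors, d, a),
      group = "glcm", vi = NA, stat = NA, descriptor = config$descriptors,
      distance = d, angle = a))
  if (config$pixelCount)
    out <- rbind(out, data.frame(feature = "n_pixels", group = "structural",
                                 vi = NA, stat = NA, descriptor = NA,
                                 distance = NA, angle = NA))
  rownames(out) <- out$feature
  out
}

extractOnePlot <- function(image, mask, config) {
  catalog <- featureCatalog(config)
  vals <- setNames(rep(NA_real_, nrow(catalog)), catalog$feature)
  rgb <- if (is(image, "PlotImage")) rgbArray(image) else image
  nPlant <- sum(mask == 1)
  if (config$pixelCount) vals["n_pixels"] <- nPlant
  if (nPlant == 0) return(list(values = vals, failed = TRUE))
  ok <- TRUE
  for (vi in config$vis) {
    m <- computeViMap(rgb, mask, vi, config$registry)
    v <- m[is.finite(m)]
    if (length(v)) {
      st <- suppressWarnings(summarizeDistribution(v))
      vals[paste(vi, names(st), sep = "_")] <- st
    } else ok <- FALSE
  }
  gray <- quantizeGray(rgb, mask, config$glcmLevels)
  for (d in config$glcmDistances) for (a in config$glcmAngles) {
    res <- tryCatch({
      g <- computeGlcm(gray, glcmConfig(d, a, config$glcmLevels))
      haralickDescriptors(g)[config$descriptors]
    }, error = function(e) NULL)
    if (is.null(res)) ok <- FALSE
    else vals[sprintf("%s_d%d_a%d", config$descriptors, d, a)] <- res
  }
  list(values = vals, failed = !ok)
}

#' Extract the digital-trait table for a batch of plots
#'
#' One column per plot, one row per feature.  Plots whose extraction fails
#' (no plant pixels, no valid GLCM pair) are flagged in
#' \code{colData()$failed} rather than dropped.
#'
#' @param plots named list; each element a \linkS4class{PlotImage} carrying
#'   a mask, or a list with elements \code{image} and \code{mask}.
#' @param config an \code{\link{extractionConfig}}.
#' @return A \linkS4class{FeatureTable} with assay \code{"raw"}; plot
#'   metadata (entry, environment, dap, gsd) is carried into
#'   \code{colData}.
#' @export
extractFeatureTable <- function(plots, config = extractionConfig()) {
  if (!length(plots)) stop("need at least one plot")
  catalog <- featureCatalog(config)
  nm <- names(plots) %||% paste0("plot", seq_along(plots))
  raw <- matrix(NA_real_, nrow(catalog), length(plots),
                dimnames = list(catalog$feature, nm))
  failed <- logical(length(plots))
  cd <- vector("list", length(plots))
  for (k in seq_along(plots)) {
    p <- plots[[k]]
    if (is(p, "PlotImage")) {
      img <- p; msk <- plantMask(p); meta <- imageMeta(p)
    } else {
      img <- p$image; msk <- p$mask
      meta <- if (is(img, "PlotImage")) imageMeta(img) else list()
    }
    res <- extractOnePlot(img, msk, config)
    raw[, k] <- res$values
    failed[k] <- res$failed
    cd[[k]] <- data.frame(
      entry = meta$entry %||% nm[k],
      environment = meta$environment %||% NA_character_,
      dap = meta$dap %||% NA_real_,
      gsd = meta$gsd %||% NA_real_)
  }
  if (any(failed))
    warning(sum(failed), " plot(s) flagged: extraction incomplete")
  coldf <- do.call(rbind, cd)
  coldf$failed <- failed
  rownames(coldf) <- nm
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw),
    rowData = S4Vectors::DataFrame(catalog[, -1, drop = FALSE]),
    colData = S4Vectors::DataFrame(coldf))
  new("FeatureTable", se)
}

minmaxVec <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1L]) || diff(rng) == 0) return(NULL)
  (x - rng[1L]) / diff(rng)
}

#' Min-max normalize features to [0, 1]
#'
#' x' = (x - min x) / (max x - min x), applied per feature across plots.
#' Constant features map to all zeros with a warning.  For a
#' \linkS4class{FeatureTable} the result is stored as assay
#' \code{"normalized"}; matrices and data frames are normalized per column.
#'
#' @param table a \linkS4class{FeatureTable}, matrix or data.frame of
#'   numeric columns.
#' @return Same shape as the input, normalized.
#' @export
minmaxNormalize <- function(table) {
  if (is(table, "FeatureTable")) {
    raw <- SummarizedExperiment::assay(table, "raw")
    norm <- t(apply(raw, 1L, function(x) {
      v <- minmaxVec(x)
      if (is.null(v)) rep(0, length(x)) else v
    }))
    const <- apply(raw, 1L, function(x) {
      r <- range(x, na.rm = TRUE)
      !is.finite(r[1L]) || diff(r) == 0
    })
    if (any(const))
      warning(sum(const), " constant feature(s) normalized to all zeros")
    dimnames(norm) <- dimnames(raw)
    SummarizedExperiment::assay(table, "normalized") <- norm
    return(table)
  }
  wasDf <- is.data.frame(table)
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("non-numeric column in table")
  out <- apply(m, 2L, function(x) {
    v <- minmaxVec(x)
    if (is.null(v)) {
      warning("constant column normalized to all zeros")
      rep(0, length(x))
    } else v
  })
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  if (wasDf) as.data.frame(out) else out
}
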
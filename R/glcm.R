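# Gray-level co-occurrence matrices and Haralick descriptors, computed over
# plant pixels only (background excluded pairwise).

#' GLCM configuration
#'
#' @param distance offset length in pixels (>= 1).
#' @param angle offset direction in degrees; one of 0, 45, 90, 135 with
#'   0 = +x (rightward) and 45 = up-right, in row-major top-left-origin
#'   coordinates.
#' @param levels number of gray levels (>= 2).
#' @param symmetric accumulate each pair in both orders.
#' @param normalized scale counts to sum 1.
#' @return list of class \code{"glcmConfig"}.
#' @export
glcmConfig <- function(distance = 1L, angle = 0, levels = 32L,
                       symmetric = TRUE, normalized = TRUE) {
  if (distance < 1) stop("distance must be >= 1")
  if (!angle %in% c(0, 45, 90, 135))
    stop("angle must be one of 0, 45, 90, 135")
  if (levels < 2) stop("levels must be >= 2")
  structure(list(distance = as.integer(distance), angle = angle,
                 levels = as.integer(levels), symmetric = symmetric,
                 normalized = normalized), class = "glcmConfig")
}

#' Quantize an RGB image to gray levels over the plant-pixel range
#'
#' Luminance 0.299 R + 0.587 G + 0.114 B, linearly binned into
#' \code{levels} levels between the minimum and maximum luminance of the
#' plant pixels.  Background pixels are NA.
#'
#' @param rgb a \linkS4class{PlotImage} or H x W x 3 array.
#' @param mask 0/1 plant mask.
#' @param levels number of gray levels.
#' @return integer matrix of levels in 1..levels, NA outside the mask.
#' @export
quantizeGray <- function(rgb, mask, levels = 32L) {
  if (is(rgb, "PlotImage")) {
    if (missing(mask)) mask <- plantMask(rgb)
    rgb <- rgbArray(rgb)
  }
  stopIfNot3Channel(rgb)
  lum <- matrix(0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] +
                  0.114 * rgb[, , 3L], dim(rgb)[1L], dim(rgb)[2L])
  lum[mask != 1] <- NA_real_
  v <- lum[is.finite(lum)]
  if (!length(v)) stop("no plant pixels to quantize")
  rng <- range(v)
  if (diff(rng) == 0) {
    q <- lum
    q[is.finite(q)] <- 1L
  } else {
    q <- floor((lum - rng[1L]) / diff(rng) * levels) + 1L
    q[q > levels] <- levels
  }
  storage.mode(q) <- "integer"
  q
}

glcmOffset <- function(config) {
  a <- config$angle * pi / 180
  c(dr = -round(config$distance * sin(a)),
    dc = round(config$distance * cos(a)))
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts level pairs (p, p + offset) where both pixels are valid plant
#' pixels; accumulated symmetrically and normalized to sum 1 by default.
#'
#' @param gray integer level matrix (1..levels, NA = background), e.g. from
#'   \code{\link{quantizeGray}}.
#' @param config a \code{\link{glcmConfig}}.
#' @return levels x levels matrix.
#' @export
computeGlcm <- function(gray, config = glcmConfig()) {
  L <- config$levels
  if (any(gray > L, na.rm = TRUE)) stop("gray levels exceed config levels")
  off <- glcmOffset(config)
  H <- nrow(gray); W <- ncol(gray)
  r1 <- max(1L, 1L - off["dr"]):min(H, H - off["dr"])
  c1 <- max(1L, 1L - off["dc"]):min(W, W - off["dc"])
  if (!length(r1) || !length(c1)) stop("offset exceeds image size")
  a <- gray[r1, c1, drop = FALSE]
  b <- gray[r1 + off["dr"], c1 + off["dc"], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no valid plant-pixel pair for this offset")
  counts <- matrix(0, L, L)
  tab <- table(factor(a[keep], levels = seq_len(L)),
               factor(b[keep], levels = seq_len(L)))
  counts <- counts + as.matrix(tab)
  if (config$symmetric) counts <- counts + t(counts)
  if (config$normalized) counts <- counts / sum(counts)
  counts
}

#' Haralick descriptors of a normalized GLCM
#'
#' ASM = sum p^2; entropy = -sum p log2 p (0 log 0 = 0); contrast =
#' sum (i-j)^2 p; homogeneity = sum p / (1 + (i-j)^2); variance =
#' sum (i - mu)^2 p with mu the marginal mean; correlation =
#' sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j), defined as 0 when
#' sigma_i sigma_j = 0.  Indices are 0-based.
#'
#' @param glcm normalized co-occurrence matrix (sums to 1).
#' @return named numeric vector with ASM, entropy, contrast, homogeneity,
#'   variance, correlation.
#' @export
haralickDescriptors <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-8)
    stop("GLCM must be normalized to sum 1")
  L <- nrow(glcm)
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  p <- glcm
  asm <- sum(p^2)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  contrast <- sum((i - j)^2 * p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  mi <- sum(i * p)
  mj <- sum(j * p)
  varI <- sum((i - mi)^2 * p)
  varJ <- sum((j - mj)^2 * p)
  s <- sqrt(varI * varJ)
  corr <- if (s == 0) 0 else sum((i - mi) * (j - mj) * p) / s
  c(ASM = asm, entropy = entropy, contrast = contrast,
    homogeneity = homogeneity, variance = varI, correlation = corr)
}
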
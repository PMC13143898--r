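# Plant/background segmentation: MExG index map, Otsu or fixed-threshold
# binarization, and mask application.

#' Modified excess-green (MExG) index map
#'
#' Per-pixel MExG = 1.262 G - 0.884 R - 0.311 B on raw 8-bit channel values.
#' High values mark vegetation; thresholding the map separates plant from
#' soil.
#'
#' @param rgb a \linkS4class{PlotImage} or an H x W x 3 array.
#' @return H x W numeric matrix of index values.
#' @export
computeMexg <- function(rgb) {
  if (is(rgb, "PlotImage")) rgb <- rgbArray(rgb)
  stopIfNot3Channel(rgb)
  matrix(1.262 * rgb[, , 2L] - 0.884 * rgb[, , 1L] - 0.311 * rgb[, , 3L],
         dim(rgb)[1L], dim(rgb)[2L])
}

# Otsu's threshold on a continuous-valued map: the bin edge maximizing
# between-class variance over a 256-bin histogram of the finite values.
# With valleyEmphasis the criterion is weighted by one minus the histogram
# density at the candidate bin (valley-emphasis variant), which keeps the
# threshold in the gap between modes when one class is much smaller than
# the other -- small plants against a large soil background.
otsuThreshold <- function(map, nbins = 256L, valleyEmphasis = FALSE) {
  v <- map[is.finite(map)]
  rng <- range(v)
  if (diff(rng) <= 0)
    stop("degenerate histogram: map is constant, Otsu threshold undefined")
  h <- tabulate(pmin(pmax(floor((v - rng[1L]) / diff(rng) * nbins) + 1L, 1L),
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  muCum <- cumsum(p * seq_len(nbins))
  muT <- muCum[nbins]
  between <- (muT * omega - muCum)^2 / (omega * (1 - omega))
  if (valleyEmphasis) between <- (1 - p) * between
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1L] + k / nbins * diff(rng)
}

# 4-connected component labelling, used for optional small-object removal.
removeSmallObjects <- function(mask, minSize) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nextLab <- 0L
  for (start in which(mask == 1)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    comp <- start
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      i <- (cur - 1L) %% H + 1L; j <- (cur - 1L) %/% H + 1L
      for (nb in c(if (i > 1) cur - 1L, if (i < H) cur + 1L,
                   if (j > 1) cur - H, if (j < W) cur + H)) {
        if (mask[nb] == 1 && lab[nb] == 0L) {
          lab[nb] <- nextLab
          queue <- c(queue, nb)
          comp <- c(comp, nb)
        }
      }
    }
    if (length(comp) < minSize) mask[comp] <- 0
  }
  mask
}

#' Binarize an MExG map into a plant mask
#'
#' Threshold is picked by Otsu's criterion on a 256-bin histogram of the map
#' (default) or supplied as a fixed value; the mask is \code{map > t}.
#'
#' Otsu always proposes a split, including on vegetation-free plots where
#' any split only carves up soil noise.  The split is therefore accepted
#' only when the two classes separate by more than \code{minSeparation}
#' pooled within-class standard deviations (a unimodal Gaussian map scores
#' about 2.7); otherwise the plot is declared bare and the mask is empty.
#'
#' @param map numeric matrix (e.g. from \code{\link{computeMexg}}).
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold fixed threshold (required when \code{method = "fixed"}).
#' @param minObjectSize when > 0, connected plant components smaller than
#'   this many pixels are removed.
#' @param minSeparation bimodality guard for the Otsu path; set to 0 to
#'   disable.
#' @return 0/1 matrix with attributes \code{threshold} and
#'   \code{plantFraction}.
#' @export
binarizeMexg <- function(map, method = c("otsu", "fixed"), threshold = NULL,
                         minObjectSize = 0L, minSeparation = 3) {
  method <- match.arg(method)
  if (!all(is.finite(map))) stop("index map must be finite")
  t <- if (method == "otsu") otsuThreshold(map) else {
    if (is.null(threshold)) stop("method='fixed' needs a threshold")
    threshold
  }
  mask <- (map > t) + 0
  if (method == "otsu" && minSeparation > 0 && any(mask == 1) &&
      any(mask == 0)) {
    lo <- map[mask == 0]; hi <- map[mask == 1]
    pooled <- sqrt(mean(c((lo - mean(lo))^2, (hi - mean(hi))^2)))
    if (pooled > 0 && (mean(hi) - mean(lo)) / pooled < minSeparation) {
      mask[] <- 0
      t <- Inf
    }
  }
  if (minObjectSize > 0L) mask <- removeSmallObjects(mask, minObjectSize)
  attr(mask, "threshold") <- t
  attr(mask, "plantFraction") <- mean(mask)
  mask
}

#' Segment a plot image
#'
#' Convenience wrapper: MExG map, binarization, and attachment of the
#' estimated mask to the image.
#'
#' @inheritParams binarizeMexg
#' @param image a \linkS4class{PlotImage}.
#' @return The image with the estimated mask attached.
#' @export
segmentPlot <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                        minObjectSize = 0L, minSeparation = 3) {
  mask <- binarizeMexg(computeMexg(image), method, threshold, minObjectSize,
                       minSeparation)
  attributes(mask) <- attributes(mask)["dim"]
  PlotImage(rgbArray(image), mask, imageMeta(image))
}

#' Apply a plant mask to an image
#'
#' Background pixels are flagged invalid (set to \code{NA}), not zero-filled,
#' so downstream statistics exclude them rather than averaging them in.
#'
#' @param rgb a \linkS4class{PlotImage} or H x W x 3 array.
#' @param mask 0/1 matrix of matching dimensions.
#' @return H x W x 3 array with \code{NA} outside the mask.
#' @export
applyMask <- function(rgb, mask) {
  if (is(rgb, "PlotImage")) rgb <- rgbArray(rgb)
  stopIfNot3Channel(rgb)
  if (!identical(dim(rgb)[1:2], dim(mask)))
    stop("mask dimensions do not match the image")
  bad <- mask != 1
  for (c3 in 1:3) {
    ch <- rgb[, , c3]
    ch[bad] <- NA_real_
    rgb[, , c3] <- ch
  }
  rgb
}
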
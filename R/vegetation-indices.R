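# Registry of RGB vegetation indices.  Indices are computed either on raw
# 8-bit channel values (R, G, B) or on chromatic coordinates
# r = R/(R+G+B) etc.; zero denominators invalidate the pixel (NA).

safeDiv <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Vegetation-index registry
#'
#' Named list of 14 per-pixel RGB vegetation indices in their common
#' literature forms.  Each entry is a function of raw channel matrices
#' \code{R}, \code{G}, \code{B} (0-255).  Chromatic-coordinate indices (ExG,
#' ExR, ExGR, VDVI) normalize by R+G+B first.  The registry is an argument
#' to the extraction functions so alternative formulations can be swapped
#' in.
#'
#' @return Named list of functions \code{f(R, G, B)}.
#' @export
viRegistry <- function() {
  chrom <- function(R, G, B) {
    s <- R + G + B
    list(r = safeDiv(R, s), g = safeDiv(G, s), b = safeDiv(B, s))
  }
  list(
    ExG   = function(R, G, B) { cc <- chrom(R, G, B); 2 * cc$g - cc$r - cc$b },
    ExR   = function(R, G, B) { cc <- chrom(R, G, B); 1.4 * cc$r - cc$g },
    ExGR  = function(R, G, B) {
      cc <- chrom(R, G, B)
      (2 * cc$g - cc$r - cc$b) - (1.4 * cc$r - cc$g)
    },
    NGRDI = function(R, G, B) safeDiv(G - R, G + R),
    GRVI  = function(R, G, B) safeDiv(G, R),
    VARI  = function(R, G, B) safeDiv(G - R, G + R - B),
    TGI   = function(R, G, B) G - 0.39 * R - 0.61 * B,
    CIVE  = function(R, G, B) 0.441 * R - 0.811 * G + 0.385 * B + 18.78745,
    GCC   = function(R, G, B) safeDiv(G, R + G + B),
    GLI   = function(R, G, B) safeDiv(2 * G - R - B, 2 * G + R + B),
    VDVI  = function(R, G, B) {
      cc <- chrom(R, G, B)
      safeDiv(2 * cc$g - cc$r - cc$b, 2 * cc$g + cc$r + cc$b)
    },
    WI    = function(R, G, B) safeDiv(G - B, R - G),
    GBVI  = function(R, G, B) safeDiv(G - B, G + B),
    BRVI  = function(R, G, B) safeDiv(B - R, B + R))
}

#' Compute a vegetation-index map over plant pixels
#'
#' @param rgb a \linkS4class{PlotImage} or H x W x 3 array (0-255).
#' @param mask 0/1 plant mask; only plant pixels are populated.
#' @param viName index name from the registry.
#' @param registry registry of index functions (default
#'   \code{\link{viRegistry}()}).
#' @return H x W matrix: index values on valid plant pixels, NA elsewhere
#'   (background and guarded zero-denominator pixels).
#' @export
computeViMap <- function(rgb, mask, viName, registry = viRegistry()) {
  if (is(rgb, "PlotImage")) {
    if (missing(mask)) mask <- plantMask(rgb)
    rgb <- rgbArray(rgb)
  }
  stopIfNot3Channel(rgb)
  if (!viName %in% names(registry))
    stop("unknown vegetation index '", viName, "'")
  vals <- matrix(registry[[viName]](rgb[, , 1L], rgb[, , 2L], rgb[, , 3L]),
                 dim(rgb)[1L], dim(rgb)[2L])
  vals[mask != 1] <- NA_real_
  vals
}
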
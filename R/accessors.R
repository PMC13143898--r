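# Accessors and show() methods for the core classes.

#' Construct a PlotImage
#'
#' @param rgb numeric H x W x 3 array in [0, 255].
#' @param mask optional H x W matrix of 0/1 plant indicators.
#' @param meta named list of acquisition metadata.
#' @return A \linkS4class{PlotImage}.
#' @export
PlotImage <- function(rgb, mask = NULL, meta = list()) {
  stopIfNot3Channel(rgb)
  if (is.null(mask)) mask <- matrix(numeric(0), 0, 0)
  new("PlotImage", rgb = rgb, mask = mask, meta = meta)
}

#' @describeIn PlotImage the RGB array.
#' @param x,object a \code{PlotImage}.
#' @export
rgbArray <- function(x) x@rgb

#' @describeIn PlotImage the plant mask (0 x 0 matrix when absent).
#' @export
plantMask <- function(x) x@mask

#' @describeIn PlotImage \code{TRUE} when a mask is attached.
#' @export
hasMask <- function(x) length(x@mask) > 0L

#' @describeIn PlotImage acquisition metadata list.
#' @export
imageMeta <- function(x) x@meta

#' @describeIn PlotImage ground sampling distance in cm/pixel (or NA).
#' @export
gsd <- function(x) x@meta$gsd %||% NA_real_

setMethod("show", "PlotImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("PlotImage %d x %d px", d[1], d[2]))
  if (hasMask(object))
    cat(sprintf(", %d plant pixels (%.1f%%)", sum(object@mask),
                100 * mean(object@mask)))
  if (!is.null(object@meta$gsd))
    cat(sprintf(", GSD %.2f cm/px", object@meta$gsd))
  if (!is.null(object@meta$entry)) cat(", entry", object@meta$entry)
  cat("\n")
})

#' @describeIn makeDesign plot table (plot, block, entry, role).
#' @param x,object a \code{FieldDesign}.
#' @export
designTable <- function(x) x@plots

#' @describeIn makeDesign check genotype labels.
#' @export
checkNames <- function(x) x@checks

#' @describeIn makeDesign number of blocks.
#' @export
nBlocks <- function(x) length(unique(x@plots$block))

#' @describeIn makeDesign number of plots.
#' @export
nPlots <- function(x) nrow(x@plots)

#' @describeIn makeDesign all distinct entry labels.
#' @export
entryNames <- function(x) unique(x@plots$entry)

setMethod("show", "FieldDesign", function(object) {
  cat(sprintf(
    "FieldDesign '%s': %d plots in %d blocks (%d checks, %d progenies)\n",
    object@environment, nPlots(object), nBlocks(object),
    length(object@checks),
    sum(object@plots$role == "progeny")))
})

setMethod("show", "FeatureTable", function(object) {
  callNextMethod()
  grp <- table(SummarizedExperiment::rowData(object)$group)
  cat("feature groups:", paste(names(grp), grp, sep = "=", collapse = ", "),
      "\n")
})

#' @describeIn fitLmmReml named variance components.
#' @param fit an \code{LmmFit}.
#' @export
varComp <- function(fit) fit@components

#' @describeIn fitLmmReml standard errors of the variance components.
#' @export
varCompSE <- function(fit) fit@componentSE

#' @describeIn fitLmmReml BLUPs for one random term (default: progenies).
#' @param term random-term name; defaults to the progeny term.
#' @export
blups <- function(fit, term = fit@progenyTerm) fit@blup[[term]]

#' @describeIn fitLmmReml fixed-effect estimates (BLUEs).
#' @export
blues <- function(fit) fit@fixedCoef

#' @describeIn fitLmmReml PEV covariance matrix of the progeny BLUPs.
#' @export
pevMatrix <- function(fit) fit@pev

#' @describeIn fitLmmReml restricted log-likelihood.
#' @export
logRestrictedLik <- function(fit) fit@logRestrictedLik

setMethod("show", "LmmFit", function(object) {
  cat(sprintf("LmmFit for '%s' (n = %d, %s)\n", object@response,
              object@nobs,
              if (object@converged) "converged" else "NOT converged"))
  comp <- format(signif(object@components, 4))
  cat("variance components:\n")
  for (i in seq_along(comp))
    cat(sprintf("  %-18s %s%s\n", names(object@components)[i], comp[i],
                if (object@boundary[i]) " (boundary)" else ""))
})

#' @describeIn coincidenceIndex the coincidence index in percent.
#' @param x a \code{SelectionResult}.
#' @export
ciValue <- function(x) x@ci

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult %s vs %s @ %.0f%% intensity: CI = %.1f%% (%d of %d)\n",
    object@traitA, object@traitB, 100 * object@intensity, object@ci,
    length(intersect(object@selectedA, object@selectedB)),
    length(object@selectedA)))
})
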
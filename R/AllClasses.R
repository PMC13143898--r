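#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor cor.test sd var quantile rnorm runif pt pf pchisq
#'   qchisq optim prcomp predict coef aov anova model.matrix terms lm setNames
#'   complete.cases median qf
#' @importFrom utils head write.csv read.csv
NULL

#' PlotImage: a single-plot RGB raster with mask and acquisition metadata
#'
#' Container for one genotype plot as seen by the UAV: an 8-bit RGB array
#' (origin top-left, row-major), an optional ground-truth or estimated plant
#' mask, and acquisition metadata (environment, days after planting, flight
#' height, ground sampling distance).
#'
#' @slot rgb numeric H x W x 3 array with values in [0, 255].
#' @slot mask numeric H x W matrix with values in {0, 1} (1 = plant), or a
#'   0 x 0 matrix when no mask is attached.
#' @slot meta named list of acquisition metadata; recognised entries are
#'   \code{environment}, \code{dap}, \code{flightHeight} (m), \code{gsd}
#'   (cm/pixel) and \code{entry}.
#'
#' @aliases PlotImage
#' @export
setClass("PlotImage",
  representation(rgb = "array", mask = "matrix", meta = "list"),
  prototype(rgb = array(0, c(1, 1, 3)), mask = matrix(numeric(0), 0, 0),
            meta = list()))

setValidity("PlotImage", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3L] != 3L)
    return("rgb must be an H x W x 3 array")
  if (anyNA(object@rgb) || min(object@rgb) < 0 || max(object@rgb) > 255)
    return("rgb channel values must lie in [0, 255]")
  if (length(object@mask)) {
    if (!identical(dim(object@mask), d[1:2]))
      return("mask dimensions must match the image")
    if (!all(object@mask %in% c(0, 1)))
      return("mask values must be 0 or 1")
  }
  TRUE
})

#' FieldDesign: plot layout of an augmented block trial
#'
#' One environment of an augmented block design: every block carries the same
#' replicated check genotypes, and each progeny appears in exactly one block.
#'
#' @slot plots data.frame with columns \code{plot}, \code{block},
#'   \code{entry}, \code{role} (\code{"check"} or \code{"progeny"}).
#' @slot checks character vector of check genotype labels.
#' @slot environment environment label.
#'
#' @aliases FieldDesign
#' @export
setClass("FieldDesign",
  representation(plots = "data.frame", checks = "character",
                 environment = "character"))

setValidity("FieldDesign", function(object) {
  df <- object@plots
  need <- c("plot", "block", "entry", "role")
  if (!all(need %in% names(df)))
    return(paste("plots must have columns", paste(need, collapse = ", ")))
  if (!all(df$role %in% c("check", "progeny")))
    return("role must be 'check' or 'progeny'")
  for (b in unique(df$block)) {
    inb <- df[df$block == b, ]
    if (!setequal(intersect(inb$entry, object@checks), object@checks))
      return(sprintf("block %s does not contain every check", b))
    if (anyDuplicated(inb$entry))
      return(sprintf("block %s repeats an entry", b))
  }
  prog <- df[df$role == "progeny", ]
  if (anyDuplicated(prog$entry))
    return("a progeny appears in more than one block (augmented design)")
  TRUE
})

#' FeatureTable: digital traits per plot
#'
#' A \linkS4class{SummarizedExperiment} whose rows are digital traits
#' (vegetation-index statistics, Haralick descriptors, pixel count) and whose
#' columns are plots.  Assay \code{"raw"} holds the extracted values; assay
#' \code{"normalized"} (added by \code{\link{minmaxNormalize}}) holds the
#' min-max rescaled values in [0, 1].  \code{rowData} records the feature
#' group and its parameters; \code{colData} carries the plot metadata.
#'
#' @aliases FeatureTable
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"raw" %in% SummarizedExperiment::assayNames(object))
    return("FeatureTable needs an assay named 'raw'")
  if ("normalized" %in% SummarizedExperiment::assayNames(object)) {
    z <- SummarizedExperiment::assay(object, "normalized")
    z <- z[is.finite(z)]
    if (length(z) && (min(z) < -1e-12 || max(z) > 1 + 1e-12))
      return("normalized assay must lie in [0, 1]")
  }
  TRUE
})

#' LmmFit: a fitted linear mixed model for genetic evaluation
#'
#' REML fit of a mixed model with fixed check/harvest structure and random
#' progeny, interaction and block terms.  Holds variance components with
#' standard errors, BLUEs for the fixed effects, BLUPs and the prediction
#' error variance (PEV) covariance for the progenies, and the design
#' matrices needed for Wald and likelihood-ratio tests.
#'
#' @slot response name of the modelled trait.
#' @slot components named variance components (one per random term plus
#'   \code{"residual"}).
#' @slot componentSE asymptotic standard errors of the components.
#' @slot fixedCoef named fixed-effect estimates (BLUEs).
#' @slot vcovFixed covariance matrix of the fixed-effect estimates.
#' @slot assign integer mapping each fixed coefficient to a term label.
#' @slot termLabels labels of the fixed-effect terms (after the intercept).
#' @slot blup named list of BLUP vectors, one per random term.
#' @slot pev PEV covariance matrix of the progeny BLUPs (if requested).
#' @slot progenyTerm name of the random term holding the progeny effects.
#' @slot logRestrictedLik restricted log-likelihood at the optimum.
#' @slot converged logical convergence flag.
#' @slot nobs,X,y,Zlist fitting data retained for downstream tests.
#' @slot boundary logical per component: estimate at the zero boundary.
#'
#' @aliases LmmFit
#' @export
setClass("LmmFit",
  representation(response = "character", components = "numeric",
                 componentSE = "numeric", fixedCoef = "numeric",
                 vcovFixed = "matrix", assign = "integer",
                 termLabels = "character", blup = "list", pev = "matrix",
                 progenyTerm = "character", logRestrictedLik = "numeric",
                 converged = "logical", nobs = "integer", X = "matrix",
                 y = "numeric", Zlist = "list", boundary = "logical"))

setValidity("LmmFit", function(object) {
  if (any(object@components < 0))
    return("variance components must be >= 0")
  TRUE
})

#' SelectionResult: coincidence of two genotype selections
#'
#' Top-set comparison between two traits ranked by breeding value at a given
#' selection intensity.
#'
#' @slot traitA,traitB trait labels.
#' @slot intensity selection intensity in (0, 1].
#' @slot selectedA,selectedB selected genotype sets (size
#'   \code{ceiling(intensity * n)}).
#' @slot ci coincidence index in percent.
#'
#' @aliases SelectionResult
#' @export
setClass("SelectionResult",
  representation(traitA = "character", traitB = "character",
                 intensity = "numeric", selectedA = "character",
                 selectedB = "character", ci = "numeric"))

setValidity("SelectionResult", function(object) {
  if (object@ci < 0 || object@ci > 100) return("CI must lie in [0, 100]")
  if (length(object@selectedA) != length(object@selectedB))
    return("both selections must have the same size")
  TRUE
})
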
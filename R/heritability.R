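# Broad-sense and Cullis heritability from a mixed-model fit.

#' Broad-sense heritability
#'
#' H2 = s2_G / s2_P.  The phenotypic variance basis is stated explicitly
#' because it changes the meaning of H2: the default entry-mean basis is
#' s2_P = s2_G + s2_GH / nHarvests + s2_E / (nHarvests * nRep) (the
#' variance of an entry mean over harvests and replicates); the plot basis
#' is the simple sum of all components.
#'
#' @param components named vector or an \linkS4class{LmmFit}; recognised
#'   names are the fit's random terms, with the progeny term as s2_G,
#'   any term containing both progeny and harvest as s2_GH, block terms as
#'   s2_B, and \code{"residual"} as s2_E.
#' @param basis \code{"entry-mean"} (default) or \code{"plot"}.
#' @param nHarvests,nRep divisor structure of the entry-mean basis.
#' @return H2 in [0, 1], with attribute \code{basis}.
#' @export
broadSenseH2 <- function(components, basis = c("entry-mean", "plot"),
                         nHarvests = 1, nRep = 1) {
  basis <- match.arg(basis)
  cp <- extractComponents(components)
  s2P <- switch(basis,
    "entry-mean" = cp["G"] + cp["GH"] / nHarvests +
      cp["E"] / (nHarvests * nRep),
    plot = cp["G"] + cp["GH"] + cp["B"] + cp["E"])
  if (s2P == 0) stop("zero phenotypic variance: H2 undefined")
  structure(unname(cp["G"] / s2P), basis = basis)
}

extractComponents <- function(components) {
  if (is(components, "LmmFit")) {
    comp <- components@components
    pt <- components@progenyTerm
    g <- comp[pt]
    gh <- comp[grepl(pt, names(comp), fixed = TRUE) &
                 grepl("harvest", names(comp), ignore.case = TRUE) &
                 names(comp) != pt]
    b <- comp[grepl("block", names(comp), ignore.case = TRUE)]
    c(G = unname(g), GH = sum(gh), B = sum(b),
      E = unname(comp["residual"]))
  } else {
    cp <- c(G = 0, GH = 0, B = 0, E = 0)
    nm <- names(components)
    if (is.null(nm)) stop("components must be named")
    key <- toupper(nm)
    key[key %in% c("SIGMA2G", "PROGENY", "GENOTYPE")] <- "G"
    key[key %in% c("SIGMA2GH")] <- "GH"
    key[key %in% c("SIGMA2B", "BLOCK")] <- "B"
    key[key %in% c("SIGMA2E", "RESIDUAL", "ERROR")] <- "E"
    for (k in c("G", "GH", "B", "E"))
      if (k %in% key) cp[k] <- sum(components[key == k])
    cp
  }
}

#' Mean variance of pairwise BLUP differences
#'
#' v_delta = mean over progeny pairs (i, j) of PEV_ii + PEV_jj - 2 PEV_ij,
#' computed from the PEV covariance of the fit.
#'
#' @param fit an \linkS4class{LmmFit} fitted with \code{computePev = TRUE}.
#' @return scalar v_delta.
#' @export
meanPairwisePev <- function(fit) {
  P <- pevMatrix(fit)
  q <- nrow(P)
  if (q < 2) stop("need PEV for at least 2 progenies")
  Tt <- sum(diag(P)); S <- sum(P)
  (2 * (q - 1) * Tt - 2 * (S - Tt)) / (q * (q - 1))
}

#' Cullis heritability
#'
#' HC2 = 1 - v_delta / (2 s2_G), where v_delta is the average variance of
#' pairwise BLUP differences (the prediction error variance of individual
#' genotype comparisons).  Approaches 1 as replication grows and the BLUPs
#' approach the true genetic values.
#'
#' @param fit an \linkS4class{LmmFit} with PEV available and s2_G > 0.
#' @return HC2 (<= 1).
#' @export
cullisH2 <- function(fit) {
  s2G <- fit@components[fit@progenyTerm]
  if (is.na(s2G) || s2G <= 0)
    stop("genetic variance is 0: Cullis heritability undefined")
  unname(1 - meanPairwisePev(fit) / (2 * s2G))
}
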
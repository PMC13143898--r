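# Selection analysis: genotype ranking by breeding value, coincidence
# indices between trait rankings, BV correlation network and PCA.

#' Rank genotypes by breeding value
#'
#' Descending by default (higher is better); ties broken by genotype label
#' so rankings are deterministic.
#'
#' @param bvs named vector of breeding values, one per genotype.
#' @param direction \code{"desc"} or \code{"asc"}.
#' @return character vector of genotype labels, best first.
#' @export
rankGenotypes <- function(bvs, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  if (is.null(names(bvs)) || anyNA(bvs))
    stop("missing BV for genotypes: ",
         paste(names(bvs)[is.na(bvs)], collapse = ", "))
  o <- order(if (direction == "desc") -bvs else bvs, names(bvs))
  names(bvs)[o]
}

#' Coincidence index between two rankings
#'
#' CI = 100 x |top_a intersect top_b| / top-set size, with top-set size
#' ceiling(intensity x n).  Measures how far two traits select the same
#' genotypes at a given selection intensity.
#'
#' @param rankA,rankB ranked genotype vectors over the same universe (best
#'   first), e.g. from \code{\link{rankGenotypes}}.
#' @param intensity selection intensity in (0, 1].
#' @param traitA,traitB trait labels recorded on the result.
#' @return A \linkS4class{SelectionResult}.
#' @export
coincidenceIndex <- function(rankA, rankB, intensity,
                             traitA = "traitA", traitB = "traitB") {
  if (!setequal(rankA, rankB) || length(rankA) != length(rankB))
    stop("rankings must cover the same genotype universe")
  if (intensity <= 0 || intensity > 1) stop("intensity must be in (0, 1]")
  k <- ceiling(intensity * length(rankA))
  topA <- rankA[seq_len(k)]; topB <- rankB[seq_len(k)]
  ci <- 100 * length(intersect(topA, topB)) / k
  new("SelectionResult", traitA = traitA, traitB = traitB,
      intensity = intensity, selectedA = topA, selectedB = topB, ci = ci)
}

#' Correlation network of breeding values
#'
#' Pearson correlations between trait BV vectors; edges with |r| >=
#' \code{threshold} are returned with sign and weight.  Constant BV columns
#' are isolated with a warning.
#'
#' @param bvTable genotypes x traits matrix or data.frame of BVs.
#' @param threshold minimum |r| for an edge.
#' @return list with \code{nodes} (trait names) and \code{edges}
#'   (data.frame from, to, r).
#' @export
bvCorrelationNetwork <- function(bvTable, threshold = 0.5) {
  m <- as.matrix(bvTable)
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 genotypes and >= 2 traits")
  traits <- colnames(m)
  edges <- NULL
  for (a in seq_len(ncol(m) - 1L)) for (b in (a + 1L):ncol(m)) {
    if (popSd(m[, a]) == 0 || popSd(m[, b]) == 0) {
      warning("constant BV column: node isolated")
      next
    }
    r <- cor(m[, a], m[, b])
    if (abs(r) >= threshold)
      edges <- rbind(edges, data.frame(from = traits[a], to = traits[b],
                                       r = r, stringsAsFactors = FALSE))
  }
  list(nodes = traits,
       edges = edges %||% data.frame(from = character(0), to = character(0),
                                     r = numeric(0)))
}

#' PCA of breeding values
#'
#' Principal components of the (optionally standardized) genotype x trait
#' BV matrix.  Component signs are fixed by making the largest-magnitude
#' loading of each component positive; explained-variance fractions sum
#' to 1.
#'
#' @param bvTable genotypes x traits matrix of BVs.
#' @param standardize scale columns to unit variance (default TRUE: traits
#'   are on different scales).
#' @return list with \code{scores}, \code{loadings},
#'   \code{explained} (fractions).
#' @export
pcaBreedingValues <- function(bvTable, standardize = TRUE) {
  m <- as.matrix(bvTable)
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 genotypes and >= 2 traits")
  sds <- apply(m, 2L, stats::sd)
  if (standardize && any(sds == 0)) {
    warning("constant column dropped from standardized PCA")
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = standardize)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  if (!all(keep)) warning("rank-deficient input: components reduced")
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  ev <- pc$sdev[keep]^2
  list(scores = sco, loadings = rot, explained = ev / sum(ev))
}
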
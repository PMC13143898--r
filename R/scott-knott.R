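# Scott-Knott clustering of treatment means and a Tukey-HSD letter
# grouping alternative.

# Between-group sum of squares of a split of sorted means after position s.
skBetweenSS <- function(m, s) {
  k <- length(m)
  t1 <- m[seq_len(s)]; t2 <- m[(s + 1L):k]
  length(t1) * (mean(t1) - mean(m))^2 + length(t2) * (mean(t2) - mean(m))^2
}

skPartition <- function(means, s2, df, alpha, labels, out, nextLab) {
  k <- length(means)
  if (k < 2L) {
    out[labels] <- nextLab
    return(list(out = out, nextLab = nextLab + 1L))
  }
  b0 <- vapply(seq_len(k - 1L), function(s) skBetweenSS(means, s),
               numeric(1))
  s <- which.max(b0)
  B0 <- b0[s]
  sig02 <- (sum((means - mean(means))^2) + df * s2) / (k + df)
  lambda <- pi / (2 * (pi - 2)) * B0 / sig02
  nu0 <- k / (pi - 2)
  if (sig02 > 0 && lambda > qchisq(1 - alpha, nu0)) {
    res <- skPartition(means[seq_len(s)], s2, df, alpha,
                       labels[seq_len(s)], out, nextLab)
    skPartition(means[(s + 1L):k], s2, df, alpha, labels[(s + 1L):k],
                res$out, res$nextLab)
  } else {
    out[labels] <- nextLab
    list(out = out, nextLab = nextLab + 1L)
  }
}

#' Scott-Knott clustering of means
#'
#' Recursive binary partition of the sorted means: at each level the split
#' maximizing the between-group sum of squares is accepted when the
#' likelihood-ratio statistic lambda = pi/(2(pi-2)) B0 / sigma0^2 exceeds
#' the (1 - alpha) quantile of chi-square with k/(pi-2) degrees of freedom.
#' Unlike pairwise procedures the result is a disjoint grouping with no
#' overlapping letters.
#'
#' @param means named vector of group means.
#' @param s2 within-group variance of a mean (e.g. MSE / replicates).
#' @param df degrees of freedom of \code{s2}.
#' @param alpha significance level (default 0.05).
#' @return integer group labels (1 = highest-mean group), in the order of
#'   \code{means}; labels respect the mean ordering.
#' @export
scottKnottGroups <- function(means, s2, df, alpha = 0.05) {
  if (any(!is.finite(means))) stop("means must be finite")
  if (s2 < 0) stop("variance must be >= 0")
  nm <- names(means) %||% as.character(seq_along(means))
  names(means) <- nm
  if (length(means) == 1L) return(setNames(1L, nm))
  o <- order(means, decreasing = TRUE)
  res <- skPartition(means[o], s2, df, alpha, nm[o],
                     setNames(integer(length(means)), nm), 1L)
  res$out[nm]
}

#' Tukey-HSD letter grouping of means
#'
#' All-pairs comparison with the studentized-range critical value; means
#' not significantly different share a group.  Provided as an alternative
#' to \code{\link{scottKnottGroups}}; groups may overlap, in which case a
#' mean is assigned to the first (highest) compatible group.
#'
#' @inheritParams scottKnottGroups
#' @param n replicates per mean (for the standard error of a mean,
#'   \code{sqrt(s2)} already being the SE when \code{n = 1}).
#' @return integer group labels in the order of \code{means}.
#' @export
tukeyGroups <- function(means, s2, df, alpha = 0.05, n = 1) {
  nm <- names(means) %||% as.character(seq_along(means))
  k <- length(means)
  if (k == 1L) return(setNames(1L, nm))
  hsd <- stats::qtukey(1 - alpha, k, df) * sqrt(s2 / n)
  o <- order(means, decreasing = TRUE)
  lab <- integer(k)
  cur <- 0L
  leader <- 1L
  for (i in seq_len(k)) {
    if (cur == 0L || means[o[leader]] - means[o[i]] > hsd) {
      cur <- cur + 1L
      leader <- i
    }
    lab[o[i]] <- cur
  }
  setNames(lab, nm)
}
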
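# Pairwise association between digital and conventional traits: Pearson r,
# t test of significance, flight-to-measurement date matching.

#' Match flight dates to conventional measurement dates
#'
#' Flights within \code{tolerance} days of a measurement date are matched to
#' it (same-date match).  Flights taken 3-7 days after a harvest are matched
#' forward to the next available measurement date, to support prediction
#' from early regrowth.  Other flights are left unmatched (reported, not an
#' error).
#'
#' @param flightDates integer flight dates (days after planting, DAP).
#' @param measurementDates integer measurement DAPs.
#' @param harvestDates integer harvest DAPs (defaults to
#'   \code{measurementDates}).
#' @param tolerance same-date tolerance in days (default 1).
#' @return data.frame with columns \code{flight}, \code{measurement} (NA if
#'   unmatched) and \code{matchType} (\code{"same-date"},
#'   \code{"post-harvest-forward"} or \code{"unmatched"}).
#' @export
matchFlightsToMeasurements <- function(flightDates, measurementDates,
                                       harvestDates = measurementDates,
                                       tolerance = 1L) {
  measurementDates <- sort(unique(measurementDates))
  out <- data.frame(flight = flightDates, measurement = NA_real_,
                    matchType = "unmatched", stringsAsFactors = FALSE)
  for (k in seq_along(flightDates)) {
    f <- flightDates[k]
    d <- abs(measurementDates - f)
    if (any(d <= tolerance)) {
      out$measurement[k] <- measurementDates[which.min(d)]
      out$matchType[k] <- "same-date"
      next
    }
    gap <- f - harvestDates
    if (any(gap >= 3 & gap <= 7)) {
      nxt <- measurementDates[measurementDates > f]
      if (length(nxt)) {
        out$measurement[k] <- nxt[1L]
        out$matchType[k] <- "post-harvest-forward"
      }
    }
  }
  out
}

#' Pearson correlation coefficient
#'
#' r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2)).
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return r in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (popSd(x) == 0 || popSd(y) == 0)
    stop("correlation undefined for a constant vector")
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' t test for a Pearson correlation
#'
#' t = r sqrt(n - 2) / sqrt(1 - r^2); two-sided p from Student's t with
#' n - 2 degrees of freedom.
#'
#' @param r correlation coefficient with |r| < 1.
#' @param n number of observations (>= 3).
#' @return list with \code{t} and \code{p}.
#' @export
correlationTTest <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) stop("|r| = 1 gives an infinite test statistic")
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(t = t, p = 2 * pt(-abs(t), df = n - 2))
}

#' Digital-by-conventional trait association grid
#'
#' Pearson r, t statistic and two-sided p for every feature x trait pair
#' over rows matched by plot/genotype; pairs are flagged \code{strong} when
#' r > 0.75 (strict, signed).  Pairs with fewer than 3 complete matched
#' rows are skipped with a warning.
#'
#' @param features a \linkS4class{FeatureTable} or plots x features matrix.
#' @param traits data.frame of conventional traits, rows aligned with the
#'   plots of \code{features} (use \code{traitCols} to pick columns).
#' @param traitCols names of the trait columns (default: all numeric).
#' @param strongThreshold threshold for the strong flag.
#' @return data.frame grid with feature, trait, r, t, n, p, strong.
#' @export
associationMatrix <- function(features, traits, traitCols = NULL,
                              strongThreshold = 0.75) {
  fm <- if (is(features, "FeatureTable"))
    t(SummarizedExperiment::assay(features, "raw")) else as.matrix(features)
  if (is.null(traitCols))
    traitCols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  if (nrow(fm) != nrow(traits))
    stop("features and traits must describe the same plots")
  out <- NULL
  for (ft in colnames(fm)) for (tr in traitCols) {
    x <- fm[, ft]; y <- traits[[tr]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || popSd(x[ok]) == 0 || popSd(y[ok]) == 0) {
      warning("pair ", ft, " x ", tr, " skipped (<3 rows or constant)")
      next
    }
    r <- pearsonCorrelation(x[ok], y[ok])
    tt <- if (abs(r) < 1) correlationTTest(r, sum(ok))
          else list(t = Inf * sign(r), p = 0)
    out <- rbind(out, data.frame(
      feature = ft, trait = tr, r = r, t = tt$t, n = sum(ok), p = tt$p,
      strong = r > strongThreshold, stringsAsFactors = FALSE))
  }
  out
}
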
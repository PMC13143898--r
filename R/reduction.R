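# Collinearity pruning of digital traits: within-group greedy scan that
# keeps the earliest feature of every highly correlated pair.

pruneGroup <- function(mat, cols, threshold) {
  # mat: plots x features; cols scanned in the given (registry) order
  kept <- character(0)
  dropped <- data.frame(feature = character(0), partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (cl in cols) {
    x <- mat[, cl]
    if (stats::sd(x, na.rm = TRUE) %in% c(0, NA) || all(is.na(x))) {
      warning("constant feature '", cl, "' excluded from correlation, kept")
      kept <- c(kept, cl)
      next
    }
    hit <- NA_character_; hitR <- NA_real_
    for (kp in kept) {
      y <- mat[, kp]
      if (stats::sd(y, na.rm = TRUE) %in% c(0, NA)) next
      r <- suppressWarnings(cor(x, y, use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > threshold) { hit <- kp; hitR <- r; break }
    }
    if (is.na(hit)) kept <- c(kept, cl)
    else dropped <- rbind(dropped, data.frame(feature = cl, partner = hit,
                                              r = hitR))
  }
  list(kept = kept, dropped = dropped)
}

#' Prune collinear digital traits
#'
#' Within each feature group, columns are scanned in fixed registry order
#' and any later feature whose |r| with an already-retained feature strictly
#' exceeds the group threshold is dropped (the earlier feature wins).  For a
#' \linkS4class{FeatureTable} the groups are the seven statistics of each
#' vegetation index (threshold \code{thresholdVi}) and the twelve
#' distance/angle configurations of each Haralick descriptor (threshold
#' \code{thresholdGlcm}); \code{n_pixels} is always kept.
#'
#' @param table a \linkS4class{FeatureTable} (>= 2 plots), or a plots x
#'   features matrix/data.frame with \code{groups} supplied.
#' @param thresholdVi |r| threshold for VI statistic groups (default 0.75).
#' @param thresholdGlcm |r| threshold for GLCM configuration groups
#'   (default 0.95).
#' @param groups for the matrix interface: list of column-name vectors
#'   partitioning the columns.
#' @param threshold for the matrix interface: per-group threshold
#'   (recycled).
#' @return The reduced table; the \code{ReductionReport} (kept features,
#'   dropped features with partner and r, thresholds) is attached as
#'   \code{metadata()$reduction} (FeatureTable) or
#'   \code{attr(, "reduction")}.
#' @export
pruneCollinear <- function(table, thresholdVi = 0.75, thresholdGlcm = 0.95,
                           groups = NULL, threshold = NULL) {
  if (is(table, "FeatureTable")) {
    if (ncol(table) < 2) stop("need at least 2 plots to assess collinearity")
    rd <- SummarizedExperiment::rowData(table)
    mat <- t(SummarizedExperiment::assay(table, "raw"))
    keptAll <- character(0)
    droppedAll <- NULL
    for (vi in unique(stats::na.omit(rd$vi))) {
      cols <- rownames(table)[!is.na(rd$vi) & rd$vi == vi]
      res <- pruneGroup(mat, cols, thresholdVi)
      keptAll <- c(keptAll, res$kept)
      droppedAll <- rbind(droppedAll, res$dropped)
    }
    for (ds in unique(stats::na.omit(rd$descriptor))) {
      cols <- rownames(table)[!is.na(rd$descriptor) & rd$descriptor == ds]
      res <- pruneGroup(mat, cols, thresholdGlcm)
      keptAll <- c(keptAll, res$kept)
      droppedAll <- rbind(droppedAll, res$dropped)
    }
    keptAll <- c(keptAll, rownames(table)[rd$group == "structural"])
    out <- table[rownames(table) %in% keptAll, ]
    S4Vectors::metadata(out)$reduction <- list(
      kept = rownames(out), dropped = droppedAll,
      thresholds = c(vi = thresholdVi, glcm = thresholdGlcm))
    return(out)
  }
  mat <- as.matrix(table)
  if (nrow(mat) < 2) stop("need at least 2 rows")
  if (is.null(groups)) groups <- list(colnames(mat))
  thr <- rep_len(threshold %||% thresholdVi, length(groups))
  keptAll <- character(0); droppedAll <- NULL
  for (gidx in seq_along(groups)) {
    res <- pruneGroup(mat, groups[[gidx]], thr[gidx])
    keptAll <- c(keptAll, res$kept)
    droppedAll <- rbind(droppedAll, res$dropped)
  }
  out <- mat[, colnames(mat)[colnames(mat) %in% keptAll], drop = FALSE]
  attr(out, "reduction") <- list(kept = colnames(out), dropped = droppedAll,
                                 thresholds = thr)
  out
}

#' Preset reduction to the canonical 76-feature configuration
#'
#' Data-independent preset: for every vegetation index the 50th and 75th
#' percentiles are removed (collinear with mean/q25/stdev); of the GLCM
#' grid a single configuration (distance 1, angle 0) is retained with the
#' ASM descriptor dropped (complement of entropy), leaving five Haralick
#' descriptors; the pixel count is kept.  Under the full extraction
#' configuration this yields 14 x 5 + 5 + 1 = 76 features.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param keepDistance,keepAngle retained GLCM configuration.
#' @param dropStats VI statistics to remove.
#' @param dropDescriptor Haralick descriptor to remove.
#' @return Reduced \linkS4class{FeatureTable} with a reduction report in
#'   \code{metadata()}.
#' @export
presetReduction <- function(table, keepDistance = 1L, keepAngle = 0,
                            dropStats = c("q50", "q75"),
                            dropDescriptor = "ASM") {
  stopifnot(is(table, "FeatureTable"))
  rd <- SummarizedExperiment::rowData(table)
  keep <- rep(TRUE, nrow(table))
  isVi <- rd$group == "vi"
  keep[isVi & rd$stat %in% dropStats] <- FALSE
  isGl <- rd$group == "glcm"
  keep[isGl & !(rd$distance == keepDistance & rd$angle == keepAngle)] <- FALSE
  keep[isGl & rd$descriptor %in% dropDescriptor] <- FALSE
  out <- table[keep, ]
  S4Vectors::metadata(out)$reduction <- list(
    kept = rownames(out),
    dropped = data.frame(feature = rownames(table)[!keep],
                         partner = NA_character_, r = NA_real_),
    mode = "preset")
  out
}

#' @describeIn pruneCollinear retrieve the reduction report.
#' @export
reductionReport <- function(table) {
  if (is(table, "FeatureTable")) S4Vectors::metadata(table)$reduction
  else attr(table, "reduction")
}
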
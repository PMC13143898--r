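# REML estimation of variance components for the augmented-design mixed
# models, with BLUEs/BLUPs, prediction error variances, Wald F tests for
# fixed effects and likelihood-ratio tests for variance components.
#
# The model is y = X b + sum_r Z_r u_r + e with u_r ~ N(0, s2_r I) and
# e ~ N(0, s2_e I).  Progeny terms may cover only part of the rows (checks
# get all-zero Z rows), which is how the fixed-check / random-progeny split
# of the augmented design is realized.

# Sparse indicator matrix for a factor; rows with NA are all-zero.
randomDesign <- function(data, term) {
  cols <- strsplit(term, ":", fixed = TRUE)[[1L]]
  f <- if (length(cols) == 1L) factor(data[[cols]])
       else factor(do.call(paste, c(data[cols], sep = ":")))
  lev <- levels(f)
  ok <- !is.na(f)
  Matrix::sparseMatrix(i = which(ok), j = as.integer(f)[ok], x = 1,
                       dims = c(nrow(data), length(lev)),
                       dimnames = list(NULL, lev))
}

# -2 restricted log-likelihood (without additive constants) for variance
# components s2 = c(per random term, residual).  Uses the mixed-model
# equations identity log|V| + log|X' V^-1 X| = log|R| + log|G| + log|C|
# so every evaluation is one sparse Cholesky of the (p + q) x (p + q)
# coefficient matrix instead of an n x n factorization.
remlDeviance <- function(s2, y, X, Zlist, W = NULL) {
  n <- length(y)
  p <- ncol(X)
  s2e <- s2[length(s2)]
  if (s2e <= 0) return(1e10)
  if (!length(Zlist)) {
    rss <- sum(lm.fit(X, y)$residuals^2)
    XtX <- crossprod(X)
    return(as.numeric((n - p) * log(s2e) +
                        determinant(XtX, logarithm = TRUE)$modulus +
                        rss / s2e))
  }
  if (is.null(W))
    W <- cbind(Matrix::Matrix(X, sparse = TRUE), do.call(cbind, Zlist))
  q <- vapply(Zlist, ncol, integer(1))
  s2r <- pmax(s2[seq_along(Zlist)], 1e-300)
  Dinv <- Matrix::Diagonal(x = c(rep(0, p), rep(1 / s2r, q)))
  C <- Matrix::crossprod(W) / s2e + Dinv
  ldC <- tryCatch(
    as.numeric(Matrix::determinant(C, logarithm = TRUE)$modulus),
    error = function(e) NA_real_)
  if (!is.finite(ldC)) return(1e10)
  Wty <- Matrix::crossprod(W, y)
  sol <- tryCatch(Matrix::solve(C, Wty / s2e), error = function(e) NULL)
  if (is.null(sol)) return(1e10)
  yPy <- (sum(y^2) - sum(as.vector(sol) * as.vector(Wty))) / s2e
  as.numeric(n * log(s2e) + sum(q * log(s2r)) + ldC + yPy)
}

#' Fit a linear mixed model by REML
#'
#' Variance components are estimated by direct maximization of the
#' restricted log-likelihood over log-variances (L-BFGS-B, converged when
#' the profiled deviance is stationary; components are constrained
#' non-negative and estimates collapsing to the lower bound are reported
#' as 0 with a boundary flag).  BLUEs, BLUPs and the prediction-error
#' covariance come from the inverse coefficient matrix of the mixed-model
#' equations at the estimates.
#'
#' Random terms are given as column names of \code{data} (interactions with
#' \code{":"}); rows where the factor is \code{NA} contribute all-zero
#' design rows, so a progeny term covering only non-check plots realizes
#' the fixed-check / random-progeny split of the augmented design.
#'
#' @param data data.frame with the response, fixed-effect columns and
#'   random-term factors.
#' @param response response column name.
#' @param fixed one-sided formula of fixed effects (default intercept
#'   only).
#' @param random character vector of random-term names; the residual is
#'   always included.
#' @param progenyTerm which random term holds the progeny (breeding-value)
#'   effects; defaults to the first.
#' @param computePev invert the MME coefficient matrix for PEV (needed for
#'   Cullis heritability).
#' @param maxit maximum optimizer iterations.
#' @return An \linkS4class{LmmFit}.
#' @examples
#' d <- expand.grid(geno = factor(1:20), rep = factor(1:3))
#' d$y <- rnorm(20)[d$geno] + rnorm(60)
#' fit <- fitLmmReml(d, "y", random = "geno")
#' varComp(fit)
#' @export
fitLmmReml <- function(data, response, fixed = ~1, random = character(0),
                       progenyTerm = if (length(random)) random[1L] else
                         character(0),
                       computePev = TRUE, maxit = 200L) {
  mf <- stats::model.frame(fixed, data, na.action = stats::na.pass)
  X <- model.matrix(fixed, mf)
  y <- data[[response]]
  if (anyNA(y) || anyNA(X)) stop("missing values in response or fixed part")
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) {
    ali <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("singular fixed-effect design; aliased: ",
         paste(ali, collapse = ", "))
  }
  Zlist <- lapply(random, function(tm) randomDesign(data, tm))
  names(Zlist) <- random
  for (tm in random)
    if (ncol(Zlist[[tm]]) < 2)
      stop("random term '", tm, "' needs at least 2 levels")
  vy <- var(y)
  if (vy == 0) stop("constant response")
  R <- length(random)
  if (R == 0L) {
    rss <- sum(lm.fit(X, y)$residuals^2)
    s2 <- setNames(rss / (n - p), "residual")
    dev <- remlDeviance(s2, y, X, Zlist)
    comp <- s2
    se <- setNames(sqrt(2 * s2^2 / (n - p)), "residual")
    bound <- setNames(FALSE, "residual")
    convd <- TRUE
  } else {
    Wall <- cbind(Matrix::Matrix(X, sparse = TRUE), do.call(cbind, Zlist))
    theta0 <- log(rep(vy / (R + 1), R + 1L))
    lower <- rep(log(vy) - 25, R + 1L)
    upper <- rep(log(vy) + 15, R + 1L)
    obj <- function(th) remlDeviance(exp(th), y, X, Zlist, Wall)
    # Nelder-Mead is robust to the small numerical noise of the sparse
    # determinant; a bounded quasi-Newton polish tightens the optimum.
    opt <- optim(theta0, obj, method = "Nelder-Mead",
                 control = list(maxit = 5L * maxit, reltol = 1e-13))
    polish <- tryCatch(
      optim(pmin(pmax(opt$par, lower), upper), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e1,
                           ndeps = rep(1e-7, R + 1L))),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= opt$value) {
      opt$par <- polish$par
      opt$value <- polish$value
    }
    convd <- opt$convergence == 0L ||
      (!is.null(polish) && polish$convergence == 0L)
    if (!convd)
      warning("REML optimizer did not report convergence after ",
              opt$counts[1L], " evaluations")
    s2 <- exp(opt$par)
    names(s2) <- c(random, "residual")
    bound <- s2 < vy * 1e-7
    comp <- ifelse(bound, 0, s2)
    names(comp) <- names(s2)
    dev <- remlDeviance(comp, y, X, Zlist, Wall)
    # asymptotic SEs from the curvature of the deviance in the components
    se <- rep(NA_real_, R + 1L)
    int <- which(!bound)
    if (length(int)) {
      h <- pmax(1e-4 * comp[int], 1e-8 * vy)
      m <- length(int)
      Hm <- matrix(NA_real_, m, m)
      f0 <- dev
      fp <- fm <- numeric(m)
      for (a in seq_len(m)) {
        ea <- replace(comp, int[a], comp[int[a]] + h[a])
        sa <- replace(comp, int[a], max(comp[int[a]] - h[a], 0))
        fp[a] <- remlDeviance(ea, y, X, Zlist, Wall)
        fm[a] <- remlDeviance(sa, y, X, Zlist, Wall)
        Hm[a, a] <- (fp[a] - 2 * f0 + fm[a]) / h[a]^2
      }
      if (m > 1) for (a in seq_len(m - 1)) for (b in (a + 1):m) {
        epp <- replace(replace(comp, int[a], comp[int[a]] + h[a]),
                       int[b], comp[int[b]] + h[b])
        emm <- replace(replace(comp, int[a], max(comp[int[a]] - h[a], 0)),
                       int[b], max(comp[int[b]] - h[b], 0))
        Hm[a, b] <- Hm[b, a] <-
          (remlDeviance(epp, y, X, Zlist, Wall) - fp[a] - fp[b] + 2 * f0 -
             fm[a] - fm[b] + remlDeviance(emm, y, X, Zlist, Wall)) / (2 * h[a] * h[b])
      }
      covm <- tryCatch(2 * solve(Hm), error = function(e) NULL)
      if (!is.null(covm)) {
        dg <- diag(covm)
        se[int] <- sqrt(pmax(dg, 0))
      }
    }
    names(se) <- names(s2)
  }
  # mixed-model equations at the estimates
  act <- if (R) which(comp[seq_len(R)] > 0) else integer(0)
  s2e <- comp["residual"]
  Wm <- if (length(act))
    cbind(Matrix::Matrix(X, sparse = TRUE), do.call(cbind, Zlist[act]))
  else Matrix::Matrix(X, sparse = TRUE)
  qs <- if (length(act)) vapply(Zlist[act], ncol, integer(1)) else integer(0)
  Dinv <- Matrix::Diagonal(
    x = c(rep(0, p), rep(if (length(act)) 1 / comp[act] else numeric(0),
                         qs)))
  C <- Matrix::crossprod(Wm) / s2e + Dinv
  rhs <- Matrix::crossprod(Wm, y) / s2e
  sol <- as.vector(Matrix::solve(C, rhs))
  fixedCoef <- setNames(sol[seq_len(p)], colnames(X))
  blup <- setNames(vector("list", R), random)
  off <- p
  for (idx in seq_len(R)) {
    if (idx %in% act) {
      qi <- ncol(Zlist[[idx]])
      blup[[idx]] <- setNames(sol[off + seq_len(qi)],
                              colnames(Zlist[[idx]]))
      off <- off + qi
    } else {
      blup[[idx]] <- setNames(rep(0, ncol(Zlist[[idx]])),
                              colnames(Zlist[[idx]]))
    }
  }
  pev <- matrix(numeric(0), 0, 0)
  vcf <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  if (computePev) {
    Cinv <- as.matrix(Matrix::solve(C))
    vcf <- Cinv[seq_len(p), seq_len(p), drop = FALSE]
    dimnames(vcf) <- list(colnames(X), colnames(X))
    if (length(progenyTerm) && progenyTerm %in% random[act]) {
      pos <- p
      for (idx in act) {
        qi <- ncol(Zlist[[idx]])
        if (random[idx] == progenyTerm) {
          pev <- Cinv[pos + seq_len(qi), pos + seq_len(qi), drop = FALSE]
          dimnames(pev) <- list(colnames(Zlist[[idx]]),
                                colnames(Zlist[[idx]]))
        }
        pos <- pos + qi
      }
    }
  }
  asgn <- attr(X, "assign")
  tl <- attr(terms(fixed), "term.labels")
  new("LmmFit", response = response, components = comp,
      componentSE = se, fixedCoef = fixedCoef, vcovFixed = vcf,
      assign = as.integer(asgn), termLabels = as.character(tl),
      blup = blup, pev = pev,
      progenyTerm = as.character(progenyTerm),
      logRestrictedLik = -0.5 * (dev + (n - p) * log(2 * pi)),
      converged = convd, nobs = as.integer(n), X = X, y = as.numeric(y),
      Zlist = Zlist,
      boundary = if (R) c(bound) else setNames(FALSE, "residual"))
}

# y' P y for a given fixed design under the fitted covariance.
quadFormPy <- function(fit, Xsub) {
  n <- fit@nobs
  s2 <- fit@components
  V <- diag(s2["residual"], n)
  for (r in seq_along(fit@Zlist))
    if (s2[r] > 0)
      V <- V + s2[r] * as.matrix(Matrix::tcrossprod(fit@Zlist[[r]]))
  L <- chol(V)
  Viy <- backsolve(L, forwardsolve(t(L), fit@y))
  if (is.null(Xsub) || ncol(Xsub) == 0L) return(sum(fit@y * Viy))
  ViX <- backsolve(L, forwardsolve(t(L), Xsub))
  XtViX <- crossprod(ViX, Xsub)
  beta <- solve(XtViX, crossprod(ViX, fit@y))
  sum(fit@y * Viy) - sum(crossprod(Xsub, Viy) * beta)
}

#' Incremental Wald F tests for fixed effects
#'
#' Terms are tested sequentially in model order: the Wald statistic for a
#' term is the drop in the generalized residual quadratic form y'Py when
#' the term's columns enter, divided by the number of columns.  Denominator
#' degrees of freedom use the residual-df approximation n - p (simpler than
#' reference-implementation adjustments; exactness is not claimed for
#' unbalanced designs).
#'
#' @param fit a converged \linkS4class{LmmFit}.
#' @return data.frame with term, df, F and p.
#' @export
waldFixedEffects <- function(fit) {
  if (!is(fit, "LmmFit")) stop("need an LmmFit")
  if (!fit@converged) stop("model did not converge")
  asgn <- fit@assign
  labels <- c("(Intercept)", fit@termLabels)
  pTot <- ncol(fit@X)
  ddf <- fit@nobs - pTot
  out <- NULL
  prevQ <- quadFormPy(fit, if (any(asgn == 0))
    fit@X[, asgn == 0, drop = FALSE] else NULL)
  for (t in sort(unique(asgn[asgn > 0]))) {
    Xt <- fit@X[, asgn <= t, drop = FALSE]
    q <- sum(asgn == t)
    Qt <- quadFormPy(fit, Xt)
    Fstat <- max(prevQ - Qt, 0) / q
    out <- rbind(out, data.frame(
      term = labels[t + 1L], df = q, F = Fstat,
      p = pf(Fstat, q, ddf, lower.tail = FALSE)))
    prevQ <- Qt
  }
  out
}

#' Likelihood-ratio test for one variance component
#'
#' LRT = 2 (logLik full - logLik reduced), clamped at 0; the p-value uses
#' the boundary mixture 0.5 chi2_0 + 0.5 chi2_1 appropriate for testing a
#' variance on the edge of its parameter space.
#'
#' @param fitFull,fitReduced nested \linkS4class{LmmFit} objects differing
#'   by exactly one random term, with identical fixed effects.
#' @return list with \code{statistic}, \code{p} and the tested term.
#' @export
lrtRandomEffect <- function(fitFull, fitReduced) {
  full <- names(fitFull@Zlist); red <- names(fitReduced@Zlist)
  if (!all(red %in% full) || length(setdiff(full, red)) > 1L)
    stop("models must be nested and differ by at most one random term")
  if (!identical(fitFull@termLabels, fitReduced@termLabels) ||
      ncol(fitFull@X) != ncol(fitReduced@X))
    stop("fixed effects differ: LRT for a variance component is invalid")
  stat <- max(2 * (fitFull@logRestrictedLik - fitReduced@logRestrictedLik), 0)
  p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p = p, term = setdiff(full, red))
}

#' Prepare augmented-design trait data for model fitting
#'
#' Builds the factors the augmented-design models need: \code{checkF}
#' (check label, baseline \code{"progeny"} for progeny plots),
#' \code{progenyF} (progeny label, \code{NA} for checks, giving zero
#' random-design rows), and factor versions of harvest and block.
#'
#' @param traits trait table with columns entry, role, block and optionally
#'   harvest.
#' @param checks character vector of check labels.
#' @return The table with columns \code{checkF}, \code{progenyF},
#'   \code{blockF} and (if present) \code{harvestF} appended.
#' @export
prepareAugmented <- function(traits, checks) {
  isC <- traits$role == "check"
  traits$checkF <- factor(ifelse(isC, traits$entry, "progeny"),
                          levels = c("progeny", sort(unique(checks))))
  traits$progenyF <- factor(ifelse(isC, NA, traits$entry))
  traits$blockF <- factor(traits$block)
  if ("harvest" %in% names(traits))
    traits$harvestF <- factor(traits$harvest)
  if ("gsd" %in% names(traits))
    traits$gsdF <- factor(traits$gsd)
  traits
}

#' Fit the conventional-trait model for one environment
#'
#' Fixed: intercept, check effects, harvest, check x harvest.  Random:
#' progeny, progeny x harvest, block within harvest.  Residual completes
#' the model.
#'
#' @param traits prepared table (see \code{\link{prepareAugmented}}).
#' @param response trait column name.
#' @param ... passed to \code{\link{fitLmmReml}}.
#' @return An \linkS4class{LmmFit}.
#' @export
fitConventionalModel <- function(traits, response, ...) {
  fitLmmReml(traits, response,
             fixed = ~ checkF + harvestF + checkF:harvestF,
             random = c("progenyF", "progenyF:harvestF", "blockF:harvestF"),
             progenyTerm = "progenyF", ...)
}

#' Fit the digital-trait model for one environment
#'
#' Fixed: intercept, check effects, GSD.  Random: progeny and block;
#' residual completes the model.  Used per digital trait with plots
#' replicated across GSDs.
#'
#' @inheritParams fitConventionalModel
#' @export
fitDigitalModel <- function(traits, response, ...) {
  fixed <- if ("gsdF" %in% names(traits) &&
               nlevels(factor(traits$gsdF)) > 1)
    ~ checkF + gsdF else ~ checkF
  fitLmmReml(traits, response, fixed = fixed,
             random = c("progenyF", "blockF"),
             progenyTerm = "progenyF", ...)
}
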
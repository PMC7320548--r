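#' Filter genes by minimum expression
#'
#' Keeps genes with abundance strictly greater than \code{minValue} in at
#' least \code{minSamples} samples.
#'
#' @param x gene x sample matrix.
#' @param minSamples minimum number of samples above \code{minValue}.
#' @param minValue expression threshold.
#' @return The filtered matrix (possibly with zero rows).
#' @export
filterExpressed <- function(x, minSamples = 3, minValue = 1) {
  keep <- rowSums(x > minValue) >= minSamples
  x[keep, , drop = FALSE]
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM method: a reference sample
#' is chosen as the one whose upper-quartile (of count fractions) is closest
#' to the mean upper-quartile; per-gene log2 expression ratios (M) against the
#' reference are trimmed (30% of M extremes, 5% of A extremes by default) and
#' averaged with inverse asymptotic-variance weights; factors are rescaled to
#' geometric mean 1. Effective library size = raw library size x factor.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param logratioTrim,sumTrim two-sided trim fractions for M and A values.
#' @return A list of class \code{NormFactors}: \code{factors} (geometric mean
#'   1), \code{libSizes}, \code{effectiveLibSizes}.
#' @export
tmmFactors <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  uq <- apply(counts, 2, function(v) stats::quantile(v / sum(v), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    .tmmPair(counts[, s], counts[, ref], lib[s], lib[ref],
             logratioTrim, sumTrim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  out <- list(factors = f, libSizes = lib, effectiveLibSizes = lib * f)
  class(out) <- "NormFactors"
  out
}

# Weighted trimmed mean of per-gene log ratios for one sample vs the reference.
.tmmPair <- function(y, yr, n, nr, logratioTrim, sumTrim) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (!length(y)) return(1)
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)  # delta-method var of M
  fin <- is.finite(M) & is.finite(A) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M)) return(1)
  if (max(abs(M)) < 1e-6) return(1)  # identical composition
  loM <- stats::quantile(M, logratioTrim); hiM <- stats::quantile(M, 1 - logratioTrim)
  loA <- stats::quantile(A, sumTrim); hiA <- stats::quantile(A, 1 - sumTrim)
  keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
  if (!any(keep2)) return(1)
  2 ^ (sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

.normOrTmm <- function(counts, norm) {
  if (is.null(norm)) tmmFactors(counts) else norm
}

# Average log2 CPM per gene on effective library sizes.
.aveLogCPM <- function(counts, effLib) {
  log2((rowSums(counts) + 0.5) / (sum(effLib) + 1) * 1e6)
}

## ---- vectorized NB GLM fitting (log link, fixed dispersion) ----------------

# NB log-likelihood matrix helper; phi may be scalar or per-gene (columns of
# mu/y are genes). phi == 0 falls back to Poisson.
.nbLoglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (length(phi) == 1) {
    if (phi < 1e-12) return(stats::dpois(y, mu, log = TRUE))
    return(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  phirow <- rep(phi, each = nrow(y))
  out <- stats::dnbinom(y, size = 1 / pmax(phirow, 1e-12), mu = mu,
                        log = TRUE)
  small <- phirow < 1e-12
  if (any(small)) out[small] <- stats::dpois(y[small], mu[small], log = TRUE)
  matrix(out, nrow(y), ncol(y))
}

# Fit log-linear NB GLMs for all genes against a shared design matrix by IRLS.
# y: samples x genes; X: samples x p; offset: length-S log effective library
# sizes; phi: scalar or per-gene dispersion. Returns coefficients, fitted
# means, per-gene log-likelihood and convergence flags.
.nbGlmFitMatrix <- function(y, X, offset, phi, maxit = 30L, tol = 1e-8) {
  S <- nrow(y); G <- ncol(y); P <- ncol(X)
  if (length(phi) == 1) phi <- rep(phi, G)
  ## init from least squares on shifted log counts
  z0 <- log(y + 0.5) - offset
  XtXinv <- tryCatch(solve(crossprod(X)), error = function(e)
    stop("design matrix is singular"))
  B <- XtXinv %*% crossprod(X, z0)            # p x G
  conv <- rep(FALSE, G)
  ll_old <- rep(-Inf, G)
  phirow <- rep(phi, each = S)
  for (it in seq_len(maxit)) {
    eta <- X %*% B
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta + offset)
    ll <- colSums(matrix(.nbLoglik(y, mu, phi), S, G))
    newly <- abs(ll - ll_old) < tol * (abs(ll) + 1)
    conv <- conv | newly
    ll_old <- ll
    if (all(conv) && it > 1) break
    w <- mu / (1 + phirow * mu)
    z <- eta + (y - mu) / mu
    for (g in which(!conv)) {
      Xw <- X * w[, g]
      A <- crossprod(X, Xw)
      b <- crossprod(Xw, z[, g])
      bg <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(bg)) { conv[g] <- TRUE; next }  # keep last stable estimate
      B[, g] <- bg
    }
  }
  eta <- pmin(pmax(X %*% B, -30), 30)
  mu <- exp(eta + offset)
  ll <- colSums(matrix(.nbLoglik(y, mu, phi), S, G))
  list(coefficients = B, fitted = mu, loglik = ll, converged = conv)
}

## ---- dispersion estimation -------------------------------------------------

#' Estimate common, trended and tagwise NB dispersions
#'
#' The common dispersion maximizes the Cox-Reid adjusted profile
#' log-likelihood pooled over genes (fitted means profiled out against the
#' design). Per-gene estimates are maximized on a dispersion grid, the trend
#' is a lowess fit of the per-gene estimates against average logCPM, and the
#' tagwise values shrink the per-gene estimates toward the trend with
#' \code{priorDf} prior degrees of freedom (weighted geometric interpolation
#' with the residual degrees of freedom).
#'
#' @param counts filtered gene x sample count matrix.
#' @param design model formula (e.g. \code{~ treatment + patient}) evaluated
#'   in \code{metadata}, or a design matrix.
#' @param metadata per-sample data.frame when \code{design} is a formula.
#' @param norm a [tmmFactors()] result; computed internally when NULL.
#' @param priorDf prior degrees of freedom for tagwise shrinkage.
#' @return list of class \code{DispersionEstimates}: \code{common},
#'   \code{trended}, \code{tagwise} (per gene), \code{genewise}, \code{logCPM},
#'   \code{residualDf}.
#' @export
estimateDispersions <- function(counts, design, metadata = NULL, norm = NULL,
                                priorDf = 10) {
  counts <- as.matrix(counts)
  X <- .designMatrix(design, metadata)
  S <- ncol(counts); G <- nrow(counts)
  if (nrow(X) != S) stop("design rows do not match sample count")
  dfRes <- S - ncol(X)
  if (dfRes < 1) stop("fewer than 1 residual degree of freedom")
  norm <- .normOrTmm(counts, norm)
  eff <- norm$effectiveLibSizes
  offset <- log(eff)
  y <- t(counts)
  ## outer products of design rows, for fast Cox-Reid adjustments
  O <- t(apply(X, 1, function(x) as.vector(tcrossprod(x))))  # S x p^2
  P <- ncol(X)

  aplAt <- function(phi, mu) {
    ll <- colSums(matrix(.nbLoglik(y, mu, phi), S, G))
    w <- mu / (1 + phi * mu)                   # S x G
    V <- crossprod(w, O)                       # G x p^2
    cr <- vapply(seq_len(G), function(g) {
      M <- matrix(V[g, ], P, P)
      d <- determinant(M, logarithm = TRUE)
      as.numeric(d$modulus)
    }, numeric(1))
    ll - 0.5 * cr
  }

  fit0 <- .nbGlmFitMatrix(y, X, offset, phi = 0.1)
  mu <- fit0$fitted
  pooled <- function(lphi) sum(aplAt(exp(lphi), mu))
  opt <- stats::optimize(pooled, interval = log(c(1e-6, 10)), maximum = TRUE,
                         tol = 1e-4)
  common <- exp(opt$maximum)
  ## refit means at the common dispersion, then per-gene grid estimates
  fit1 <- .nbGlmFitMatrix(y, X, offset, phi = common)
  mu <- fit1$fitted
  opt <- stats::optimize(pooled, interval = log(c(1e-6, 10)), maximum = TRUE,
                         tol = 1e-4)
  common <- exp(opt$maximum)
  grid <- exp(seq(log(1e-5), log(10), length.out = 35))
  A <- vapply(grid, function(p) aplAt(p, mu), numeric(G))  # G x grid
  if (G == 1) A <- matrix(A, nrow = 1)
  genewise <- exp(.quadInterpMax(log(grid), A,
                                 max.col(A, ties.method = "first")))
  logCPM <- .aveLogCPM(counts, eff)
  ## empirical Bayes on the likelihood surfaces: the trend maximizes the
  ## locally averaged APL (window over genes ordered by logCPM) and the
  ## tagwise value maximizes own APL + prior-weighted local APL
  Abar <- .runningMeanByOrder(A, order(logCPM),
                              halfWidth = max(10L, ceiling(0.1 * G)))
  trended <- exp(.quadInterpMax(log(grid), Abar,
                                max.col(Abar, ties.method = "first")))
  W <- A + (priorDf / dfRes) * Abar
  tagwise <- exp(.quadInterpMax(log(grid), W,
                                max.col(W, ties.method = "first")))
  out <- list(common = common, trended = trended, tagwise = tagwise,
              genewise = genewise, logCPM = logCPM, residualDf = dfRes,
              priorDf = priorDf)
  class(out) <- "DispersionEstimates"
  out
}

# Quadratic interpolation of the per-gene argmax around the best grid point;
# values are returned on the (log) grid scale.
.quadInterpMax <- function(lgrid, A, idx) {
  n <- length(lgrid)
  vapply(seq_len(nrow(A)), function(g) {
    i <- idx[g]
    if (i == 1 || i == n) return(lgrid[i])
    y1 <- A[g, i - 1]; y2 <- A[g, i]; y3 <- A[g, i + 1]
    den <- y1 - 2 * y2 + y3
    if (!is.finite(den) || den >= 0) return(lgrid[i])
    lgrid[i] + 0.5 * (y1 - y3) / den * (lgrid[i + 1] - lgrid[i])
  }, numeric(1))
}

# Running mean of the rows of A over a window of genes in the given order
# (used to share dispersion likelihood across genes of similar abundance).
.runningMeanByOrder <- function(A, ord, halfWidth) {
  G <- nrow(A)
  if (G == 1) return(A)
  cs <- apply(rbind(0, A[ord, , drop = FALSE]), 2, cumsum)
  lo <- pmax(seq_len(G) - halfWidth, 1L)
  hi <- pmin(seq_len(G) + halfWidth, G)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  res <- matrix(NA_real_, G, ncol(A))
  res[ord, ] <- out
  res
}

.designMatrix <- function(design, metadata) {
  if (inherits(design, "formula")) {
    if (is.null(metadata)) stop("metadata required with a formula design")
    X <- stats::model.matrix(design, data = metadata)
  } else {
    X <- as.matrix(design)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    att <- attr(X, "assign")
    X2 <- X[, sort(keep), drop = FALSE]
    attr(X2, "assign") <- att[sort(keep)]
    X <- X2
  }
  X
}

## ---- exact test ------------------------------------------------------------

#' Negative-binomial exact test for a two-group comparison
#'
#' Counts are scaled to a common (geometric-mean) effective library size
#' ("pseudo-counts"), and for each gene the two-sided p-value sums the
#' probabilities of all group splits as or less probable than the observed
#' one, conditional on the gene's total, under the NB distribution of the
#' group sums at the gene's tagwise dispersion. log2 fold-changes come from
#' normalized group means with a small prior count to avoid infinities.
#'
#' @param counts gene x sample count matrix.
#' @param group two-level factor (second level is the "treated" numerator of
#'   the fold-change).
#' @param norm [tmmFactors()] result or NULL.
#' @param dispersions [estimateDispersions()] result or NULL (estimated with
#'   the one-factor design).
#' @param priorCount prior count per sample used in the fold-change.
#' @return A \linkS4class{DEResult} with test \code{"exact"}.
#' @export
nbExactTest <- function(counts, group, norm = NULL, dispersions = NULL,
                        priorCount = 0.125) {
  counts <- as.matrix(counts)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2)
    stop("exact test needs exactly two groups")
  if (any(table(group) == 0)) stop("a group has zero samples")
  norm <- .normOrTmm(counts, norm)
  if (is.null(dispersions)) {
    md <- data.frame(group = group)
    dispersions <- estimateDispersions(counts, ~group, md, norm = norm)
  }
  phi <- dispersions$tagwise
  if (length(phi) == 1) phi <- rep(phi, nrow(counts))
  eff <- norm$effectiveLibSizes
  common_lib <- exp(mean(log(eff)))
  pseudo <- sweep(counts, 2, common_lib / eff, "*")
  g1 <- group == levels(group)[1]
  nA <- sum(g1); nB <- sum(!g1)
  tA <- round(rowSums(pseudo[, g1, drop = FALSE]))
  tB <- round(rowSums(pseudo[, !g1, drop = FALSE]))
  pv <- vapply(seq_len(nrow(counts)), function(g)
    .exactNbPvalue(tA[g], tB[g], nA, nB, phi[g]), numeric(1))
  mA <- rowMeans(pseudo[, g1, drop = FALSE])
  mB <- rowMeans(pseudo[, !g1, drop = FALSE])
  logFC <- log2((mB + priorCount) / (mA + priorCount))
  tab <- DataFrame(gene = rownames(counts), logFC = logFC,
                   logCPM = .aveLogCPM(counts, eff),
                   PValue = pv, FDR = adjustFdr(pv))
  new("DEResult", table = tab,
      contrast = paste0(levels(group)[2], "_vs_", levels(group)[1]),
      test = "exact")
}

# Conditional two-sided exact NB p-value for observed group sums (tA, tB)
# with nA and nB samples and dispersion phi; phi = 0 uses the Poisson /
# binomial conditional limit.
.exactNbPvalue <- function(tA, tB, nA, nB, phi) {
  t <- tA + tB
  if (t == 0) return(1)
  ys <- 0:t
  if (phi < 1e-12) {
    lp <- stats::dbinom(ys, t, nA / (nA + nB), log = TRUE)
  } else {
    muhat <- t / (nA + nB)
    lp <- stats::dnbinom(ys, size = nA / phi, mu = nA * muhat, log = TRUE) +
      stats::dnbinom(t - ys, size = nB / phi, mu = nB * muhat, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  sel <- p <= p[tA + 1] * (1 + 1e-7)
  if (all(sel)) return(1)
  min(1, sum(p[sel]))
}

## ---- GLM likelihood-ratio test ---------------------------------------------

#' Negative-binomial GLM likelihood-ratio test
#'
#' Fits per-gene NB log-linear models (fixed tagwise dispersion, IRLS) for the
#' full design and the design with the tested term dropped; the p-value is
#' the chi-square upper tail of twice the log-likelihood difference with df
#' equal to the number of dropped columns. The log2 fold-change is the tested
#' coefficient (first column of the tested term).
#'
#' @param counts gene x sample count matrix.
#' @param design model formula containing \code{tested}.
#' @param metadata per-sample data.frame.
#' @param tested name of the model term to test (e.g. \code{"treatment"}).
#' @param norm,dispersions as in [nbExactTest()].
#' @param allowSaturated permit a full design with zero residual degrees of
#'   freedom (valid only with externally supplied dispersions; used by the
#'   interaction-design permutation scheme).
#' @return A \linkS4class{DEResult} with test \code{"glm_lrt"}; genes whose
#'   IRLS did not converge carry \code{PValue = NA}, are excluded from the FDR
#'   computation, and trigger a warning.
#' @export
nbGlmLRT <- function(counts, design, metadata, tested = "treatment",
                     norm = NULL, dispersions = NULL,
                     allowSaturated = FALSE) {
  counts <- as.matrix(counts)
  X <- .designMatrix(design, metadata)
  trm <- attr(stats::terms(design), "term.labels")
  if (!tested %in% trm)
    stop("tested term '", tested, "' not in the design")
  tidx <- which(attr(X, "assign") == match(tested, trm))
  if (!length(tidx))
    stop("tested term '", tested, "' has no estimable columns")
  if (nrow(X) - ncol(X) < 1 && !allowSaturated)
    stop("saturated design: no residual degrees of freedom")
  norm <- .normOrTmm(counts, norm)
  if (is.null(dispersions))
    dispersions <- estimateDispersions(counts, design, metadata, norm = norm)
  phi <- dispersions$tagwise
  if (length(phi) == 1) phi <- rep(phi, nrow(counts))
  eff <- norm$effectiveLibSizes
  offset <- log(eff)
  y <- t(counts)
  Xr <- X[, -tidx, drop = FALSE]
  full <- .nbGlmFitMatrix(y, X, offset, phi)
  red <- .nbGlmFitMatrix(y, Xr, offset, phi)
  lr <- pmax(2 * (full$loglik - red$loglik), 0)
  df <- length(tidx)
  pv <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  conv <- full$converged & red$converged
  if (any(!conv)) {
    warning(sum(!conv), " gene(s) failed IRLS convergence; PValue set to NA")
    pv[!conv] <- NA_real_
  }
  fdr <- rep(NA_real_, length(pv))
  fdr[conv] <- adjustFdr(pv[conv])
  logFC <- full$coefficients[tidx[1], ] / log(2)
  tab <- DataFrame(gene = rownames(counts), logFC = as.numeric(logFC),
                   logCPM = .aveLogCPM(counts, eff), PValue = pv, FDR = fdr,
                   converged = conv)
  new("DEResult", table = tab,
      contrast = paste0(tested, " (", deparse(design), ")"),
      test = "glm_lrt")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, capped at 1 and monotone in the p-value ranking.
#' NA/NaN p-values are rejected unless \code{naMask = TRUE}, in which case
#' they propagate as NA.
#'
#' @param p vector of p-values in [0, 1].
#' @param naMask allow and propagate missing p-values.
#' @return Adjusted p-values.
#' @export
adjustFdr <- function(p, naMask = FALSE) {
  if (anyNA(p) && !naMask)
    stop("NA/NaN p-values; use naMask = TRUE to propagate them")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
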
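#' Choose the soft-threshold power for an unsigned co-expression network
#'
#' For each candidate power the unsigned adjacency \code{|cor|^beta} is
#' formed, per-gene connectivity computed, and the scale-free topology fit
#' R^2 evaluated by regressing log10 p(k) on log10 k over connectivity bins
#' (signed R^2, truncated at 0, so a positive slope scores 0). Returns the
#' smallest power whose fit exceeds \code{r2Target}, or the best-fitting
#' power with a warning when none does. Constant gene rows are dropped with
#' a warning before correlation.
#'
#' @param logtpm gene x sample matrix (>= 3 genes, >= 4 samples).
#' @param r2Target scale-free fit target.
#' @param maxPower largest power tried.
#' @param nBins connectivity histogram bins for the fit.
#' @return list of class \code{NetworkParams}: \code{power},
#'   \code{scale_free_r2}, \code{fit_by_power}, \code{network_type}.
#' @export
pickSoftPower <- function(logtpm, r2Target = 0.9, maxPower = 20, nBins = 10) {
  x <- as.matrix(logtpm)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene row(s) dropped")
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 3 || ncol(x) < 4)
    stop("need >= 3 varying genes and >= 4 samples")
  ac <- abs(stats::cor(t(x)))
  diag(ac) <- 0
  fits <- vapply(seq_len(maxPower), function(beta) {
    k <- rowSums(ac ^ beta)
    .scaleFreeR2(k, nBins)
  }, numeric(1))
  ok <- which(fits > r2Target)
  if (length(ok)) {
    power <- min(ok)
  } else {
    power <- which.max(fits)
    warning("no power reached the scale-free target R^2 > ", r2Target,
            "; returning the best fit (power = ", power, ")")
  }
  out <- list(power = power, scale_free_r2 = fits[power],
              fit_by_power = fits, network_type = "unsigned")
  class(out) <- "NetworkParams"
  out
}

# Signed scale-free fit statistic of a connectivity distribution, truncated
# at zero; degenerate (near-constant) connectivity scores 0.
.scaleFreeR2 <- function(k, nBins) {
  k <- k[k > 0]
  if (length(k) < 3 || stats::sd(k) < 1e-12) return(0)
  br <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  dk <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0 & !is.na(dk) & dk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  max(0, -sign(slope) * r2)
}

#' Unsigned co-expression adjacency matrix
#'
#' @param logtpm gene x sample matrix.
#' @param power soft-threshold power.
#' @return \code{|cor|^power} with zero diagonal.
#' @export
adjacencyMatrix <- function(logtpm, power) {
  a <- abs(stats::cor(t(as.matrix(logtpm)))) ^ power
  a[is.na(a)] <- 0
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' with unit diagonal (unsigned TOM).
#'
#' @param adjacency symmetric matrix in [0, 1] with zero diagonal.
#' @return TOM similarity matrix.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(a < 0) || any(a > 1)) stop("adjacency values must lie in [0, 1]")
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# WGCNA-style module color sequence for deterministic size-ordered labels.
.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue")

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM with
#' a static cut at \code{cutHeight}; clusters smaller than
#' \code{minModuleSize} are pooled into the \code{"grey"} label (the
#' unassigned set, which remains reportable as a gene set). Assigned modules
#' are labeled deterministically by descending size (turquoise, blue, brown,
#' ...), so the clustering involves no randomness.
#'
#' @param tom square symmetric TOM matrix with gene dimnames.
#' @param minModuleSize smallest cluster kept as a module (>= 2).
#' @param cutHeight static cut height on 1 - TOM.
#' @return list of class \code{ModuleAssignment}: \code{labels} (named
#'   per-gene), \code{sizes}, \code{assigned} (labels excluding grey).
#' @export
detectModules <- function(tom, minModuleSize = 10, cutHeight = 0.99) {
  if (minModuleSize < 2) stop("minModuleSize must be >= 2")
  tom <- as.matrix(tom)
  if (!isSymmetric(unname(tom), tol = 1e-8)) stop("TOM must be symmetric")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cutHeight)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= minModuleSize]
  ord <- big[order(-sizes[big], as.integer(big))]
  labels <- rep("grey", length(cl))
  for (i in seq_along(ord)) {
    lab <- if (i <= length(.MODULE_COLORS)) .MODULE_COLORS[i] else
      paste0("module_", i)
    labels[cl == ord[i]] <- lab
  }
  names(labels) <- genes
  out <- list(labels = labels, sizes = table(labels),
              assigned = setdiff(unique(labels), "grey"),
              min_module_size = minModuleSize, cut_height = cutHeight)
  class(out) <- "ModuleAssignment"
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right-singular-vector score of the
#' module's gene-standardized expression (zero mean across samples),
#' sign-aligned so that its correlation with the module's average
#' standardized expression is positive. A one-gene module's eigengene is that
#' gene's (unit-normalized) z-score. Eigengenes are computed for every label,
#' including \code{"grey"}, which the analysis treats as a reportable set.
#'
#' @param logtpm gene x sample matrix covering the assigned genes.
#' @param assignment a [detectModules()] result (or named label vector).
#' @return list: \code{eigengenes} (samples x modules), \code{var_explained}
#'   (named fractions).
#' @export
moduleEigengenes <- function(logtpm, assignment) {
  labels <- if (inherits(assignment, "ModuleAssignment"))
    assignment$labels else assignment
  miss <- setdiff(names(labels), rownames(logtpm))
  if (length(miss))
    stop("assigned genes absent from the matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  mods <- unique(labels)
  eg <- matrix(NA_real_, ncol(logtpm), length(mods),
               dimnames = list(colnames(logtpm), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(labels)[labels == m]
    z <- .zscoreRows(logtpm[genes, , drop = FALSE])
    sv <- svd(z)
    v1 <- sv$v[, 1]
    avg <- colMeans(z)
    if (stats::sd(avg) > 0 && stats::cor(v1, avg) < 0) v1 <- -v1
    eg[, m] <- v1
    tot <- sum(sv$d ^ 2)
    ve[m] <- if (tot > 0) sv$d[1] ^ 2 / tot else 0
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Disease x treatment interaction model per module eigengene
#'
#' Fits \code{lm(eigengene ~ diagnosis + treatment + diagnosis:treatment)}
#' per module and reports sequential F-tests for the disease, treatment, and
#' interaction terms; modules with interaction p < 0.05 are flagged.
#'
#' @param eigengenes samples x modules matrix from [moduleEigengenes()].
#' @param metadata per-sample data.frame with \code{sample_id},
#'   \code{diagnosis}, \code{treatment}.
#' @return data.frame: one row per module with F and p for each term and
#'   \code{interaction_significant}.
#' @export
eigengeneModel <- function(eigengenes, metadata) {
  md <- as.data.frame(metadata)
  idx <- match(rownames(eigengenes), md$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  dg <- factor(md$diagnosis[idx], levels = .DIAGNOSIS_LEVELS)
  tr <- factor(md$treatment[idx])
  do.call(rbind, lapply(colnames(eigengenes), function(m) {
    y <- eigengenes[, m]
    av <- stats::anova(stats::lm(y ~ dg * tr))
    data.frame(module = m,
               F_disease = av$`F value`[1], p_disease = av$`Pr(>F)`[1],
               F_treatment = av$`F value`[2], p_treatment = av$`Pr(>F)`[2],
               F_interaction = av$`F value`[3],
               p_interaction = av$`Pr(>F)`[3],
               interaction_significant = av$`Pr(>F)`[3] < 0.05,
               stringsAsFactors = FALSE)
  }))
}
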
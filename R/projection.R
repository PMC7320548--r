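#' Fit a reference PC space on the control treatment signature
#'
#' Restricts the log-expression matrix to the signature genes and the
#' fitting samples (controls in the vehicle and acute arms by default),
#' centers and optionally scales each gene by the fitting-sample statistics,
#' and extracts the first two principal components by singular value
#' decomposition. PC1 is oriented so that the mean score of treated fitting
#' samples exceeds that of vehicle samples, making "positive shift =
#' control-like response" stable across runs. Zero-variance genes in the
#' fitting samples are dropped with a warning.
#'
#' @param logtpm gene x sample log2(TPM+1) matrix.
#' @param metadata per-sample data.frame (\code{sample_id},
#'   \code{diagnosis}, \code{treatment}).
#' @param genes signature genes (>= 2 retained after variance filtering).
#' @param fitDiagnosis diagnosis of the fitting samples.
#' @param arms the two arms defining the response axis (reference, treated).
#' @param scale z-scale genes by fitting-sample SD (default TRUE).
#' @return A \linkS4class{PCSpace}.
#' @export
fitPCSpace <- function(logtpm, metadata, genes, fitDiagnosis = "CTL",
                       arms = c("H2O", "acute"), scale = TRUE) {
  md <- as.data.frame(metadata)
  idx <- match(colnames(logtpm), md$sample_id)
  sel <- md$diagnosis[idx] %in% fitDiagnosis & md$treatment[idx] %in% arms
  if (sum(sel) < 3) stop("fewer than 3 fitting samples")
  genes <- intersect(genes, rownames(logtpm))
  x <- t(logtpm[genes, sel, drop = FALSE])      # samples x genes
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance signature gene(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
    genes <- genes[sds > 0]
  }
  if (length(genes) < 2) stop("fewer than 2 usable signature genes")
  center <- colMeans(x)
  scl <- if (scale) apply(x, 2, stats::sd) else rep(1, length(genes))
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  sv <- svd(xs)
  rot <- sv$v[, 1:2, drop = FALSE]
  if (ncol(rot) < 2) rot <- cbind(rot, 0)
  scores <- xs %*% rot
  tr <- md$treatment[idx][sel]
  if (mean(scores[tr == arms[2], 1]) < mean(scores[tr == arms[1], 1])) {
    rot[, 1] <- -rot[, 1]
    scores[, 1] <- -scores[, 1]
  }
  dimnames(rot) <- list(genes, c("PC1", "PC2"))
  colnames(scores) <- c("PC1", "PC2")
  rownames(scores) <- rownames(x)
  ev <- sv$d ^ 2
  new("PCSpace", genes = genes,
      center = stats::setNames(center, genes),
      scale = stats::setNames(scl, genes),
      rotation = rot,
      varExplained = if (sum(ev) > 0) ev[1:2] / sum(ev) else c(0, 0),
      fitScores = scores)
}

#' Project samples onto a fitted PC space
#'
#' Samples are standardized with the space's own center and scale (learned
#' from the fitting samples) and multiplied by the stored loadings, so each
#' sample's score is independent of which other samples are projected.
#' Missing signature genes are an error, not imputed.
#'
#' @param logtpm gene x sample matrix containing all space genes.
#' @param pcSpace a \linkS4class{PCSpace}.
#' @return samples x 2 score matrix (PC1, PC2).
#' @export
projectSamples <- function(logtpm, pcSpace) {
  miss <- setdiff(pcSpace@genes, rownames(logtpm))
  if (length(miss))
    stop("signature gene(s) absent from input: ",
         paste(utils::head(miss, 10), collapse = ", "))
  x <- t(logtpm[pcSpace@genes, , drop = FALSE])
  xs <- sweep(sweep(x, 2, pcSpace@center), 2, pcSpace@scale, "/")
  scores <- xs %*% pcSpace@rotation
  colnames(scores) <- c("PC1", "PC2")
  scores
}

#' Per-patient response shift along PC1
#'
#' Averages each patient's PC1 score within the vehicle and treated arms and
#' reports \code{delta_pc1 = mean(treated) - mean(vehicle)} with the strict
#' responder rule \code{delta_pc1 > 0}. Patients missing an arm are flagged
#' (\code{complete = FALSE}), not dropped. The table is ordered by
#' descending delta.
#'
#' @param scores samples x >=1 score matrix from [projectSamples()].
#' @param metadata per-sample data.frame (\code{sample_id},
#'   \code{patient_id}, \code{diagnosis}, \code{treatment}).
#' @param arms reference and treated arm labels.
#' @return A \linkS4class{ProjectionResult}.
#' @export
patientShift <- function(scores, metadata, arms = c("H2O", "acute")) {
  md <- as.data.frame(metadata)
  idx <- match(rownames(scores), md$sample_id)
  if (anyNA(idx)) stop("scored samples missing from metadata")
  df <- data.frame(sample_id = rownames(scores),
                   patient_id = md$patient_id[idx],
                   diagnosis = md$diagnosis[idx],
                   treatment = md$treatment[idx],
                   PC1 = scores[, 1],
                   PC2 = if (ncol(scores) > 1) scores[, 2] else NA_real_,
                   stringsAsFactors = FALSE)
  df <- df[df$treatment %in% arms, ]
  shifts <- do.call(rbind, lapply(split(df, df$patient_id), function(d) {
    ref <- d$PC1[d$treatment == arms[1]]
    trt <- d$PC1[d$treatment == arms[2]]
    complete <- length(ref) > 0 && length(trt) > 0
    delta <- if (complete) mean(trt) - mean(ref) else NA_real_
    data.frame(patient_id = d$patient_id[1], diagnosis = d$diagnosis[1],
               mean_pc1_ref = if (length(ref)) mean(ref) else NA_real_,
               mean_pc1_treated = if (length(trt)) mean(trt) else NA_real_,
               delta_pc1 = delta,
               responder = isTRUE(delta > 0),
               complete = complete, stringsAsFactors = FALSE)
  }))
  shifts <- shifts[order(-ifelse(is.na(shifts$delta_pc1), -Inf,
                                 shifts$delta_pc1)), ]
  rownames(shifts) <- NULL
  new("ProjectionResult", scores = df, shifts = shifts)
}

#' Association between a response measure and a covariate
#'
#' Ordinary least squares \code{y ~ x} with the F-test of the slope.
#'
#' @param x numeric predictor (e.g. per-patient delta PC1); zero variance is
#'   an error.
#' @param y numeric covariate of the same length.
#' @param name covariate label carried into the result.
#' @return list of class \code{CovariateAssociation}: \code{covariate},
#'   \code{slope}, \code{F}, \code{p}, \code{n}.
#' @export
covariateAssociation <- function(x, y, name = "covariate") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  av <- stats::anova(fit)
  out <- list(covariate = name, slope = unname(stats::coef(fit)[2]),
              F = av$`F value`[1], p = av$`Pr(>F)`[1], n = length(x))
  class(out) <- "CovariateAssociation"
  out
}
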
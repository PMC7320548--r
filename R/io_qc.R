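#' Read a gene x sample abundance table
#'
#' Reads a TSV whose first column is the gene id and whose remaining columns
#' are samples, validating uniqueness and non-negativity.
#'
#' @param path TSV file path.
#' @param kind \code{"counts"}, \code{"tpm"} or \code{"logtpm"}; stored as the
#'   \code{"abundanceKind"} attribute of the returned matrix.
#' @return Numeric matrix with gene rownames, sample colnames and an
#'   \code{abundanceKind} attribute.
#' @export
readAbundance <- function(path, kind = c("counts", "tpm", "logtpm")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("abundance file has no columns: ", path)
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (length(m) && (any(!is.finite(m)) || any(m < 0)))
    stop("abundance matrix contains negative or non-finite values")
  attr(m, "abundanceKind") <- kind
  m
}

#' Read a sample metadata table
#'
#' @param path TSV with columns \code{sample_id}, \code{patient_id},
#'   \code{diagnosis}, \code{treatment}, \code{replicate} and optional
#'   covariates (e.g. \code{activity}).
#' @return Validated data.frame.
#' @export
readMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "diagnosis", "treatment", "replicate")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(md$diagnosis), .DIAGNOSIS_LEVELS)
  if (length(bad))
    stop("invalid diagnosis value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(md$treatment), .TREATMENT_LEVELS)
  if (length(bad))
    stop("invalid treatment value(s): ", paste(bad, collapse = ", "))
  md
}

#' Read a fixture directory into a ResponseExperiment
#'
#' Counterpart of [writeFixture()]: reads \code{counts.tsv}, \code{tpm.tsv}
#' and \code{metadata.tsv} and validates that matrices and metadata agree.
#'
#' @param directory directory holding the fixture files.
#' @return A \linkS4class{ResponseExperiment}.
#' @export
readResponseExperiment <- function(directory) {
  counts <- readAbundance(file.path(directory, "counts.tsv"), "counts")
  tpm_path <- file.path(directory, "tpm.tsv")
  tpm <- if (file.exists(tpm_path)) readAbundance(tpm_path, "tpm") else NULL
  md <- readMetadata(file.path(directory, "metadata.tsv"))
  ResponseExperiment(counts, md, tpm = tpm)
}

#' log2(x + 1) normalization of a TPM matrix
#'
#' @param x a TPM-tagged matrix (attribute \code{abundanceKind == "tpm"}) or a
#'   \linkS4class{ResponseExperiment} with a \code{tpm} assay.
#' @return Matrix tagged \code{logtpm}, or the experiment with a \code{logtpm}
#'   assay added.
#' @export
setGeneric("logNormalize", function(x) standardGeneric("logNormalize"))

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "matrix", function(x) {
  kind <- attr(x, "abundanceKind")
  if (!is.null(kind) && kind != "tpm")
    stop("logNormalize expects a TPM matrix, got kind '", kind, "'")
  out <- log2(x + 1)
  attr(out, "abundanceKind") <- "logtpm"
  out
})

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "ResponseExperiment", function(x) {
  if (!"tpm" %in% assayNames(x))
    stop("experiment has no 'tpm' assay")
  assay(x, "logtpm") <- log2(assay(x, "tpm") + 1)
  x
})

.logtpmOf <- function(se) {
  if ("logtpm" %in% assayNames(se)) return(assay(se, "logtpm"))
  if ("tpm" %in% assayNames(se)) return(log2(assay(se, "tpm") + 1))
  stop("experiment has neither 'logtpm' nor 'tpm' assay")
}

#' Exclude outlier samples by detected-gene count and PCA position
#'
#' Two passes, mirroring standard bulk RNA-seq sample QC: (1) samples whose
#' natural-log number of detected genes (abundance > 0) falls below
#' \code{logGeneCountThreshold} are removed; (2) on the log-normalized data of
#' the remaining samples, samples whose Euclidean distance from the centroid
#' in (PC1, PC2) exceeds the mean centroid distance by more than
#' \code{pcaSdK} standard deviations of that distance are removed. With \code{ln} threshold 6 the first rule corresponds to
#' roughly 403 detected genes. Identical samples (zero distance spread) yield
#' no PCA exclusions.
#'
#' @param se a \linkS4class{ResponseExperiment} (>= 3 samples).
#' @param logGeneCountThreshold threshold on ln(detected genes).
#' @param pcaSdK number of SDs of centroid distance beyond which a sample is
#'   an outlier.
#' @return list with \code{experiment} (filtered) and \code{report} (class
#'   \code{QCReport}: \code{excluded} data.frame of sample/reason,
#'   \code{detected_genes}, \code{pca_coordinates}).
#' @export
excludeOutliers <- function(se, logGeneCountThreshold = 6, pcaSdK = 3) {
  if (ncol(se) < 3L) stop("need at least 3 samples for outlier QC")
  counts <- assay(se, "counts")
  detected <- colSums(counts > 0)
  low <- colnames(se)[log(pmax(detected, 1)) < logGeneCountThreshold]
  keep <- setdiff(colnames(se), low)
  if (!length(keep))
    stop("all samples excluded by the gene-count rule; check inputs")
  excluded <- data.frame(sample_id = low,
                         reason = rep("low_gene_count", length(low)),
                         stringsAsFactors = FALSE)
  sub <- se[, keep]
  lt <- .logtpmOf(sub)
  pcs <- tryCatch({
    pr <- stats::prcomp(t(lt), center = TRUE, scale. = FALSE, rank. = 2)
    sc <- pr$x
    if (ncol(sc) < 2) cbind(sc, 0)[, 1:2, drop = FALSE] else sc[, 1:2]
  }, error = function(e) matrix(0, ncol(sub), 2))
  rownames(pcs) <- colnames(sub)
  cent <- colMeans(pcs)
  d <- sqrt((pcs[, 1] - cent[1])^2 + (pcs[, 2] - cent[2])^2)
  sdd <- stats::sd(d)
  pca_out <- if (is.na(sdd) || sdd == 0) character(0) else
    names(d)[d > mean(d) + pcaSdK * sdd]
  if (length(pca_out) == ncol(sub))
    stop("all samples excluded by the PCA rule; check inputs")
  excluded <- rbind(excluded,
                    data.frame(sample_id = pca_out,
                               reason = rep("pca_outlier", length(pca_out)),
                               stringsAsFactors = FALSE))
  keep2 <- setdiff(keep, pca_out)
  report <- list(excluded = excluded,
                 detected_genes = detected,
                 pca_coordinates = pcs)
  class(report) <- "QCReport"
  list(experiment = se[, keep2], report = report)
}

#' Cell-type signature scores and disease association
#'
#' For each marker set, each member gene's log expression is z-scored across
#' samples (a zero-variance gene contributes 0) and summed per sample; the
#' per-set disease association p-value comes from the F-test on diagnosis in
#' the linear model \code{score ~ diagnosis}.
#'
#' @param se a \linkS4class{ResponseExperiment}.
#' @param markerSets named list of character vectors of marker genes. Markers
#'   absent from the matrix are dropped with a warning; an empty set after
#'   intersection is an error.
#' @return list with \code{scores} (samples x sets matrix) and
#'   \code{association} (data.frame: set, n_genes, F, p).
#' @export
cellTypeScores <- function(se, markerSets) {
  if (is.null(names(markerSets)) || any(!nzchar(names(markerSets))))
    stop("markerSets must be a named list")
  lt <- .logtpmOf(se)
  dg <- factor(diagnosis(se), levels = .DIAGNOSIS_LEVELS)
  scores <- matrix(0, ncol(se), length(markerSets),
                   dimnames = list(colnames(se), names(markerSets)))
  assoc <- data.frame(set = names(markerSets), n_genes = NA_integer_,
                      F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(markerSets)) {
    nm <- names(markerSets)[i]
    genes <- intersect(markerSets[[i]], rownames(lt))
    dropped <- setdiff(markerSets[[i]], genes)
    if (length(dropped))
      warning("marker set '", nm, "': ", length(dropped),
              " gene(s) absent from the matrix, dropped")
    if (!length(genes))
      stop("marker set '", nm, "' is empty after intersection with the matrix")
    sub <- lt[genes, , drop = FALSE]
    z <- .zscoreRows(sub)
    scores[, i] <- colSums(z)
    assoc$n_genes[i] <- length(genes)
    if (nlevels(droplevels(dg)) == 2 && stats::sd(scores[, i]) > 0) {
      fit <- stats::lm(scores[, i] ~ dg)
      av <- stats::anova(fit)
      assoc$F[i] <- av$`F value`[1]
      assoc$p[i] <- av$`Pr(>F)`[1]
    } else {
      assoc$p[i] <- 1
    }
  }
  list(scores = scores, association = assoc)
}

# Row-wise z-score; zero-variance rows map to 0 by convention.
.zscoreRows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Serialize a QC report to JSON
#'
#' @param report a \code{QCReport} from [excludeOutliers()].
#' @param path output JSON path.
#' @export
writeQCReport <- function(report, path) {
  jsonlite::write_json(
    list(excluded = report$excluded,
         detected_genes = as.list(report$detected_genes),
         pca_coordinates = data.frame(sample_id = rownames(report$pca_coordinates),
                                      PC1 = report$pca_coordinates[, 1],
                                      PC2 = report$pca_coordinates[, 2])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
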
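#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.DIAGNOSIS_LEVELS <- c("CTL", "ASD")
.TREATMENT_LEVELS <- c("H2O", "acute", "chronic")

#' ResponseExperiment: gene x sample abundances with treatment design
#'
#' A \linkS4class{SummarizedExperiment} subclass holding raw counts (assay
#' \code{"counts"}) and optionally TPM (\code{"tpm"}) and log2(TPM+1)
#' (\code{"logtpm"}) views of the same gene x sample table, together with the
#' per-sample design: patient, diagnosis (\code{CTL}/\code{ASD}), treatment arm
#' (\code{H2O}/\code{acute}/\code{chronic}), replicate, and optional covariates
#' such as the mean spontaneous burst rate from multielectrode recordings.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots are added,
#'   the class exists for validity and method dispatch.
#'
#' @export
setClass("ResponseExperiment", contains = "SummarizedExperiment")

setValidity("ResponseExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!"counts" %in% an)
    msg <- c(msg, "assay 'counts' is required")
  for (nm in an) {
    a <- assay(object, nm)
    if (any(!is.finite(a)) || any(a < 0))
      msg <- c(msg, sprintf("assay '%s' contains negative or non-finite values", nm))
  }
  cd <- colData(object)
  need <- c("patient_id", "diagnosis", "treatment", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData is missing column(s): ", paste(miss, collapse = ", ")))
  if ("diagnosis" %in% colnames(cd) &&
      !all(as.character(cd$diagnosis) %in% .DIAGNOSIS_LEVELS))
    msg <- c(msg, "diagnosis values must be in {CTL, ASD}")
  if ("treatment" %in% colnames(cd) &&
      !all(as.character(cd$treatment) %in% .TREATMENT_LEVELS))
    msg <- c(msg, "treatment values must be in {H2O, acute, chronic}")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ResponseExperiment
#'
#' @param counts non-negative gene x sample count matrix with row and column
#'   names.
#' @param metadata data.frame (or DataFrame) with one row per sample and
#'   columns \code{sample_id}, \code{patient_id}, \code{diagnosis},
#'   \code{treatment}, \code{replicate} plus optional covariate columns.
#'   Rows are matched to \code{colnames(counts)} by \code{sample_id}.
#' @param tpm optional TPM matrix of identical dimensions.
#' @param logtpm optional log2(TPM+1) matrix; computed lazily by
#'   [logNormalize()] when absent.
#'
#' @return A \linkS4class{ResponseExperiment}.
#' @export
ResponseExperiment <- function(counts, metadata, tpm = NULL, logtpm = NULL) {
  counts <- as.matrix(counts)
  attr(counts, "abundanceKind") <- NULL
  metadata <- as.data.frame(metadata)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("'counts' must have gene rownames and sample colnames")
  if (!"sample_id" %in% colnames(metadata))
    stop("metadata must contain a 'sample_id' column")
  if (anyDuplicated(metadata$sample_id))
    stop("metadata sample_id values must be unique")
  missing_md <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_md))
    stop("samples absent from metadata: ", paste(missing_md, collapse = ", "))
  extra_md <- setdiff(metadata$sample_id, colnames(counts))
  if (length(extra_md))
    stop("metadata rows without matrix columns: ", paste(extra_md, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  assays <- list(counts = counts)
  for (nm in c("tpm", "logtpm")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m)
      attr(m, "abundanceKind") <- NULL
      if (!identical(dim(m), dim(counts)))
        stop("'", nm, "' dimensions differ from 'counts'")
      dimnames(m) <- dimnames(counts)
      assays[[nm]] <- m
    }
  }
  cd <- DataFrame(metadata, row.names = metadata$sample_id)
  se <- SummarizedExperiment(assays = assays, colData = cd)
  new("ResponseExperiment", se)
}

setMethod("show", "ResponseExperiment", function(object) {
  cd <- colData(object)
  cat("ResponseExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (nrow(cd)) {
    cat("  patients:", length(unique(cd$patient_id)),
        sprintf("(%d CTL, %d ASD samples)",
                sum(cd$diagnosis == "CTL"), sum(cd$diagnosis == "ASD")), "\n")
    cat("  treatment arms:", paste(names(table(cd$treatment)), collapse = ", "), "\n")
  }
})

#' @rdname ResponseExperiment
#' @param object,x a \code{ResponseExperiment}.
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))
#' @rdname ResponseExperiment
#' @export
setMethod("diagnosis", "ResponseExperiment",
          function(x) as.character(colData(x)$diagnosis))
#' @rdname ResponseExperiment
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))
#' @rdname ResponseExperiment
#' @export
setMethod("treatment", "ResponseExperiment",
          function(x) as.character(colData(x)$treatment))
#' @rdname ResponseExperiment
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname ResponseExperiment
#' @export
setMethod("patientId", "ResponseExperiment",
          function(x) as.character(colData(x)$patient_id))

#' DEResult: one differential-expression contrast
#'
#' Per-gene log2 fold-change, average abundance (logCPM), p-value and
#' Benjamini-Hochberg adjusted p-value for a single contrast. Genes failing the
#' expression filter are absent from the table, not NA.
#'
#' @slot table DataFrame with columns \code{gene}, \code{logFC}, \code{logCPM},
#'   \code{PValue}, \code{FDR} (and \code{converged} for GLM results).
#' @slot contrast character label of the contrast tested.
#' @slot test one of \code{"exact"} or \code{"glm_lrt"}.
#' @export
setClass("DEResult",
         representation(table = "DataFrame", contrast = "character",
                        test = "character"))

setValidity("DEResult", function(object) {
  tab <- object@table
  need <- c("gene", "logFC", "logCPM", "PValue", "FDR")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    return(paste0("table missing column(s): ", paste(miss, collapse = ", ")))
  p <- tab$PValue[!is.na(tab$PValue)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    return("PValue outside [0,1]")
  if (!object@test %in% c("exact", "glm_lrt"))
    return("test must be 'exact' or 'glm_lrt'")
  TRUE
})

setMethod("show", "DEResult", function(object) {
  tab <- object@table
  cat("DEResult [", object@test, "] contrast:", object@contrast, "\n")
  cat(" ", nrow(tab), "genes tested;",
      sum(tab$FDR < 0.05, na.rm = TRUE), "at FDR < 0.05\n")
})

#' @rdname DEResult
#' @param object,x a \code{DEResult}.
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))
#' @rdname DEResult
#' @export
setMethod("deTable", "DEResult", function(x) as.data.frame(x@table))

#' @rdname DEResult
#' @param fdrCut FDR threshold for calling a gene significant.
#' @export
setGeneric("significantGenes", function(x, fdrCut = 0.05)
  standardGeneric("significantGenes"))
#' @rdname DEResult
#' @export
setMethod("significantGenes", "DEResult", function(x, fdrCut = 0.05) {
  tab <- x@table
  as.character(tab$gene[!is.na(tab$FDR) & tab$FDR < fdrCut])
})

#' PCSpace: a reference principal-component space
#'
#' Loadings, per-gene center and scale learned from a set of fitting samples
#' (the control acute-treatment signature), onto which further samples can be
#' projected with [projectSamples()].
#'
#' @slot genes character vector of signature genes retained in the fit.
#' @slot center,scale per-gene centering/scaling values from the fitting
#'   samples.
#' @slot rotation genes x 2 loading matrix (PC1, PC2), orthonormal columns.
#' @slot varExplained fraction of variance carried by PC1 and PC2.
#' @slot fitScores scores of the fitting samples (for reference/plotting).
#' @export
setClass("PCSpace",
         representation(genes = "character", center = "numeric",
                        scale = "numeric", rotation = "matrix",
                        varExplained = "numeric", fitScores = "matrix"))

setValidity("PCSpace", function(object) {
  p <- length(object@genes)
  if (length(object@center) != p || length(object@scale) != p)
    return("center/scale lengths must equal gene count")
  if (!identical(dim(object@rotation), c(p, 2L)))
    return("rotation must be genes x 2")
  ctc <- crossprod(object@rotation)
  if (max(abs(ctc - diag(2))) > 1e-6)
    return("loadings must be orthonormal")
  TRUE
})

setMethod("show", "PCSpace", function(object) {
  cat("PCSpace:", length(object@genes), "signature genes,",
      nrow(object@fitScores), "fitting samples\n")
  cat("  variance explained: PC1",
      sprintf("%.1f%%,", 100 * object@varExplained[1]),
      "PC2", sprintf("%.1f%%\n", 100 * object@varExplained[2]))
})

#' ProjectionResult: per-sample scores and per-patient response shifts
#'
#' @slot scores data.frame of per-sample PC1/PC2 scores with design columns.
#' @slot shifts data.frame with one row per patient: mean PC1 per arm,
#'   \code{delta_pc1} (treated minus vehicle), strict-positive
#'   \code{responder} flag, and a \code{complete} flag marking patients with
#'   both arms present (patients missing an arm are flagged, not dropped).
#' @export
setClass("ProjectionResult",
         representation(scores = "data.frame", shifts = "data.frame"))

setMethod("show", "ProjectionResult", function(object) {
  sh <- object@shifts
  cat("ProjectionResult:", nrow(object@scores), "samples,",
      nrow(sh), "patients\n")
  ok <- sh$complete
  cat("  responders (delta PC1 > 0):", sum(sh$responder[ok]),
      "of", sum(ok), "patients with both arms\n")
})

#' @rdname ProjectionResult
#' @param object,x a \code{ProjectionResult}.
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))
#' @rdname ProjectionResult
#' @export
setMethod("sampleScores", "ProjectionResult", function(x) x@scores)
#' @rdname ProjectionResult
#' @export
setGeneric("patientShifts", function(x) standardGeneric("patientShifts"))
#' @rdname ProjectionResult
#' @export
setMethod("patientShifts", "ProjectionResult", function(x) x@shifts)
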
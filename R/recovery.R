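#' Baseline disease differential expression
#'
#' Exact-test comparison of ASD vs CTL samples within the vehicle (H2O) arm;
#' the fold-change is ASD relative to CTL.
#'
#' @param se a \linkS4class{ResponseExperiment}.
#' @param minSamples,minValue expression filter (see [filterExpressed()]).
#' @param ... passed to [nbExactTest()].
#' @return A \linkS4class{DEResult}.
#' @export
baselineDE <- function(se, minSamples = 3, minValue = 1, ...) {
  sub <- se[, treatment(se) == "H2O"]
  dg <- factor(diagnosis(sub), levels = .DIAGNOSIS_LEVELS)
  if (nlevels(droplevels(dg)) != 2)
    stop("both diagnoses must be present in the H2O arm")
  counts <- filterExpressed(assay(sub, "counts"), minSamples, minValue)
  res <- nbExactTest(counts, dg, ...)
  res@contrast <- "ASD_vs_CTL_H2O"
  res
}

#' Classify recovery of baseline disease genes under treatment
#'
#' For every gene differentially expressed between ASD and CTL at baseline
#' (FDR < \code{fdrCut}), the gene is called \code{recovered} under an arm
#' when the treatment shift in ASD opposes the baseline disease sign
#' (\code{sign(treatment logFC) == -sign(baseline logFC)}) and — under the
#' default \code{"strict"} rule — the treated-ASD vs control contrast for
#' that arm is no longer significant. \code{rule = "sign"} uses the sign
#' condition alone (pure fold-change quadrant membership). The combined
#' category intersects the per-arm calls.
#'
#' Separately, "IGF-1 altered" genes — normal at baseline but significantly
#' different from the control state only after treatment — are reported per
#' arm under both readings of that definition: treated-ASD vs control
#' (\code{igf1_altered_vs_ctl}) and treated-ASD vs vehicle-ASD
#' (\code{igf1_altered_within_asd}).
#'
#' @param baseline baseline ASD-vs-CTL \linkS4class{DEResult} (H2O arm).
#' @param asdAcute,asdChronic treated-vs-vehicle \linkS4class{DEResult}s
#'   within ASD.
#' @param postVsCtlAcute,postVsCtlChronic treated-ASD vs vehicle-CTL
#'   \linkS4class{DEResult}s.
#' @param fdrCut significance cutoff.
#' @param rule \code{"strict"} (sign reversal + post-treatment
#'   non-difference) or \code{"sign"}.
#' @return list of class \code{RecoveryCalls}: \code{calls} (one row per
#'   baseline-DE gene: per-arm logFCs, per-arm categories, \code{combined})
#'   and the two per-arm IGF-1-altered gene lists.
#' @export
classifyRecovery <- function(baseline, asdAcute, asdChronic,
                             postVsCtlAcute, postVsCtlChronic,
                             fdrCut = 0.05, rule = c("strict", "sign")) {
  rule <- match.arg(rule)
  inputs <- list(baseline = baseline, asdAcute = asdAcute,
                 asdChronic = asdChronic, postVsCtlAcute = postVsCtlAcute,
                 postVsCtlChronic = postVsCtlChronic)
  for (nm in names(inputs))
    if (!methods::is(inputs[[nm]], "DEResult"))
      stop("missing or invalid contrast: ", nm)
  bt <- deTable(baseline)
  baseGenes <- significantGenes(baseline, fdrCut)
  lookup <- function(res) {
    tab <- deTable(res)
    miss <- setdiff(baseGenes, tab$gene)
    if (length(miss))
      stop("contrast '", res@contrast, "' lacks ", length(miss),
           " baseline-DE gene(s); compute all contrasts on one filtered set")
    tab[match(baseGenes, tab$gene), ]
  }
  bl <- bt[match(baseGenes, bt$gene), ]
  armCall <- function(treatRes, postRes) {
    tt <- lookup(treatRes); pp <- lookup(postRes)
    signOpp <- sign(tt$logFC) == -sign(bl$logFC) & tt$logFC != 0
    postOk <- is.na(pp$FDR) | pp$FDR >= fdrCut
    rec <- if (rule == "strict") signOpp & postOk else signOpp
    list(logFC = tt$logFC, recovered = rec)
  }
  ac <- armCall(asdAcute, postVsCtlAcute)
  ch <- armCall(asdChronic, postVsCtlChronic)
  combined <- ifelse(ac$recovered & ch$recovered, "recovered_both",
               ifelse(ac$recovered, "recovered_acute_only",
                ifelse(ch$recovered, "recovered_chronic_only",
                       "not_recovered")))
  calls <- data.frame(gene = baseGenes,
                      baseline_logfc = bl$logFC,
                      logfc_acute = ac$logFC,
                      logfc_chronic = ch$logFC,
                      recovered_acute = ac$recovered,
                      recovered_chronic = ch$recovered,
                      combined = combined,
                      stringsAsFactors = FALSE)
  notBase <- function(res) {
    tab <- deTable(res)
    nb <- setdiff(tab$gene, baseGenes)
    tabb <- tab[match(nb, tab$gene), ]
    as.character(tabb$gene[!is.na(tabb$FDR) & tabb$FDR < fdrCut])
  }
  out <- list(calls = calls,
              igf1_altered_vs_ctl = list(acute = notBase(postVsCtlAcute),
                                         chronic = notBase(postVsCtlChronic)),
              igf1_altered_within_asd = list(acute = notBase(asdAcute),
                                             chronic = notBase(asdChronic)),
              rule = rule, fdr_cut = fdrCut)
  class(out) <- "RecoveryCalls"
  out
}
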
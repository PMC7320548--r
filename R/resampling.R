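#' Permutation test of transcriptional response magnitude
#'
#' Tests whether the number of genes passing the FDR cutoff under the true
#' treatment labels exceeds what random relabelings produce. Genes are
#' pre-filtered to a total abundance of at least \code{minTotal} across all
#' samples; normalization factors and dispersions are estimated once from the
#' data and held fixed, and only the differential-expression test is re-run
#' per permutation. Labels are reshuffled within patient by default (each
#' patient's arm multiset is preserved); \code{scheme = "global"} shuffles
#' across all samples.
#'
#' @param se a \linkS4class{ResponseExperiment}.
#' @param contrast length-2 character: reference arm then treated arm, e.g.
#'   \code{c("H2O", "acute")}.
#' @param design \code{"additive"} (\code{~ treatment + patient}, default),
#'   \code{"interaction"} (\code{~ treatment * patient} with dispersions from
#'   the additive fit), or \code{"exact"} (two-group exact test, no patient
#'   term).
#' @param scheme \code{"within_patient"} or \code{"global"}.
#' @param nPerm number of permutations (>= 1).
#' @param fdrCut significance cutoff counted per run.
#' @param minTotal total-count filter applied once before testing.
#' @param seed RNG seed for the permutation stream.
#' @param norm,dispersions optional precomputed [tmmFactors()] /
#'   [estimateDispersions()] results for the filtered matrix (estimated
#'   internally when NULL).
#' @return list of class \code{PermutationResult}: \code{observed},
#'   \code{null_counts}, \code{bootstrap_p} (add-one corrected),
#'   \code{raw_fraction}, \code{n_perm}, \code{seed}.
#' @export
permutationTest <- function(se, contrast = c("H2O", "acute"),
                            design = c("additive", "interaction", "exact"),
                            scheme = c("within_patient", "global"),
                            nPerm = 100, fdrCut = 0.05, minTotal = 6,
                            seed = 1, norm = NULL, dispersions = NULL) {
  design <- match.arg(design)
  scheme <- match.arg(scheme)
  if (nPerm < 1) stop("nPerm must be >= 1")
  stopifnot(length(contrast) == 2)
  sel <- treatment(se) %in% contrast
  sub <- se[, sel]
  tr <- factor(treatment(sub), levels = contrast)
  if (nlevels(droplevels(tr)) != 2)
    stop("both contrast arms must be present")
  pat <- factor(patientId(sub))
  counts <- assay(sub, "counts")
  counts <- counts[rowSums(counts) >= minTotal, , drop = FALSE]
  if (!nrow(counts)) stop("no genes pass the total-count filter")
  if (is.null(norm)) norm <- tmmFactors(counts)
  md <- data.frame(treatment = tr, patient = pat)
  disp <- if (is.null(dispersions))
    estimateDispersions(counts, ~ treatment + patient, md, norm = norm)
  else dispersions
  if (scheme == "within_patient") {
    oneArm <- tapply(as.character(tr), pat, function(v) length(unique(v)) == 1)
    if (any(oneArm))
      warning("patient(s) with a single arm keep fixed labels under ",
              "within-patient permutation: ",
              paste(names(oneArm)[oneArm], collapse = ", "))
  }
  countFor <- function(labels) {
    md2 <- data.frame(treatment = labels, patient = pat)
    res <- switch(design,
      additive = nbGlmLRT(counts, ~ treatment + patient, md2,
                          tested = "treatment", norm = norm,
                          dispersions = disp),
      interaction = nbGlmLRT(counts, ~ treatment * patient, md2,
                             tested = "treatment", norm = norm,
                             dispersions = disp, allowSaturated = TRUE),
      exact = nbExactTest(counts, labels, norm = norm, dispersions = disp))
    length(significantGenes(res, fdrCut))
  }
  observed <- countFor(tr)
  set.seed(seed)
  nullCounts <- vapply(seq_len(nPerm), function(i) {
    countFor(.permuteLabels(tr, pat, scheme))
  }, numeric(1))
  k <- sum(nullCounts >= observed)
  out <- list(observed = observed, null_counts = nullCounts,
              bootstrap_p = (1 + k) / (nPerm + 1),
              raw_fraction = k / nPerm, n_perm = nPerm, seed = seed)
  class(out) <- "PermutationResult"
  out
}

# Shuffle treatment labels globally or within each patient (the latter
# preserves every patient's arm multiset by construction).
.permuteLabels <- function(tr, pat, scheme) {
  if (scheme == "global") return(sample(tr))
  out <- tr
  for (p in levels(pat)) {
    ii <- which(pat == p)
    out[ii] <- tr[ii][sample.int(length(ii))]
  }
  out
}

#' Random-forest robustness check of a DE signature
#'
#' Trains a bagged decision-tree ensemble on the signature genes' log
#' expression and reports the out-of-bag error rate, confusion matrix, and
#' AUC computed from out-of-bag vote fractions for the positive (second)
#' class via the rank statistic (ties averaged).
#'
#' @param logtpm signature genes x samples matrix of log2(TPM+1) values.
#' @param labels two-level factor of treatment status per sample
#'   (>= 2 samples per class).
#' @param nTrees number of trees.
#' @param seed RNG seed; results are deterministic given the seed.
#' @return list of class \code{ClassifierReport}: \code{oob_error} (percent),
#'   \code{confusion} (2x2 counts), \code{auc}, \code{n_trees}, \code{seed}.
#' @export
classifyTreatment <- function(logtpm, labels, nTrees = 500, seed = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("need exactly two classes (one class absent?)")
  if (any(table(labels) < 2)) stop("need >= 2 samples per class")
  x <- t(as.matrix(logtpm))
  if (ncol(x) < 1) stop("need at least one feature gene")
  if (nrow(x) != length(labels))
    stop("label length does not match sample count")
  set.seed(seed)
  if (all(apply(x, 2, stats::sd) == 0)) {
    ## no informative split exists: every tree predicts the majority class
    maj <- levels(labels)[which.max(table(labels))]
    pred <- factor(rep(maj, nrow(x)), levels = levels(labels))
    votes <- stats::setNames(rep(0.5, nrow(x)), rownames(x))
  } else {
    rf <- randomForest::randomForest(x, labels, ntree = nTrees)
    pred <- rf$predicted
    votes <- rf$votes[, levels(labels)[2]]
  }
  conf <- table(truth = labels, predicted = pred)
  oob <- 100 * mean(pred != labels)
  pos <- labels == levels(labels)[2]
  r <- rank(votes)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  out <- list(oob_error = oob, confusion = conf, auc = auc,
              n_trees = nTrees, seed = seed)
  class(out) <- "ClassifierReport"
  out
}
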
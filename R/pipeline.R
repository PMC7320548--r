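#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of the end-to-end analysis.
#' Either \code{inputDir} points at a fixture directory readable by
#' [readResponseExperiment()], or a \code{simulate} block provides a
#' [simulationConfig()] to generate the data in place. Defaults mirror the
#' analysis parameters used throughout: FDR 0.05, 100 permutations, minimum
#' module size 10, scale-free target 0.9.
#'
#' @param inputDir optional directory with counts/tpm/metadata TSVs.
#' @param simulate a [simulationConfig()] (used when \code{inputDir} is NULL).
#' @param fdrCut FDR cutoff used by every stage.
#' @param nPerm permutations for the magnitude test.
#' @param scheme permutation scheme (see [permutationTest()]).
#' @param nTrees random-forest ensemble size.
#' @param minModuleSize,r2Target,cutHeight co-expression parameters.
#' @param recoveryRule recovery rule (see [classifyRecovery()]).
#' @param logGeneCountThreshold,pcaSdK QC parameters (see
#'   [excludeOutliers()]).
#' @param seed master seed propagated to all stochastic stages.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(inputDir = NULL, simulate = simulationConfig(),
                           fdrCut = 0.05, nPerm = 100,
                           scheme = "within_patient", nTrees = 500,
                           minModuleSize = 10, r2Target = 0.9,
                           cutHeight = 0.99, recoveryRule = "strict",
                           logGeneCountThreshold = 6, pcaSdK = 3, seed = 1L) {
  if (!is.null(inputDir) && !dir.exists(inputDir))
    stop("inputDir does not exist: ", inputDir)
  cfg <- list(inputDir = inputDir, simulate = simulate, fdrCut = fdrCut,
              nPerm = as.integer(nPerm), scheme = scheme,
              nTrees = as.integer(nTrees),
              minModuleSize = as.integer(minModuleSize),
              r2Target = r2Target, cutHeight = cutHeight,
              recoveryRule = recoveryRule,
              logGeneCountThreshold = logGeneCountThreshold,
              pcaSdK = pcaSdK, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys map onto [pipelineConfig()] arguments; a nested
#' \code{simulate:} section maps onto [simulationConfig()] arguments.
#'
#' @param path YAML file.
#' @return list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulationConfig, as.list(y$simulate))
  y$simulate <- NULL
  do.call(pipelineConfig, c(y, list(simulate = sim)))
}

.logStage <- function(stage, seed, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  message(sprintf("[igfresponse] stage=%s elapsed=%.2fs seed=%d",
                  stage, proc.time()[["elapsed"]] - t0, seed))
  res
}

#' Run the full analysis pipeline
#'
#' Executes QC, the five differential-expression contrasts (control and ASD
#' acute/chronic vs vehicle, and ASD vs CTL at baseline, plus the treated-ASD
#' vs control contrasts used by the recovery stage), overlap and temporal
#' signature statistics, the permutation magnitude test and random-forest
#' robustness check, supervised co-expression modules with the disease x
#' treatment eigengene model, the control-signature PC projection with
#' per-patient response shifts and covariate associations, and the recovery
#' classification. Writes per-stage TSV/JSON outputs plus a consolidated
#' \code{report.json} (validated against the bundled schema) into
#' \code{outputDir}.
#'
#' @param config a [pipelineConfig()].
#' @param outputDir output directory (created if needed); NULL skips writing.
#' @return The report, invisibly a list with one block per stage.
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  seed <- config$seed
  fdr <- config$fdrCut

  dat <- .logStage("data", seed, {
    if (!is.null(config$inputDir)) {
      list(experiment = readResponseExperiment(config$inputDir), truth = NULL)
    } else {
      sim <- config$simulate
      sim$seed <- seed
      simulateDataset(sim)
    }
  })
  se <- dat$experiment

  qc <- .logStage("qc", seed,
                  excludeOutliers(se, config$logGeneCountThreshold,
                                  config$pcaSdK))
  se <- logNormalize(qc$experiment)
  counts <- filterExpressed(assay(se, "counts"))
  lt <- .logtpmOf(se)[rownames(counts), , drop = FALSE]
  md <- as.data.frame(colData(se))

  subDE <- function(diagSel, arms) {
    sel <- diagnosis(se) %in% diagSel & treatment(se) %in% arms
    cs <- counts[, sel, drop = FALSE]
    mdd <- data.frame(treatment = factor(treatment(se)[sel], levels = arms),
                      patient = factor(patientId(se)[sel]))
    nbGlmLRT(cs, ~ treatment + patient, mdd, tested = "treatment")
  }
  crossDE <- function(arm) {
    sel <- (diagnosis(se) == "CTL" & treatment(se) == "H2O") |
      (diagnosis(se) == "ASD" & treatment(se) == arm)
    cs <- counts[, sel, drop = FALSE]
    grp <- factor(ifelse(diagnosis(se)[sel] == "CTL", "CTL_H2O",
                         paste0("ASD_", arm)),
                  levels = c("CTL_H2O", paste0("ASD_", arm)))
    nbExactTest(cs, grp)
  }
  de <- .logStage("de", seed, {
    list(ctl_acute = subDE("CTL", c("H2O", "acute")),
         ctl_chronic = subDE("CTL", c("H2O", "chronic")),
         asd_acute = subDE("ASD", c("H2O", "acute")),
         asd_chronic = subDE("ASD", c("H2O", "chronic")),
         baseline = {
           sel <- treatment(se) == "H2O"
           nbExactTest(counts[, sel, drop = FALSE],
                       factor(diagnosis(se)[sel],
                              levels = .DIAGNOSIS_LEVELS))
         },
         post_vs_ctl_acute = crossDE("acute"),
         post_vs_ctl_chronic = crossDE("chronic"))
  })

  sig <- .logStage("signature", seed, {
    grpCTL <- temporalGrouping(de$ctl_acute, de$ctl_chronic, fdr)
    grpASD <- temporalGrouping(de$asd_acute, de$asd_chronic, fdr)
    ov <- overlapFisher(significantGenes(de$ctl_acute, fdr),
                        significantGenes(de$ctl_chronic, fdr),
                        nrow(counts))
    tabs <- rbind(CTL = table(factor(grpCTL$group,
                                     c("shared", "acute_only",
                                       "chronic_only"))),
                  ASD = table(factor(grpASD$group,
                                     c("shared", "acute_only",
                                       "chronic_only"))))
    chi <- if (any(rowSums(tabs) == 0) || any(colSums(tabs) == 0))
      NULL else categoryChisq(tabs)
    ctlMd <- md[md$diagnosis == "CTL", ]
    traj <- lapply(split(grpCTL, grpCTL$group), function(d) {
      up <- d$gene[d$direction == "up"]
      dn <- d$gene[d$direction == "down"]
      lapply(Filter(length, list(up = up, down = dn)), function(gs)
        trajectoryTest(lt[, md$diagnosis == "CTL", drop = FALSE],
                       ctlMd, gs)$tests)
    })
    list(temporal_ctl = grpCTL, temporal_asd = grpASD, overlap = ov,
         category_table = tabs, chisq = chi, trajectories = traj)
  })

  resamp <- .logStage("resampling", seed, {
    lapply(list(ctl_acute = list("CTL", "acute"),
                ctl_chronic = list("CTL", "chronic"),
                asd_acute = list("ASD", "acute"),
                asd_chronic = list("ASD", "chronic")), function(armSpec) {
      sub <- se[, diagnosis(se) == armSpec[[1]] &
                  treatment(se) %in% c("H2O", armSpec[[2]])]
      perm <- permutationTest(sub, contrast = c("H2O", armSpec[[2]]),
                              scheme = config$scheme, nPerm = config$nPerm,
                              fdrCut = fdr, seed = seed)
      key <- paste0(tolower(armSpec[[1]]), "_", armSpec[[2]])
      hits <- significantGenes(de[[key]], fdr)
      cls <- if (length(hits) >= 1)
        classifyTreatment(.logtpmOf(sub)[hits, , drop = FALSE],
                          factor(treatment(sub),
                                 levels = c("H2O", armSpec[[2]])),
                          nTrees = config$nTrees, seed = seed)
      else NULL
      list(permutation = perm, classifier = cls)
    })
  })

  coex <- .logStage("coexpression", seed, {
    genes <- union(significantGenes(de$ctl_acute, fdr),
                   significantGenes(de$asd_acute, fdr))
    sel <- treatment(se) %in% c("H2O", "acute")
    if (length(genes) >= max(3, config$minModuleSize)) {
      sub <- lt[genes, sel, drop = FALSE]
      np <- suppressWarnings(pickSoftPower(sub, config$r2Target))
      tom <- tomSimilarity(adjacencyMatrix(sub, np$power))
      mods <- detectModules(tom, config$minModuleSize, config$cutHeight)
      eg <- moduleEigengenes(sub, mods)
      fitTab <- eigengeneModel(eg$eigengenes, md[sel, ])
      list(params = np, modules = mods, eigengenes = eg, model = fitTab)
    } else {
      list(params = NULL, modules = NULL, eigengenes = NULL, model = NULL,
           note = "too few DE genes for network construction")
    }
  })

  proj <- .logStage("projection", seed, {
    sigGenes <- significantGenes(de$ctl_acute, fdr)
    note <- NULL
    if (length(sigGenes) < 2) {
      tab <- deTable(de$ctl_acute)
      sigGenes <- utils::head(tab$gene[order(tab$PValue)], 50)
      note <- "fewer than 2 significant signature genes; top-50 by p used"
    }
    space <- suppressWarnings(fitPCSpace(lt, md, sigGenes))
    sel <- treatment(se) %in% c("H2O", "acute")
    scores <- projectSamples(lt[, sel, drop = FALSE], space)
    shifts <- patientShift(scores, md)
    sh <- patientShifts(shifts)
    ok <- sh$complete
    act <- md$activity[match(sh$patient_id, md$patient_id)]
    assocActivity <- if (sum(ok) >= 3 && !is.null(act))
      covariateAssociation(sh$delta_pc1[ok], act[ok], "activity") else NULL
    recGene <- if (!is.null(dat$truth)) dat$truth$receptor_gene else NULL
    assocReceptor <- NULL
    if (!is.null(recGene) && recGene %in% rownames(lt)) {
      perPatient <- function(arm) {
        v <- .logtpmOf(se)[recGene, treatment(se) == arm]
        tapply(v, patientId(se)[treatment(se) == arm], mean)[sh$patient_id]
      }
      assocReceptor <- list(
        post = covariateAssociation(sh$delta_pc1[ok],
                                    perPatient("acute")[ok],
                                    "receptor_post"),
        pre = covariateAssociation(sh$delta_pc1[ok],
                                   perPatient("H2O")[ok],
                                   "receptor_pre"))
    }
    list(space = space, result = shifts, association = assocActivity,
         receptor = assocReceptor, note = note)
  })

  recov <- .logStage("recovery", seed,
    classifyRecovery(de$baseline, de$asd_acute, de$asd_chronic,
                     de$post_vs_ctl_acute, de$post_vs_ctl_chronic,
                     fdrCut = fdr, rule = config$recoveryRule))

  report <- .buildReport(config, dat, qc, de, sig, resamp, coex, proj, recov,
                         nGenes = nrow(counts))
  .validateReport(report)
  if (!is.null(outputDir))
    .writeOutputs(outputDir, de, sig, coex, proj, recov, report)
  invisible(list(report = report, experiment = se, de = de, signature = sig,
                 resampling = resamp, coexpression = coex, projection = proj,
                 recovery = recov, qc = qc, truth = dat$truth))
}

.buildReport <- function(config, dat, qc, de, sig, resamp, coex, proj, recov,
                         nGenes) {
  fdr <- config$fdrCut
  sh <- patientShifts(proj$result)
  list(
    simulate = list(simulated = is.null(config$inputDir),
                    seed = config$seed,
                    n_samples = ncol(dat$experiment),
                    n_genes = nrow(dat$experiment)),
    qc = list(n_excluded = nrow(qc$report$excluded),
              excluded = qc$report$excluded),
    de = lapply(de, function(r)
      list(contrast = r@contrast, n_tested = nrow(deTable(r)),
           n_significant = length(significantGenes(r, fdr)))),
    signature = list(
      overlap = sig$overlap[c("both", "only_a", "only_b", "neither",
                              "odds_ratio", "p_value")],
      chisq = if (is.null(sig$chisq)) NULL else
        sig$chisq[c("statistic", "df", "p_value")],
      temporal_counts_ctl = as.list(table(sig$temporal_ctl$group)),
      temporal_counts_asd = as.list(table(sig$temporal_asd$group))),
    resampling = lapply(resamp, function(r)
      list(observed = r$permutation$observed,
           bootstrap_p = r$permutation$bootstrap_p,
           raw_fraction = r$permutation$raw_fraction,
           oob_error = if (is.null(r$classifier)) NULL else
             r$classifier$oob_error,
           auc = if (is.null(r$classifier)) NULL else r$classifier$auc)),
    coexpression = if (is.null(coex$modules))
      list(note = coex$note) else
      list(power = coex$params$power,
           scale_free_r2 = coex$params$scale_free_r2,
           module_sizes = as.list(coex$modules$sizes),
           interaction_p = stats::setNames(
             as.list(coex$model$p_interaction), coex$model$module)),
    projection = list(
      n_signature_genes = length(proj$space@genes),
      responders = sh$patient_id[sh$complete & sh$responder],
      shifts = sh,
      activity_association = if (is.null(proj$association)) NULL else
        proj$association[c("slope", "F", "p", "n")],
      receptor_post_p = if (is.null(proj$receptor)) NULL else
        proj$receptor$post$p,
      receptor_pre_p = if (is.null(proj$receptor)) NULL else
        proj$receptor$pre$p,
      note = proj$note),
    recovery = list(
      n_baseline_de = nrow(recov$calls),
      combined_counts = as.list(table(recov$calls$combined)),
      n_igf1_altered_vs_ctl = lapply(recov$igf1_altered_vs_ctl, length)),
    config = list(fdr_cut = fdr, n_perm = config$nPerm,
                  scheme = config$scheme, seed = config$seed,
                  n_genes_tested = nGenes))
}

# Presence check of the report against the bundled schema (required keys).
.validateReport <- function(report) {
  schemaPath <- system.file("extdata", "report_schema.json",
                            package = "igfresponse")
  schema <- jsonlite::read_json(schemaPath)
  missTop <- setdiff(unlist(schema$required), names(report))
  if (length(missTop))
    stop("report missing block(s): ", paste(missTop, collapse = ", "))
  for (blk in names(schema$blocks)) {
    need <- unlist(schema$blocks[[blk]])
    have <- names(report[[blk]])
    miss <- setdiff(need, have)
    if (length(miss))
      stop("report block '", blk, "' missing field(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

.writeOutputs <- function(outputDir, de, sig, coex, proj, recov, report) {
  if (!dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  for (nm in names(de))
    utils::write.table(deTable(de[[nm]]),
                       file.path(outputDir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sig$temporal_ctl,
                     file.path(outputDir, "temporal_groups_ctl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coex$modules)) {
    utils::write.table(
      data.frame(gene = names(coex$modules$labels),
                 module = coex$modules$labels),
      file.path(outputDir, "module_membership.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(coex$eigengenes$eigengenes),
                 coex$eigengenes$eigengenes, check.names = FALSE),
      file.path(outputDir, "module_eigengenes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sampleScores(proj$result),
                     file.path(outputDir, "projection_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(patientShifts(proj$result),
                     file.path(outputDir, "patient_shifts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(recov$calls,
                     file.path(outputDir, "recovery_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(outputDir)
}
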
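#' Simulation configuration for the paired IGF-1 treatment design
#'
#' Builds and validates the parameter set of the synthetic-data generator. The
#' defaults emulate the study design the pipeline targets: 7 control and 8 ASD
#' patients, two replicate neuronal preparations each, and three treatment arms
#' (vehicle water, acute 48-h IGF-1, chronic 28-day IGF-1), i.e. 90 samples.
#'
#' Gene classes: a fraction of genes respond to treatment (\code{shared}
#' in both arms, \code{acute_only}, \code{chronic_only}), a fraction are
#' differentially expressed between ASD and CTL at baseline
#' (\code{baseline_de}), and a sub-fraction of those are recovered toward the
#' control state by treatment in ASD (\code{baseline_de_recoverable}).
#' Acute-dominant genes retain 25% of their effect in the chronic arm and vice
#' versa, so "acute-only" signatures still drift at the chronic timepoint.
#'
#' Per-patient response heterogeneity: controls have response scale
#' \code{r = 1}; ASD responders (a configured fraction, default 5/8) draw
#' \code{r ~ U(0.3, 1)} and non-responders \code{r ~ U(-0.5, 0)}, producing
#' the positive-but-reduced responder / negative non-responder split. The
#' designated receptor gene's acute-arm mean is multiplied by
#' \code{2^(r * effect_logfc)} so post-treatment receptor level tracks the
#' response, and a per-patient activity covariate is generated as
#' \code{activity_slope * r + N(0, activity_noise_sd)}.
#'
#' @param n_ctl_patients,n_asd_patients,n_replicates cohort sizes.
#' @param n_genes number of simulated genes.
#' @param baseline_log_mean_range log2 range of per-gene baseline mean
#'   abundance (at unit library scale).
#' @param dispersion_mean,dispersion_shape mean and gamma shape of the per-gene
#'   NB dispersion phi (Var = mu + phi mu^2).
#' @param library_size_range bounds of the per-sample expected total count.
#' @param frac_shared,frac_acute_only,frac_chronic_only,frac_baseline_de
#'   gene-class proportions (must sum to at most 1; the remainder is null).
#' @param frac_recoverable fraction of baseline-DE genes that treatment
#'   recovers in ASD.
#' @param effect_logfc treatment effect size, log2.
#' @param baseline_logfc disease (ASD vs CTL) effect size, log2.
#' @param patient_sd SD of the per-patient log2 random effect.
#' @param responder_fraction fraction of ASD patients with positive response.
#' @param receptor_gene_index row index of the designated receptor gene.
#' @param activity_slope,activity_noise_sd generative link from response scale
#'   to the activity covariate.
#' @param seed integer seed; identical seeds give identical datasets.
#'
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_ctl_patients = 7L,
                             n_asd_patients = 8L,
                             n_replicates = 2L,
                             n_genes = 5000L,
                             baseline_log_mean_range = c(3, 9),
                             dispersion_mean = 0.1,
                             dispersion_shape = 2,
                             library_size_range = c(8e5, 1.2e6),
                             frac_shared = 0.02,
                             frac_acute_only = 0.03,
                             frac_chronic_only = 0.03,
                             frac_baseline_de = 0.05,
                             frac_recoverable = 0.5,
                             effect_logfc = 1.0,
                             baseline_logfc = 1.0,
                             patient_sd = 0.3,
                             responder_fraction = 5 / 8,
                             receptor_gene_index = 1L,
                             activity_slope = 1.0,
                             activity_noise_sd = 0.25,
                             seed = 1L) {
  cfg <- list(n_ctl_patients = as.integer(n_ctl_patients),
              n_asd_patients = as.integer(n_asd_patients),
              n_replicates = as.integer(n_replicates),
              n_genes = as.integer(n_genes),
              baseline_log_mean_range = as.numeric(baseline_log_mean_range),
              dispersion_mean = dispersion_mean,
              dispersion_shape = dispersion_shape,
              library_size_range = as.numeric(library_size_range),
              frac_shared = frac_shared,
              frac_acute_only = frac_acute_only,
              frac_chronic_only = frac_chronic_only,
              frac_baseline_de = frac_baseline_de,
              frac_recoverable = frac_recoverable,
              effect_logfc = effect_logfc,
              baseline_logfc = baseline_logfc,
              patient_sd = patient_sd,
              responder_fraction = responder_fraction,
              receptor_gene_index = as.integer(receptor_gene_index),
              activity_slope = activity_slope,
              activity_noise_sd = activity_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  cnt <- c("n_ctl_patients", "n_asd_patients", "n_replicates", "n_genes")
  for (f in cnt)
    if (cfg[[f]] < 1L)
      stop("configuration error: '", f, "' must be >= 1")
  props <- c("frac_shared", "frac_acute_only", "frac_chronic_only",
             "frac_baseline_de", "frac_recoverable", "responder_fraction")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: '", f, "' must be in [0, 1]")
  cls <- cfg$frac_shared + cfg$frac_acute_only + cfg$frac_chronic_only +
    cfg$frac_baseline_de
  if (cls > 1)
    stop("configuration error: gene-class proportions ",
         "'frac_shared' + 'frac_acute_only' + 'frac_chronic_only' + ",
         "'frac_baseline_de' exceed 1")
  if (cfg$dispersion_mean <= 0 || cfg$dispersion_shape <= 0)
    stop("configuration error: 'dispersion_mean' and 'dispersion_shape' must be > 0")
  if (any(cfg$library_size_range <= 0))
    stop("configuration error: 'library_size_range' must be positive")
  if (diff(cfg$baseline_log_mean_range) < 0)
    stop("configuration error: 'baseline_log_mean_range' must be increasing")
  if (cfg$receptor_gene_index < 1L || cfg$receptor_gene_index > cfg$n_genes)
    stop("configuration error: 'receptor_gene_index' outside 1..n_genes")
  if (cfg$patient_sd < 0 || cfg$activity_noise_sd < 0)
    stop("configuration error: SDs must be non-negative")
  invisible(cfg)
}

# Fractional treatment multiplier per gene class and arm. Acute-dominant genes
# retain 25% of the effect chronically, chronic-dominant genes show 25% acutely.
.treatmentIndicator <- function(gene_class, arm) {
  acute <- c(null = 0, shared = 1, acute_only = 1, chronic_only = 0.25,
             baseline_de = 0, baseline_de_recoverable = 0)
  chronic <- c(null = 0, shared = 1, acute_only = 0.25, chronic_only = 1,
               baseline_de = 0, baseline_de_recoverable = 0)
  switch(arm, H2O = rep(0, length(gene_class)),
         acute = unname(acute[gene_class]),
         chronic = unname(chronic[gene_class]))
}

#' Simulate a paired-design treatment-response dataset with known truth
#'
#' Draws NB(mu, phi) counts with
#' \code{log2 mu = baseline + patient effect + disease effect + direction *
#' effect_logfc * r_patient * treatment indicator + log2(library scale)},
#' builds the TPM view (counts rescaled to 1e6 per sample; unit gene-length
#' convention), and returns the ground-truth gene classes and per-patient
#' response scales. A single RNG stream seeded from \code{config$seed} is
#' consumed in a fixed, documented order (gene parameters, then patient
#' effects and response scales, then library sizes, then counts, then
#' covariates), so identical seeds give identical datasets.
#'
#' @param config a [simulationConfig()].
#' @return A list with elements \code{experiment}
#'   (\linkS4class{ResponseExperiment} with assays counts and tpm) and
#'   \code{truth} (class \code{SimulatedTruth}: \code{gene_class},
#'   \code{gene_direction}, \code{response_scale}, \code{responder_flag},
#'   \code{activity}, \code{receptor_gene}).
#' @export
simulateDataset <- function(config = simulationConfig()) {
  validateSimulationConfig(config)
  cfg <- config
  set.seed(cfg$seed)
  G <- cfg$n_genes
  genes <- sprintf("gene_%05d", seq_len(G))

  ## 1. gene-level parameters
  baseline <- stats::runif(G, cfg$baseline_log_mean_range[1],
                           cfg$baseline_log_mean_range[2])
  phi <- stats::rgamma(G, shape = cfg$dispersion_shape,
                       rate = cfg$dispersion_shape / cfg$dispersion_mean)
  phi <- pmax(phi, 1e-6)
  n_shared <- floor(cfg$frac_shared * G)
  n_acute <- floor(cfg$frac_acute_only * G)
  n_chronic <- floor(cfg$frac_chronic_only * G)
  n_base <- floor(cfg$frac_baseline_de * G)
  n_recov <- floor(cfg$frac_recoverable * n_base)
  gene_class <- rep("null", G)
  pick <- sample.int(G, n_shared + n_acute + n_chronic + n_base)
  gene_class[pick] <- rep(c("shared", "acute_only", "chronic_only",
                            "baseline_de_recoverable", "baseline_de"),
                          c(n_shared, n_acute, n_chronic, n_recov,
                            n_base - n_recov))
  gene_direction <- sample(c(1, -1), G, replace = TRUE)

  ## 2. patient-level parameters
  patients <- c(sprintf("CTL_%02d", seq_len(cfg$n_ctl_patients)),
                sprintf("ASD_%02d", seq_len(cfg$n_asd_patients)))
  diag_p <- rep(c("CTL", "ASD"), c(cfg$n_ctl_patients, cfg$n_asd_patients))
  patient_effect <- stats::rnorm(length(patients), 0, cfg$patient_sd)
  n_resp <- round(cfg$responder_fraction * cfg$n_asd_patients)
  asd_idx <- which(diag_p == "ASD")
  resp_idx <- sample(asd_idx, n_resp)
  r <- rep(1, length(patients))
  r[asd_idx] <- stats::runif(cfg$n_asd_patients, -0.5, 0)
  r[resp_idx] <- stats::runif(n_resp, 0.3, 1)

  ## 3. library sizes
  arms <- .TREATMENT_LEVELS
  n_samples <- length(patients) * cfg$n_replicates * length(arms)
  lib_target <- stats::runif(n_samples, cfg$library_size_range[1],
                             cfg$library_size_range[2])

  ## sample sheet (deterministic order: patient x arm x replicate)
  md <- expand.grid(replicate = seq_len(cfg$n_replicates), treatment = arms,
                    patient_id = patients, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  md <- md[, c("patient_id", "treatment", "replicate")]
  md$diagnosis <- diag_p[match(md$patient_id, patients)]
  md$sample_id <- sprintf("%s_%s_r%d", md$patient_id, md$treatment,
                          md$replicate)

  ## 4. counts
  counts <- matrix(0L, nrow = G, ncol = n_samples,
                   dimnames = list(genes, md$sample_id))
  is_base_class <- gene_class %in% c("baseline_de", "baseline_de_recoverable")
  ind_arm <- lapply(arms, function(a) .treatmentIndicator(gene_class, a))
  names(ind_arm) <- arms
  for (s in seq_len(n_samples)) {
    p <- match(md$patient_id[s], patients)
    arm <- md$treatment[s]
    lmu <- baseline + patient_effect[p]
    if (md$diagnosis[s] == "ASD") {
      lmu <- lmu + ifelse(is_base_class,
                          gene_direction * cfg$baseline_logfc, 0)
      if (arm != "H2O") {
        recov <- gene_class == "baseline_de_recoverable"
        lmu[recov] <- lmu[recov] -
          gene_direction[recov] * cfg$baseline_logfc
      }
    }
    lmu <- lmu + gene_direction * cfg$effect_logfc * r[p] * ind_arm[[arm]]
    mu <- 2 ^ lmu
    if (arm == "acute") {
      i <- cfg$receptor_gene_index
      mu[i] <- mu[i] * 2 ^ (r[p] * cfg$effect_logfc)
    }
    mu <- mu * (lib_target[s] / sum(mu))
    counts[, s] <- stats::rnbinom(G, mu = mu, size = 1 / phi)
  }

  ## 5. covariates
  activity <- cfg$activity_slope * r +
    stats::rnorm(length(patients), 0, cfg$activity_noise_sd)
  md$activity <- activity[match(md$patient_id, patients)]

  tot <- colSums(counts)
  tot[tot == 0] <- 1
  tpm <- sweep(counts, 2, tot, "/") * 1e6
  se <- ResponseExperiment(counts,
                           md[, c("sample_id", "patient_id", "diagnosis",
                                  "treatment", "replicate", "activity")],
                           tpm = tpm)
  truth <- list(gene_class = stats::setNames(gene_class, genes),
                gene_direction = stats::setNames(gene_direction, genes),
                response_scale = stats::setNames(r, patients),
                responder_flag = stats::setNames(r > 0, patients),
                activity = stats::setNames(activity, patients),
                receptor_gene = genes[cfg$receptor_gene_index],
                dispersion = stats::setNames(phi, genes))
  class(truth) <- "SimulatedTruth"
  list(experiment = se, truth = truth)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Writes \code{counts.tsv}, \code{tpm.tsv}, \code{metadata.tsv} and
#' \code{truth.json} into \code{directory}; the tables round-trip losslessly
#' through [readAbundance()] / [readMetadata()].
#'
#' @param dataset result of [simulateDataset()].
#' @param directory output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
writeFixture <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  se <- dataset$experiment
  paths <- c(counts = file.path(directory, "counts.tsv"),
             tpm = file.path(directory, "tpm.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             truth = file.path(directory, "truth.json"))
  .writeMatrixTsv(assay(se, "counts"), paths["counts"])
  .writeMatrixTsv(assay(se, "tpm"), paths["tpm"])
  md <- as.data.frame(colData(se))
  utils::write.table(md, paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- dataset$truth
  jsonlite::write_json(
    list(gene_class = as.list(tr$gene_class),
         gene_direction = as.list(tr$gene_direction),
         response_scale = as.list(tr$response_scale),
         responder_flag = as.list(tr$responder_flag),
         activity = as.list(tr$activity),
         receptor_gene = tr$receptor_gene),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.writeMatrixTsv <- function(m, path) {
  gid <- rownames(m)
  if (is.null(gid)) gid <- character(nrow(m))
  df <- data.frame(gene_id = gid, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
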
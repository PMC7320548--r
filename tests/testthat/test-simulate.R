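test_that("default design yields the full paired cohort and is deterministic", {
  d1 <- simulateDataset(simulationConfig(n_genes = 200, seed = 3))
  md <- as.data.frame(colData(d1$experiment))
  expect_equal(nrow(md), (7 + 8) * 2 * 3)
  expect_equal(sort(unique(md$treatment)), sort(c("H2O", "acute", "chronic")))
  arms_per_patient <- tapply(md$treatment, md$patient_id,
                             function(x) length(unique(x)))
  expect_true(all(arms_per_patient == 3))
  expect_equal(sum(md$diagnosis == "CTL"), 7 * 2 * 3)

  d2 <- simulateDataset(simulationConfig(n_genes = 200, seed = 3))
  expect_identical(assay(d1$experiment, "counts"), assay(d2$experiment, "counts"))
  expect_identical(d1$truth$response_scale, d2$truth$response_scale)
  d3 <- simulateDataset(simulationConfig(n_genes = 200, seed = 4))
  expect_false(identical(assay(d1$experiment, "counts"),
                         assay(d3$experiment, "counts")))
})

test_that("gene classes, directions and responder flags follow the config", {
  cfg <- tinyConfig(frac_shared = 0.05, frac_acute_only = 0.1,
                    frac_chronic_only = 0.025, frac_baseline_de = 0.1,
                    frac_recoverable = 0.5)
  d <- simulateDataset(cfg)
  cls <- table(d$truth$gene_class)
  expect_equal(unname(cls["shared"]), floor(0.05 * 400))
  expect_equal(unname(cls["acute_only"]), floor(0.1 * 400))
  expect_equal(unname(cls["chronic_only"]), floor(0.025 * 400))
  nBase <- floor(0.1 * 400)
  expect_equal(unname(cls["baseline_de_recoverable"]), floor(0.5 * nBase))
  expect_equal(unname(cls["baseline_de"]), nBase - floor(0.5 * nBase))
  expect_true(all(d$truth$gene_direction %in% c(-1, 1)))
  r <- d$truth$response_scale
  expect_true(all(r[grepl("CTL", names(r))] == 1))
  expect_equal(sum(d$truth$responder_flag[grepl("ASD", names(r))]),
               round(5 / 8 * 3))
  expect_identical(d$truth$responder_flag, r > 0)
})

test_that("a configuration with zero effect fractions is a pure null", {
  cfg <- tinyConfig(frac_shared = 0, frac_acute_only = 0,
                    frac_chronic_only = 0, frac_baseline_de = 0,
                    patient_sd = 0)
  d <- simulateDataset(cfg)
  expect_true(all(d$truth$gene_class == "null"))
  lt <- log2(assay(d$experiment, "tpm") + 1)
  tr <- treatment(d$experiment)
  gap <- abs(rowMeans(lt[, tr == "acute"]) - rowMeans(lt[, tr == "H2O"]))
  expect_lt(stats::quantile(gap, 0.99), 0.75)  # sampling noise only
})

test_that("planted acute effects reproduce the analytic NB mean ratio", {
  # one patient per cohort, many replicates; shared genes at r = 1 and
  # effect_logfc = 1 have an acute/H2O mean ratio of 2 (analytic NB mean)
  cfg <- simulationConfig(n_ctl_patients = 1, n_asd_patients = 1,
                          n_replicates = 150, n_genes = 300,
                          frac_shared = 0.1, frac_acute_only = 0,
                          frac_chronic_only = 0, frac_baseline_de = 0,
                          effect_logfc = 1, patient_sd = 0,
                          dispersion_mean = 0.05,
                          library_size_range = c(1e5, 1e5), seed = 8)
  d <- simulateDataset(cfg)
  se <- d$experiment
  ctl <- diagnosis(se) == "CTL"
  shared <- names(d$truth$gene_class)[d$truth$gene_class == "shared"]
  up <- shared[d$truth$gene_direction[shared] > 0]
  cnt <- assay(se, "counts")
  ratio <- rowMeans(cnt[up, ctl & treatment(se) == "acute"]) /
    rowMeans(cnt[up, ctl & treatment(se) == "H2O"])
  # library renormalization slightly dilutes the planted factor of 2
  expect_true(all(abs(ratio - 2) < 0.35))
  expect_gt(mean(ratio), 1.7)
})

test_that("counts obey the NB mean-variance law", {
  cfg <- simulationConfig(n_ctl_patients = 1, n_asd_patients = 1,
                          n_replicates = 250, n_genes = 150,
                          frac_shared = 0, frac_acute_only = 0,
                          frac_chronic_only = 0, frac_baseline_de = 0,
                          patient_sd = 0, dispersion_mean = 0.2,
                          library_size_range = c(5e4, 5e4), seed = 9)
  d <- simulateDataset(cfg)
  se <- d$experiment
  sel <- diagnosis(se) == "CTL" & treatment(se) == "H2O"
  cnt <- assay(se, "counts")[, sel]
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1, stats::var)
  phi <- d$truth$dispersion
  expected <- mu + phi * mu ^ 2
  expect_lt(abs(stats::median(v / expected) - 1), 0.2)
  # and clearly super-Poissonian
  expect_gt(stats::median(v / mu), 2)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(simulationConfig(n_genes = 0), "n_genes")
  expect_error(simulationConfig(frac_shared = 1.2), "frac_shared")
  expect_error(simulationConfig(frac_shared = 0.5, frac_acute_only = 0.3,
                                frac_chronic_only = 0.2,
                                frac_baseline_de = 0.1), "exceed 1")
  expect_error(simulationConfig(library_size_range = c(-1, 10)),
               "library_size_range")
  expect_error(simulationConfig(dispersion_mean = 0), "dispersion_mean")
  expect_error(simulationConfig(receptor_gene_index = 10000),
               "receptor_gene_index")
})

test_that("fixtures round-trip losslessly through the readers", {
  d <- simulateDataset(tinyConfig(n_genes = 60))
  dir <- withr::local_tempdir()
  paths <- writeFixture(d, dir)
  expect_true(all(file.exists(paths)))
  se2 <- readResponseExperiment(dir)
  expect_equal(assay(se2, "counts"), assay(d$experiment, "counts"))
  expect_equal(assay(se2, "tpm"), assay(d$experiment, "tpm"),
               tolerance = 1e-12)
  expect_identical(colnames(se2), colnames(d$experiment))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(sum(unlist(truth$responder_flag[grepl("ASD",
                                                     names(truth$responder_flag))])),
               round(5 / 8 * 3))

  # degenerate: zero genes still writes valid headers-only tables
  d0 <- list(experiment = d$experiment[0, ], truth = d$truth)
  dir0 <- withr::local_tempdir()
  writeFixture(d0, dir0)
  m0 <- readAbundance(file.path(dir0, "counts.tsv"), "counts")
  expect_equal(nrow(m0), 0)
  expect_equal(ncol(m0), ncol(d$experiment))
})
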
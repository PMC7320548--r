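suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# Small cohort used by most unit tests: 3 + 3 patients, 400 genes, modest
# library sizes so count totals stay small.
tinyConfig <- function(...) {
  args <- list(n_ctl_patients = 3L, n_asd_patients = 3L, n_genes = 400L,
               library_size_range = c(4e4, 6e4), seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

# Null NB count matrix with gene/sample names.
nullCounts <- function(G, S, mu = 150, phi = 0.1, seed = 1) {
  set.seed(seed)
  m <- if (length(mu) == 1) rep(mu, G) else mu
  matrix(stats::rnbinom(G * S, mu = rep(m, S), size = 1 / phi), G, S,
         dimnames = list(sprintf("g%04d", seq_len(G)),
                         sprintf("s%02d", seq_len(S))))
}

# Paired two-arm metadata: nPat patients, nRep replicates per arm.
pairedMeta <- function(nPat = 6, nRep = 1, arms = c("H2O", "acute")) {
  md <- expand.grid(replicate = seq_len(nRep), treatment = arms,
                    patient = sprintf("p%02d", seq_len(nPat)),
                    stringsAsFactors = FALSE)
  data.frame(treatment = factor(md$treatment, levels = arms),
             patient = factor(md$patient))
}

# Build a DEResult by hand for rule-based tests.
makeDEResult <- function(genes, logFC, pvalue, contrast = "test",
                         test = "exact") {
  new("DEResult",
      table = S4Vectors::DataFrame(gene = genes, logFC = logFC,
                                   logCPM = rep(5, length(genes)),
                                   PValue = pvalue,
                                   FDR = adjustFdr(pvalue)),
      contrast = contrast, test = test)
}

# Hub-structured expression: graded loadings on one latent factor give a
# heavy-tailed connectivity distribution (scale-free-like topology).
hubStructure <- function(G = 300, S = 40, seed = 5) {
  set.seed(seed)
  f <- stats::rnorm(S)
  w <- stats::runif(G) ^ 2
  x <- w %o% f + matrix(stats::rnorm(G * S), G, S)
  dimnames(x) <- list(paste0("g", seq_len(G)), paste0("s", seq_len(S)))
  x
}

# Expression matrix with two planted correlated gene blocks (plus noise
# genes), used by the co-expression tests.
plantedBlocks <- function(nBlock = 20, nNoise = 0, S = 30, rho = 0.9,
                          seed = 5) {
  set.seed(seed)
  mk <- function(n, tag) {
    base <- stats::rnorm(S)
    m <- t(vapply(seq_len(n), function(i)
      sqrt(rho) * base + sqrt(1 - rho) * stats::rnorm(S), numeric(S)))
    rownames(m) <- sprintf("%s_%02d", tag, seq_len(n))
    m
  }
  out <- rbind(mk(nBlock, "blockA"), mk(nBlock, "blockB"))
  if (nNoise > 0) {
    noise <- matrix(stats::rnorm(nNoise * S), nNoise, S,
                    dimnames = list(sprintf("noise_%02d", seq_len(nNoise)),
                                    NULL))
    out <- rbind(out, noise)
  }
  colnames(out) <- sprintf("s%02d", seq_len(S))
  out
}
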
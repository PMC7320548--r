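test_that("expression filter respects the boundary exactly", {
  m <- rbind(kept = c(2, 2, 2, 0, 0, 0),
             dropped = c(2, 2, 0, 0, 0, 0),
             zero = rep(0, 6))
  colnames(m) <- paste0("s", 1:6)
  f <- filterExpressed(m, minSamples = 3, minValue = 1)
  expect_identical(rownames(f), "kept")
  expect_equal(nrow(filterExpressed(matrix(0, 5, 6))), 0)
})

test_that("TMM factors: symmetry, depth absorption, and a hand oracle", {
  y <- nullCounts(300, 2, seed = 1)
  y[, 2] <- y[, 1]
  f <- tmmFactors(y)$factors
  expect_equal(unname(f), c(1, 1))

  # doubling depth changes no ratio: factors stay (1, 1)
  y2 <- cbind(a = y[, 1], b = y[, 1] * 2)
  expect_equal(unname(tmmFactors(y2)$factors), c(1, 1))

  # hand-computed weighted trimmed mean on an enumerable table (trims off)
  cnt <- cbind(s1 = c(100, 200, 300, 50, 400),
               s2 = c(80, 260, 300, 70, 390))
  rownames(cnt) <- paste0("g", 1:5)
  nf <- tmmFactors(cnt, logratioTrim = 0, sumTrim = 0)
  n1 <- sum(cnt[, 1]); n2 <- sum(cnt[, 2])
  M <- log2((cnt[, 2] / n2) / (cnt[, 1] / n1))
  w <- (n2 - cnt[, 2]) / (n2 * cnt[, 2]) + (n1 - cnt[, 1]) / (n1 * cnt[, 1])
  f2 <- 2 ^ (sum(M / w) / sum(1 / w))   # sample 2 vs reference 1
  expected <- c(1 / sqrt(f2), sqrt(f2)) # after geometric-mean rescaling
  ref <- which.min(abs(apply(cnt, 2, function(v)
    stats::quantile(v / sum(v), 0.75)) -
      mean(apply(cnt, 2, function(v) stats::quantile(v / sum(v), 0.75)))))
  if (ref == 2) expected <- rev(expected)
  expect_equal(unname(nf$factors), unname(expected), tolerance = 1e-10)

  expect_error(tmmFactors(cbind(a = c(0, 0), b = c(1, 2))), "zero total")
})

test_that("TMM agrees closely with the published implementation", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  y <- matrix(stats::rnbinom(1200 * 5, mu = exp(stats::runif(1200, 2, 6)),
                             size = 5), 1200, 5,
              dimnames = list(paste0("g", 1:1200), paste0("s", 1:5)))
  y[1:80, 1] <- y[1:80, 1] * 6
  mine <- tmmFactors(y)$factors
  ref <- edgeR::calcNormFactors(edgeR::DGEList(y))$samples$norm.factors
  expect_lt(max(abs(mine - ref) / ref), 0.02)
})

test_that("dispersion estimation recovers the truth and pools degenerately", {
  md <- pairedMeta(6)
  y <- nullCounts(800, 12, mu = exp(stats::runif(800, log(30), log(400))),
                  phi = 0.4, seed = 7)
  d <- estimateDispersions(y, ~ treatment + patient, md)
  expect_gt(d$common, 0.3)
  expect_lt(d$common, 0.5)
  expect_true(all(d$tagwise > 0 & is.finite(d$tagwise)))

  yp <- nullCounts(800, 12, mu = 200, phi = 1e-8, seed = 8)
  dp <- estimateDispersions(yp, ~ treatment + patient, md)
  expect_lt(dp$common, 0.05)

  # single gene: tagwise = common = the gene's own estimate
  y1 <- nullCounts(1, 12, mu = 300, phi = 0.2, seed = 9)
  d1 <- estimateDispersions(y1, ~ treatment + patient, md)
  expect_equal(d1$tagwise, d1$common, tolerance = 0.05)
  expect_equal(d1$genewise, d1$common, tolerance = 0.05)

  # saturated design: no residual df
  expect_error(estimateDispersions(y[, 1:2], cbind(1, c(0, 1))),
               "residual")
})

test_that("exact test: symmetry, Poisson-limit oracle, column invariance", {
  y <- nullCounts(60, 4, seed = 10)
  y[, 3:4] <- y[, 1:2]
  grp <- factor(c("A", "A", "B", "B"))
  disp <- list(tagwise = rep(0.1, 60))
  r <- nbExactTest(y, grp, dispersions = disp)
  expect_true(all(deTable(r)$logFC == 0))
  expect_true(all(deTable(r)$PValue == 1))

  # Poisson limit: independent enumeration of the conditional binomial
  yy <- nullCounts(40, 6, mu = 60, phi = 1e-8, seed = 11)
  grp6 <- factor(rep(c("A", "B"), each = 3))
  rp <- nbExactTest(yy, grp6, dispersions = list(tagwise = rep(1e-9, 40)))
  pmine <- deTable(rp)$PValue
  libEq <- exp(mean(log(colSums(yy) * tmmFactors(yy)$factors)))
  eff <- colSums(yy) * tmmFactors(yy)$factors
  pseudo <- sweep(yy, 2, libEq / eff, "*")
  tA <- round(rowSums(pseudo[, 1:3])); tB <- round(rowSums(pseudo[, 4:6]))
  oracle <- vapply(seq_len(40), function(g) {
    t <- tA[g] + tB[g]
    if (t == 0) return(1)
    pr <- stats::dbinom(0:t, t, 0.5)
    sum(pr[pr <= pr[tA[g] + 1] * (1 + 1e-7)])
  }, numeric(1))
  expect_equal(pmine, oracle, tolerance = 1e-6)

  # invariance to sample column order
  perm <- c(4, 1, 6, 2, 3, 5)
  rshuf <- nbExactTest(yy[, perm], grp6[perm],
                       dispersions = list(tagwise = rep(1e-9, 40)))
  expect_equal(deTable(rshuf)$PValue, pmine, tolerance = 1e-12)

  expect_error(nbExactTest(y, factor(rep("A", 4))), "two groups")
})

test_that("scaling one sample's counts with its library leaves results unchanged", {
  y <- nullCounts(100, 6, seed = 12)
  grp <- factor(rep(c("A", "B"), each = 3))
  disp <- list(tagwise = rep(0.15, 100))
  p1 <- deTable(nbExactTest(y, grp, dispersions = disp))$PValue
  y2 <- y; y2[, 2] <- y2[, 2] * 2      # library size doubles with it
  p2 <- deTable(nbExactTest(y2, grp, dispersions = disp))$PValue
  expect_equal(p1, p2, tolerance = 0.02)
  expect_gt(stats::cor(p1, p2), 0.999)
})

test_that("exact test ranks true positives better than a t-test on logs", {
  set.seed(13)
  G <- 600; S <- 10
  mu <- exp(stats::runif(G, log(20), log(300)))
  y <- nullCounts(G, S, mu = mu, phi = 0.15, seed = 13)
  de <- seq_len(60)
  y[de, 6:10] <- matrix(stats::rnbinom(60 * 5, mu = rep(mu[de] * 4, 5),
                                       size = 1 / 0.15), 60, 5)
  grp <- factor(rep(c("A", "B"), each = 5))
  r <- nbExactTest(y, grp)
  pm <- deTable(r)$PValue
  pt <- apply(log2(y + 1), 1, function(v)
    stats::t.test(v[1:5], v[6:10])$p.value)
  tpCurve <- function(p) cumsum(order(p) %in% de) / length(de)
  expect_gt(mean(tpCurve(pm)), mean(tpCurve(pt)))
})

test_that("GLM LRT is calibrated, matches exact-test ranks, rejects saturation", {
  md <- pairedMeta(6)
  y <- nullCounts(1000, 12, mu = exp(stats::runif(1000, log(30), log(400))),
                  phi = 0.1, seed = 14)
  disp <- estimateDispersions(y, ~ treatment + patient, md)
  r <- nbGlmLRT(y, ~ treatment + patient, md, "treatment",
                dispersions = disp)
  p <- deTable(r)$PValue
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
  expect_lt(mean(deTable(r)$FDR < 0.05), 0.01)

  # two-group design without patient term: ranks match the exact test
  grp <- md$treatment
  md2 <- data.frame(group = grp)
  disp2 <- estimateDispersions(y, ~ group, md2)
  pg <- deTable(nbGlmLRT(y, ~ group, md2, "group",
                         dispersions = disp2))$PValue
  pe <- deTable(nbExactTest(y, grp, dispersions = disp2))$PValue
  expect_gt(stats::cor(pg, pe, method = "spearman"), 0.99)

  # column-order invariance
  perm <- sample(12)
  rp <- nbGlmLRT(y[, perm], ~ treatment + patient,
                 md[perm, ], "treatment", dispersions = disp)
  expect_equal(deTable(rp)$PValue, p, tolerance = 1e-6)

  # saturated single-sample-per-cell design
  mds <- data.frame(treatment = factor(c("H2O", "acute")),
                    patient = factor(c("p1", "p1")))
  expect_error(
    suppressWarnings(nbGlmLRT(y[1:5, 1:2], ~ treatment, mds, "treatment",
                              dispersions = list(tagwise = rep(0.1, 5)))),
    "residual|saturated|singular")
})

test_that("GLM logFC sign matches the planted direction for strong effects", {
  d <- simulateDataset(tinyConfig(n_genes = 600, effect_logfc = 1.2,
                                  frac_shared = 0.1, seed = 15))
  se <- d$experiment
  sel <- diagnosis(se) == "CTL" & treatment(se) %in% c("H2O", "acute")
  cnt <- filterExpressed(assay(se, "counts")[, sel])
  md <- data.frame(treatment = factor(treatment(se)[sel],
                                      levels = c("H2O", "acute")),
                   patient = factor(patientId(se)[sel]))
  r <- nbGlmLRT(cnt, ~ treatment + patient, md, "treatment")
  tab <- deTable(r)
  shared <- intersect(names(d$truth$gene_class)[
    d$truth$gene_class == "shared"], tab$gene)
  agree <- sign(tab$logFC[match(shared, tab$gene)]) ==
    d$truth$gene_direction[shared]
  expect_gte(mean(agree), 0.95)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustFdr(0.37), 0.37)
  expect_equal(adjustFdr(rep(1, 5)), rep(1, 5))
  # hand oracle: cumulative minima of n * p / i on the sorted p-values
  set.seed(16)
  p <- stats::runif(40)
  o <- order(p); n <- length(p)
  hand <- numeric(n)
  hand[o] <- rev(cummin(rev(pmin(1, n * p[o] / seq_len(n)))))
  expect_equal(adjustFdr(p), hand)
  # monotone non-decreasing in ranked p
  expect_true(all(diff(adjustFdr(p)[order(p)]) >= 0))
  expect_error(adjustFdr(c(0.1, NA)), "NA")
  expect_equal(adjustFdr(c(0.1, NA), naMask = TRUE)[2], NA_real_)
})
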
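test_that("conditional overlap statistics satisfy their exactness contracts", {
  universe <- sprintf("g%05d", 1:21231)
  a <- universe[1:116]
  b <- universe[c(1:11, 1000:1070)]
  ov <- overlapFisher(a, b, 21231)
  expect_equal(ov$both, 11)
  expect_equal(ov$only_a, 105)
  expect_equal(ov$only_b, 71)
  expect_equal(ov$neither, 21231 - 187)
  # p-value agrees with the base-R implementation exactly
  ft <- stats::fisher.test(matrix(c(11, 105, 71, 21044), 2, 2))
  expect_equal(ov$p_value, ft$p.value, tolerance = 1e-12)
  # conditional MLE agrees with fisher.test up to its looser optimizer
  expect_lt(abs(ov$odds_ratio - ft$estimate) / ft$estimate, 0.001)
  # score equation residual at the returned OR
  resid <- igfresponse:::.fisherConditional
  m1 <- 116; n2 <- 21231 - 116; k <- 82
  supp <- max(0, k - n2):min(k, m1)
  logdc <- lchoose(m1, supp) + lchoose(n2, k - supp)
  dens <- function(psi) {
    w <- logdc + supp * log(psi); w <- exp(w - max(w)); w / sum(w)
  }
  expect_lt(abs(sum(supp * dens(ov$odds_ratio)) - 11), 1e-8)
  # CI endpoints invert one-sided exact tests at 2.5% each
  expect_lt(abs(sum(dens(ov$ci95[1])[supp >= 11]) - 0.025), 1e-6)
  expect_lt(abs(sum(dens(ov$ci95[2])[supp <= 11]) - 0.025), 1e-6)
  expect_true(ov$ci95[1] < ov$odds_ratio && ov$odds_ratio < ov$ci95[2])
})

test_that("overlap edge cases and the brute-force hypergeometric oracle", {
  ov <- overlapFisher(letters[1:5], letters[1:5], 20)
  expect_equal(ov$odds_ratio, Inf)
  expect_lt(ov$p_value, 1)
  # symmetry in the two lists
  o1 <- overlapFisher(letters[1:8], letters[5:12], 26)
  o2 <- overlapFisher(letters[5:12], letters[1:8], 26)
  expect_equal(o1$p_value, o2$p_value)
  expect_equal(o1$odds_ratio, o2$odds_ratio)
  expect_error(overlapFisher(letters[1:20], letters[1:10], 15), "universe")

  # tiny table: p equals direct enumeration over fixed-margin tables
  ov3 <- overlapFisher(c("a", "b", "c"), c("a", "b", "d"), 10)
  a <- 2; b <- 1; cc <- 1; d <- 6
  m1 <- a + b; n2 <- cc + d; k <- a + cc
  supp <- max(0, k - n2):min(k, m1)
  pr <- exp(lchoose(m1, supp) + lchoose(n2, k - supp) -
              lchoose(m1 + n2, k))
  oracle <- sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
  expect_equal(ov3$p_value, oracle, tolerance = 1e-12)
})

test_that("chi-square matches hand computation and the brute-force oracle", {
  r <- categoryChisq(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- categoryChisq(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(r2$statistic, 40)
  expect_equal(r2$df, 1)
  expect_equal(categoryChisq(matrix(c(5, 10, 8, 9, 12, 7), 2, 3))$df, 2)
  set.seed(31)
  for (i in 1:5) {
    tab <- matrix(stats::rpois(6, 30) + 1, 2, 3)
    res <- categoryChisq(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E) ^ 2 / E), tolerance = 1e-12)
  }
  expect_error(categoryChisq(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
})

test_that("temporal grouping is exact set algebra with directions", {
  genes <- paste0("g", 1:6)
  acute <- makeDEResult(genes, logFC = c(2, 1, -1, 0.5, 0.2, 0.1),
                        pvalue = c(1e-6, 1e-6, 1e-6, 0.9, 0.8, 0.9))
  chronic <- makeDEResult(genes, logFC = c(2, -1, 0.3, 2, 0.1, 0.2),
                          pvalue = c(1e-6, 1e-6, 0.9, 1e-6, 0.9, 0.8))
  gr <- temporalGrouping(acute, chronic)
  lab <- stats::setNames(gr$group, gr$gene)
  expect_equal(unname(lab[c("g1", "g2")]), c("shared", "shared"))
  expect_equal(unname(lab["g3"]), "acute_only")
  expect_equal(unname(lab["g4"]), "chronic_only")
  expect_false(any(c("g5", "g6") %in% gr$gene))
  dir <- stats::setNames(gr$direction, gr$gene)
  expect_equal(unname(dir["g1"]), "up")
  expect_equal(unname(dir["g2"]), "discordant")  # acute up, chronic down
  expect_equal(unname(dir["g3"]), "down")
  expect_equal(unname(dir["g4"]), "up")

  # empty chronic hits: everything acute_only
  chronic0 <- makeDEResult(genes, logFC = rep(0.1, 6), pvalue = rep(0.9, 6))
  gr0 <- temporalGrouping(acute, chronic0)
  expect_true(all(gr0$group == "acute_only"))

  other <- makeDEResult(paste0("x", 1:6), rep(1, 6), rep(0.5, 6))
  expect_error(temporalGrouping(acute, other), "feature")
})

test_that("trajectory aggregates detect planted shifts and degrade gracefully", {
  set.seed(32)
  S <- 24
  md <- data.frame(sample_id = sprintf("s%02d", 1:S),
                   treatment = rep(c("H2O", "acute", "chronic"), each = 8))
  base <- matrix(stats::rnorm(30 * S, 5), 30, S,
                 dimnames = list(paste0("g", 1:30), md$sample_id))
  base[1:10, md$treatment == "acute"] <-
    base[1:10, md$treatment == "acute"] + 1.5
  tt <- trajectoryTest(base, md, paste0("g", 1:10))
  tests <- tt$tests
  expect_lt(tests$p[tests$contrast == "acute_vs_H2O"], 0.001)
  expect_gt(tests$p[tests$contrast == "chronic_vs_H2O"], 0.001)
  # aggregates have mean zero across all samples by construction
  expect_lt(abs(mean(tt$aggregate)), 1e-10)

  # constant genes: degenerate aggregate, p = 1 with flag
  flat <- matrix(3, 5, S, dimnames = list(paste0("f", 1:5), md$sample_id))
  td <- trajectoryTest(flat, md, paste0("f", 1:5))
  expect_true(all(td$tests$degenerate))
  expect_true(all(td$tests$p == 1))

  md1 <- md; md1$treatment <- "H2O"
  expect_error(trajectoryTest(base, md1, paste0("g", 1:5)), "one arm")
  expect_error(trajectoryTest(base, md, "absent_gene"), "empty")
})

test_that("hypergeometric ORA matches direct summation and ranks overlap", {
  universe <- paste0("g", 1:200)
  hits <- universe[1:20]
  sets <- list(perfect = hits,
               disjoint = universe[101:130],
               partial = universe[11:40])
  res <- enrichmentORA(hits, universe, sets)
  expect_equal(res$overlap[res$set == "perfect"], 20)
  expect_true(res$p[res$set == "perfect"] < res$p[res$set == "partial"])
  # direct-summation oracle for each set
  for (i in seq_len(nrow(res))) {
    m <- res$set_size[i]; k <- res$overlap[i]
    pr <- exp(lchoose(m, k:min(m, 20)) + lchoose(200 - m, 20 - (k:min(m, 20))) -
                lchoose(200, 20))
    expect_equal(res$p[i], sum(pr), tolerance = 1e-10)
  }
  expect_gte(res$p[res$set == "disjoint"], 0.5)
  expect_error(enrichmentORA(hits, character(0), sets), "universe")

  # uniform hits give calibrated p-values
  set.seed(33)
  ps <- replicate(200, {
    h <- sample(universe, 20)
    enrichmentORA(h, universe, list(s = universe[1:40]))$p
  })
  expect_gt(mean(ps > 0.5), 0.3)   # discrete but roughly uniform tail
  expect_gt(mean(ps), 0.35)
})

test_that("GMT reading round-trips gene sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tother\tg9"), path)
  sets <- readGmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g9")
})
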
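#' Fisher exact overlap statistics for two gene lists
#'
#' Builds the 2x2 overlap table of two gene lists within a universe of
#' \code{universeN} genes and computes the two-sided Fisher exact p-value,
#' the conditional maximum-likelihood odds ratio (root of the noncentral
#' hypergeometric score equation, tolerance 1e-10), and the exact central
#' 95% confidence interval obtained by inverting one-sided exact tests at
#' 2.5% each side. An infinite odds ratio is returned when the overlap sits
#' at the boundary of its support.
#'
#' @param listA,listB character vectors of gene ids (subsets of the universe).
#' @param universeN number of genes in the universe (>= size of the union).
#' @return list of class \code{OverlapResult}: \code{both}, \code{only_a},
#'   \code{only_b}, \code{neither}, \code{odds_ratio}, \code{ci95},
#'   \code{p_value}.
#' @export
overlapFisher <- function(listA, listB, universeN) {
  listA <- unique(as.character(listA))
  listB <- unique(as.character(listB))
  both <- length(intersect(listA, listB))
  onlyA <- length(setdiff(listA, listB))
  onlyB <- length(setdiff(listB, listA))
  union_n <- both + onlyA + onlyB
  if (union_n > universeN)
    stop("universe smaller than the union of the lists")
  neither <- universeN - union_n
  stats <- .fisherConditional(both, onlyA, onlyB, neither)
  out <- c(list(both = both, only_a = onlyA, only_b = onlyB,
                neither = neither), stats)
  class(out) <- "OverlapResult"
  out
}

# Conditional inference for a 2x2 table [a b; c d] given all margins.
.fisherConditional <- function(a, b, cc, d, conf = 0.95, tol = 1e-10) {
  m1 <- a + b; n2 <- cc + d; k <- a + cc
  lo <- max(0, k - n2); hi <- min(k, m1)
  supp <- lo:hi
  logdc <- lchoose(m1, supp) + lchoose(n2, k - supp)
  dens <- function(psi) {
    w <- logdc + supp * log(psi)
    w <- exp(w - max(w))
    w / sum(w)
  }
  ## two-sided exact p: sum of probabilities <= observed table's probability
  p0 <- dens(1)
  obs <- p0[supp == a]
  pval <- min(1, sum(p0[p0 <= obs * (1 + 1e-7)]))
  condMean <- function(psi) sum(supp * dens(psi))
  solvePsi <- function(f, target) {
    g <- function(lp) f(exp(lp)) - target
    r <- stats::uniroot(g, lower = log(1e-12), upper = log(1e12),
                        tol = tol, extendInt = "yes")
    exp(r$root)
  }
  orHat <- if (a == hi) Inf else if (a == lo) 0 else solvePsi(condMean, a)
  alpha <- (1 - conf) / 2
  pge <- function(psi) sum(dens(psi)[supp >= a])
  ple <- function(psi) sum(dens(psi)[supp <= a])
  ciLow <- if (a == lo) 0 else solvePsi(pge, alpha)
  ciHigh <- if (a == hi) Inf else solvePsi(ple, alpha)
  list(odds_ratio = orHat, ci95 = c(ciLow, ciHigh), p_value = pval)
}

#' Pearson chi-square test of an r x c contingency table
#'
#' \code{X^2 = sum (O - E)^2 / E} with expected counts from the margins,
#' df = (r-1)(c-1), no continuity correction.
#'
#' @param tab matrix of counts with positive row and column margins.
#' @return list: \code{statistic}, \code{df}, \code{p_value}, \code{expected}.
#' @export
categoryChisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal row or column")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected counts must be positive")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Temporal grouping of acute and chronic DE genes
#'
#' Partitions the union of acute- and chronic-significant genes into
#' \code{shared}, \code{acute_only} and \code{chronic_only}, with per-gene
#' direction (\code{up}/\code{down}) taken from the defining contrast
#' (shared genes use the acute sign; genes significant in both with opposite
#' signs are flagged \code{discordant}).
#'
#' @param acute,chronic \linkS4class{DEResult}s on the same feature space.
#' @param fdrCut significance cutoff.
#' @return data.frame with columns \code{gene}, \code{group},
#'   \code{direction}.
#' @export
temporalGrouping <- function(acute, chronic, fdrCut = 0.05) {
  ta <- deTable(acute); tc <- deTable(chronic)
  if (!setequal(ta$gene, tc$gene))
    stop("acute and chronic results are on different feature sets")
  hitsA <- significantGenes(acute, fdrCut)
  hitsC <- significantGenes(chronic, fdrCut)
  genes <- union(hitsA, hitsC)
  group <- ifelse(genes %in% hitsA & genes %in% hitsC, "shared",
                  ifelse(genes %in% hitsA, "acute_only", "chronic_only"))
  lfcA <- stats::setNames(ta$logFC, ta$gene)
  lfcC <- stats::setNames(tc$logFC, tc$gene)
  direction <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    direction[i] <- switch(group[i],
      shared = if (sign(lfcA[g]) != sign(lfcC[g])) "discordant"
               else if (lfcA[g] > 0) "up" else "down",
      acute_only = if (lfcA[g] > 0) "up" else "down",
      chronic_only = if (lfcC[g] > 0) "up" else "down")
  }
  data.frame(gene = genes, group = group, direction = direction,
             stringsAsFactors = FALSE)
}

#' Aggregate trajectory test for a gene group
#'
#' Each gene's log expression is z-scored across all samples; the per-sample
#' aggregate is the mean over the group's genes. For each contrast the F-test
#' comes from the linear model \code{aggregate ~ treatment} restricted to the
#' contrast's two arms. A group of constant-expression genes yields an
#' identically zero aggregate, reported as p = 1 with \code{degenerate}
#' flagged.
#'
#' @param logtpm gene x sample log2(TPM+1) matrix.
#' @param metadata per-sample data.frame with \code{sample_id} and
#'   \code{treatment}.
#' @param genes non-empty gene group.
#' @param contrasts list of length-2 character vectors (reference, treated).
#' @return list: \code{aggregate} (named per-sample scores), \code{tests}
#'   (data.frame contrast, F, p, degenerate).
#' @export
trajectoryTest <- function(logtpm, metadata,
                           genes,
                           contrasts = list(c("H2O", "acute"),
                                            c("H2O", "chronic"))) {
  genes <- intersect(genes, rownames(logtpm))
  if (!length(genes)) stop("gene group is empty")
  z <- .zscoreRows(logtpm[genes, , drop = FALSE])
  agg <- colMeans(z)
  md <- as.data.frame(metadata)
  tr <- as.character(md$treatment[match(colnames(logtpm), md$sample_id)])
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    sel <- tr %in% ct
    if (length(unique(tr[sel])) < 2)
      stop("contrast ", paste(ct, collapse = " vs "),
           ": only one arm present")
    a <- agg[sel]
    f <- factor(tr[sel], levels = ct)
    if (stats::sd(a) == 0)
      return(data.frame(contrast = paste0(ct[2], "_vs_", ct[1]),
                        F = NA_real_, p = 1, degenerate = TRUE))
    av <- stats::anova(stats::lm(a ~ f))
    data.frame(contrast = paste0(ct[2], "_vs_", ct[1]),
               F = av$`F value`[1], p = av$`Pr(>F)`[1], degenerate = FALSE)
  }))
  list(aggregate = agg, tests = tests)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value for the overlap of a hit list with each
#' gene set (sets intersected with the universe), BH-adjusted across sets.
#'
#' @param hits character vector of hit genes (subset of the universe).
#' @param universe character vector of all tested genes (non-empty).
#' @param geneSets named list of character vectors.
#' @return data.frame: \code{set}, \code{set_size}, \code{overlap},
#'   \code{p}, \code{fdr}.
#' @export
enrichmentORA <- function(hits, universe, geneSets) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  hits <- unique(intersect(as.character(hits), universe))
  N <- length(universe)
  res <- do.call(rbind, lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    k <- length(intersect(set, hits))
    p <- if (!length(set)) 1 else
      stats::phyper(k - 1, length(set), N - length(set), length(hits),
                    lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- adjustFdr(res$p)
  res
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, genes...).
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}
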
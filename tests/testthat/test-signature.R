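# small two-class expression toys for the selection stages
classToy <- function(n = 120, G = 60, nSignal = 3, fold = 3, seed = 1) {
  set.seed(seed)
  grp <- rep(c("DGC", "PDGC"), each = n / 2)
  mu <- matrix(2, nrow = G, ncol = n)
  mu[seq_len(nSignal), grp == "DGC"] <- 2 * fold
  m <- log1p(matrix(rpois(G * n, as.vector(mu)), nrow = G,
                    dimnames = list(sprintf("g%03d", 1:G),
                                    sprintf("c%03d", 1:n))))
  list(m = m, grp = grp)
}

test_that("correlation expansion keeps the reference and sheds noise", {
  toy <- classToy(n = 1000, G = 40, nSignal = 1, fold = 4, seed = 2)
  # a gene identical to the reference correlates perfectly
  m <- rbind(toy$m, ref_twin = colMeans(toy$m["g001", , drop = FALSE]))
  cand <- candidateGenes(m, "g001", rMin = 0.5)
  expect_true("ref_twin" %in% cand)
  expect_true("g001" %in% cand)
  # independent noise genes are excluded
  noise <- setdiff(rownames(m), c("g001", "ref_twin"))
  expect_lt(length(intersect(cand, noise)), 3)
  expect_error(candidateGenes(matrix(1, 3, 30,
                                     dimnames = list(letters[1:3], NULL)),
                              "a"), "zero-variance")
})

test_that("the lasso retains signal and drops permuted-label noise", {
  toy <- classToy(n = 200, G = 40, nSignal = 1, fold = 5, seed = 3)
  keep <- lassoSelect(toy$m, rownames(toy$m), toy$grp, seed = 1)
  expect_true("g001" %in% keep$genes)
  set.seed(44)
  nullKeep <- lassoSelect(toy$m, rownames(toy$m), sample(toy$grp), seed = 1)
  expect_lte(length(nullKeep$genes), 4)
  # duplicated signal columns: at least one copy survives
  m2 <- rbind(toy$m, g001_copy = toy$m["g001", ])
  keep2 <- lassoSelect(m2, rownames(m2), toy$grp, seed = 1)
  expect_true(any(c("g001", "g001_copy") %in% keep2$genes))
  expect_error(lassoSelect(toy$m, rownames(toy$m),
                           rep(c("DGC", "PDGC"), c(10, 190))),
               "at least 20")
})

test_that("random-forest ranking puts planted signal on top", {
  toy <- classToy(n = 200, G = 30, nSignal = 2, fold = 5, seed = 5)
  rk <- rfRank(toy$m, rownames(toy$m), toy$grp, seed = 1)
  expect_true(all(c("g001", "g002") %in% head(rk$gene, 3)))
  expect_false(any(rk$low_contribution[rk$gene %in% c("g001", "g002")]))
  expect_warning(rfRank(toy$m, rownames(toy$m)[1:5], toy$grp, mTry = 10,
                        seed = 1), "clamped")
})

test_that("the cascade recovers the planted signature with full provenance", {
  sce <- cascadeCohort(1)
  truth <- groundTruth(sce)
  mt <- truth$malignant[colnames(sce)]
  sub <- sce[, mt]
  sig <- deriveSignature(sub, sub$pathology, seed = 1)
  expect_setequal(signatureGenes(sig), truth$differentiation_genes)
  pv <- geneProvenance(sig)
  # provenance completeness: every candidate carries every flag
  expect_false(any(is.na(pv[, c("deg_up", "corr_candidate", "lasso_kept",
                                "rf_kept", "excluded", "floor_failed")])))
  # curated exclusion genes reach the cascade but never the output
  expect_true(all(truth$exclusion_genes %in% pv$gene))
  expect_false(any(truth$exclusion_genes %in% signatureGenes(sig)))
  # cascade monotonicity
  final <- pv$gene[pv$in_signature]
  expect_true(all(final %in% pv$gene[pv$lasso_kept & pv$rf_kept]))
  expect_true(all(pv$gene[pv$lasso_kept] %in% pv$gene))
})

test_that("the expression floor removes lowly expressed survivors", {
  toy <- classToy(n = 300, G = 30, nSignal = 3, fold = 4, seed = 6)
  # make the third signal gene pass detection but sit below the floor
  low <- toy$m["g003", ] * 0.15
  toy$m["g003", ] <- low
  sig <- suppressWarnings(
    deriveSignature(toy$m, toy$grp, exclusionList = character(0), seed = 1))
  pv <- geneProvenance(sig)
  expect_true("g003" %in% pv$gene)
  expect_true(pv$floor_failed[pv$gene == "g003"])
  expect_false("g003" %in% signatureGenes(sig))
  # the literal reading of the floor (ln 0.5 < 0) removes nothing
  sigLit <- suppressWarnings(
    deriveSignature(toy$m, toy$grp, exclusionList = character(0),
                    literalFloor = TRUE, seed = 1))
  expect_true("g003" %in% signatureGenes(sigLit))
})

test_that("a cohort without class differences fails at the first stage", {
  set.seed(7)
  m <- log1p(matrix(rpois(50 * 100, 2), nrow = 50,
                    dimnames = list(sprintf("g%02d", 1:50), NULL)))
  colnames(m) <- sprintf("c%03d", 1:100)
  expect_error(deriveSignature(m, rep(c("DGC", "PDGC"), each = 50)),
               "stage 'deg'")
  expect_error(deriveSignature(m, rep("DGC", 100)), "DGC or PDGC|two")
})

test_that("tumor and differentiation scores anticorrelate as constructed", {
  sce <- smallCohort(1)
  truth <- groundTruth(sce)
  epi <- sce[, sce$lineage == "epithelial"]
  m <- truth$malignant[colnames(epi)]
  ts <- tumorDiffScores(epi, m, truth$differentiation_genes, seed = 1)
  expect_lt(ts$r, 0)
  # shuffled cell order leaves the correlation unchanged
  ord <- sample(ncol(epi))
  ts2 <- tumorDiffScores(epi[, ord], m[ord], truth$differentiation_genes,
                         seed = 1)
  expect_equal(ts$r, ts2$r, tolerance = 1e-10)
})

test_that("set overlap matches the hypergeometric tail computed directly", {
  expect_equal(signatureOverlap(letters[1:5], letters[1:5], 100)$jaccard, 1)
  d <- signatureOverlap(letters[1:10], letters[11:20], 100)
  expect_equal(d$p_hyper, 1, tolerance = 1e-12)
  # brute-force tail summation oracle
  a <- 20; b <- 20; q <- 10; U <- 1000
  direct <- sum(vapply(q:min(a, b), function(k)
    choose(a, k) * choose(U - a, b - k) / choose(U, b), numeric(1)))
  sets <- list(a = sprintf("x%03d", 1:20),
               b = c(sprintf("x%03d", 1:10), sprintf("y%03d", 1:10)))
  d2 <- signatureOverlap(sets$a, sets$b, U)
  expect_equal(d2$intersection, 10)
  expect_equal(d2$p_hyper, direct, tolerance = 1e-12)
  expect_error(signatureOverlap(character(0), letters, 100), "empty")
})

test_that("immune-axis markers overlap differentiation-axis markers", {
  # the planted interferon program is shared between the two comparisons
  # only through chance here; the operation itself is exercised on planted
  # sets with a known universe
  sce <- smallCohort(1)
  truth <- groundTruth(sce)
  ov <- signatureOverlap(c(truth$differentiation_genes, truth$ifn_genes),
                         c(truth$differentiation_genes,
                           truth$malignancy_genes),
                         universe = nrow(sce))
  expect_equal(ov$intersection, length(truth$differentiation_genes))
  expect_lt(ov$p_hyper, 1e-6)
})
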
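library(Matrix)

# build a minimal SCE from a dense count matrix
toySce <- function(counts, mito = rep(FALSE, nrow(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(Matrix(counts, sparse = TRUE),
                              "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(is_mitochondrial = mito,
                                   row.names = rownames(counts))
  )
}

# a cell with the given detected genes / UMIs / mito fraction
qcToyCell <- function(nGenes, nUmis, mitoFrac, G = 700, nMito = 10) {
  v <- numeric(G)
  mitoUmis <- round(nUmis * mitoFrac)
  nucUmis <- nUmis - mitoUmis
  nNuc <- nGenes - (mitoUmis > 0)
  base <- rep(floor(nucUmis / nNuc), nNuc)
  base[seq_len(nucUmis - sum(base))] <- base[seq_len(nucUmis - sum(base))] + 1
  v[nMito + seq_len(nNuc)] <- base
  if (mitoUmis > 0) v[1] <- mitoUmis
  v
}

test_that("QC keeps cells strictly inside all three thresholds", {
  G <- 700
  cells <- cbind(
    qcToyCell(600, 1200, 0.1, G),   # passes everything
    qcToyCell(400, 1200, 0.1, G),   # too few genes
    qcToyCell(600, 900, 0.1, G),    # too few UMIs
    qcToyCell(600, 2000, 0.6, G),   # mito-heavy
    qcToyCell(501, 1001, 0.49, G)   # boundary: strictly inside
  )
  sce <- toySce(cells, mito = c(rep(TRUE, 10), rep(FALSE, G - 10)))
  out <- qcFilter(sce)
  expect_equal(colnames(out), c("c001", "c005"))
  rep <- metadata(out)$qc_report
  expect_equal(rep$n_kept, 2)
  expect_equal(rep$removed_low_genes, 1)
  expect_equal(rep$removed_low_umis, 1)
  expect_equal(rep$removed_high_mito, 1)
})

test_that("a cell with exactly 500 detected genes is removed", {
  G <- 700
  cells <- cbind(qcToyCell(500, 1200, 0.1, G), qcToyCell(600, 1200, 0.1, G))
  sce <- toySce(cells, mito = c(rep(TRUE, 10), rep(FALSE, G - 10)))
  expect_equal(ncol(qcFilter(sce)), 1)
})

test_that("QC filtering is idempotent and signals total failure", {
  sce <- smallCohortRaw()
  once <- qcFilter(sce)
  twice <- qcFilter(once)
  expect_equal(colnames(once), colnames(twice))
  bad <- toySce(matrix(1, nrow = 600, ncol = 3))
  expect_error(qcFilter(bad), class = "allCellsFailedQC")
})

test_that("log-normalization matches its closed form", {
  m <- matrix(0, nrow = 4, ncol = 2)
  m[, 1] <- c(1, 9999, 0, 0)     # total 10,000
  m[, 2] <- c(2, 0, 8, 10)       # total 20
  sce <- logNormalize(toySce(m))
  lc <- as.matrix(assay(sce, "logcounts"))
  expect_equal(lc[1, 1], log(2), tolerance = 1e-12)
  expect_equal(lc[3, 1], 0)
  expect_equal(lc[1, 2], log1p(1e4 * 2 / 20), tolerance = 1e-12)
  # scale invariance: doubling all counts of a cell changes nothing
  sce2 <- logNormalize(toySce(cbind(m[, 2], 2 * m[, 2])))
  lc2 <- as.matrix(assay(sce2, "logcounts"))
  expect_equal(lc2[, 1], lc2[, 2], tolerance = 1e-12)
  expect_error(logNormalize(toySce(cbind(m[, 1], 0 * m[, 1]))), "zero total")
})

test_that("variable-gene selection ranks planted structure first", {
  set.seed(11)
  n <- 200
  m <- matrix(rpois(300 * n, 2), nrow = 300)
  m[1, ] <- 2                                   # constant gene
  m[2, ] <- c(rpois(n / 2, 12), rpois(n / 2, 0.2))  # bimodal gene
  sce <- logNormalize(toySce(m))
  hv <- selectHvgs(sce, 50)
  expect_true("g002" %in% hv)
  expect_false("g001" %in% hv)
  expect_equal(sort(selectHvgs(sce, 300)), sort(rownames(sce)))
  expect_error(selectHvgs(sce, 301), "exceeds")
})

test_that("a homogeneous population forms a single cluster", {
  set.seed(5)
  m <- matrix(rnbinom(400 * 300, mu = 2, size = 2), nrow = 400)
  sce <- logNormalize(toySce(m))
  cl <- clusterCells(sce, resolution = 0.1, seed = 1)
  expect_equal(length(unique(cl)), 1)
})

test_that("clustering is deterministic under a fixed seed", {
  sce <- smallCohort(1)
  sub <- sce[, sce$sample_id %in% c("N1", "D1", "P1")]
  hv <- selectHvgs(sub, 500)
  a <- clusterCells(sub, genes = hv, seed = 9)
  b <- clusterCells(sub, genes = hv, seed = 9)
  expect_identical(a, b)
})

test_that("rank-sum markers match exact enumeration on tied toy data", {
  m <- rbind(g1 = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  colnames(m) <- paste0("c", 1:10)
  d <- wilcoxMarkers(m, rep(c("A", "B"), each = 5), minPct = 0,
                     logfcThreshold = 0)
  expect_equal(d$p[d$group == "A"], 2 / choose(10, 5), tolerance = 1e-12)

  set.seed(31)
  cmb <- utils::combn(16, 8)
  for (i in 1:10) {
    vals <- rpois(16, 2)
    mm <- rbind(g = vals)
    colnames(mm) <- paste0("c", 1:16)
    d <- wilcoxMarkers(mm, rep(c("A", "B"), each = 8), minPct = 0,
                       logfcThreshold = 0)
    expect_equal(d$p[d$group == "A"], enumRankSumP(vals, 8, cmb),
                 tolerance = 1e-9)
  }
})

test_that("marker detection applies its filters as specified", {
  set.seed(2)
  n <- 40
  grp <- rep(c("A", "B"), each = n / 2)
  half <- matrix(rpois(50 * n / 2, 2), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  m <- cbind(half, half)
  colnames(m) <- sprintf("c%02d", seq_len(n))
  # literally identical groups: nothing passes the fold-change filter
  d0 <- wilcoxMarkers(m, grp)
  expect_equal(nrow(d0), 0)
  # a gene expressed in 20% of cells on both sides is never tested
  m2 <- m
  m2[1, ] <- 0
  on <- c(seq_len(0.2 * n / 2), n / 2 + seq_len(0.2 * n / 2))
  m2[1, on] <- 20
  rownames(m2) <- sprintf("g%02d", 1:50)
  d2 <- wilcoxMarkers(m2, grp, minPct = 0.25, logfcThreshold = 0)
  expect_false("g01" %in% d2$gene_id)
  # groups below 3 cells are skipped with a warning (and so is the
  # complementary side of the remaining group)
  expect_warning(expect_warning(
    wilcoxMarkers(m, c(rep("A", 2), rep("B", n - 2))), "fewer than 3"))
})

test_that("BH adjustment preserves the p-value ordering", {
  sce <- smallCohort(1)
  sub <- sce[, sce$lineage %in% c("tnk", "b")]
  d <- wilcoxMarkers(sub, sub$lineage[colnames(sub) %in% colnames(sub)])
  d <- d[d$group == "tnk", ]
  expect_true(all(d$p_adj >= d$p - 1e-15))
  # monotone: sorting by p equals sorting by p_adj up to ties
  expect_true(all(diff(d$p_adj[order(d$p)]) > -1e-15))
})
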
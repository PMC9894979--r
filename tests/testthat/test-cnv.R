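library(Matrix)

# SCE with a one-chromosome toy genome and chosen logcounts
genomicSce <- function(values, chrom = NULL) {
  G <- nrow(values)
  if (is.null(chrom)) chrom <- rep("chr1", G)
  rn <- sprintf("g%03d", seq_len(G))
  rownames(values) <- rn
  colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(Matrix(values, sparse = TRUE),
                              "CsparseMatrix"),
                  logcounts = as(Matrix(values, sparse = TRUE),
                                 "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(
      gene_id = rn, chrom = chrom,
      start_bp = seq(0, by = 1000, length.out = G),
      end_bp = seq(1000, by = 1000, length.out = G),
      is_mitochondrial = rep(FALSE, G), row.names = rn)
  )
  sce
}

test_that("windowing splits chromosomes into 25-gene windows", {
  v <- matrix(1:50 / 10, nrow = 50, ncol = 30)
  v <- v + matrix(rnorm(50 * 30, sd = 1e-3), nrow = 50)
  prof <- smoothGenomic(genomicSce(abs(v) + 1), winSize = 25,
                        minCellsExpr = 1)
  expect_equal(nrow(cnvWindows(prof)), 2)
  expect_equal(cnvWindows(prof)$n_genes, c(25, 25))
  # 60 genes -> 2 full windows plus a 10-gene trailing window
  v2 <- matrix(abs(rnorm(60 * 30)) + 1, nrow = 60)
  prof2 <- smoothGenomic(genomicSce(v2), winSize = 25, minCellsExpr = 1)
  expect_equal(cnvWindows(prof2)$n_genes, c(25, 25, 10))
})

test_that("identical cells give identical centred profiles", {
  v <- matrix(rep(abs(rnorm(60)) + 1, 20), nrow = 60)
  prof <- smoothGenomic(genomicSce(v), winSize = 20, minCellsExpr = 1)
  m <- cnvMatrix(prof)
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-12)
})

test_that("chromosomes with too few genes are dropped with a warning", {
  v <- matrix(abs(rnorm(40 * 25)) + 1, nrow = 40)
  chrom <- c(rep("chr1", 30), rep("chr2", 10))
  expect_warning(prof <- smoothGenomic(genomicSce(v, chrom), winSize = 25,
                                       minCellsExpr = 1), "chr2")
  expect_true(all(cnvWindows(prof)$chrom == "chr1"))
  expect_error(
    suppressWarnings(smoothGenomic(genomicSce(v[1:10, , drop = FALSE]),
                                   winSize = 25, minCellsExpr = 1)),
    "no chromosome")
})

test_that("deviation obeys its closed forms", {
  # hand-built profile: 30 normal cells at the baseline, one offset cell
  W <- 8
  base <- rnorm(W)
  m <- matrix(rep(base, each = 31), nrow = 31)
  d <- 0.7
  m[31, ] <- base + d
  rownames(m) <- sprintf("c%02d", 1:31)
  prof <- methods::new("CnvProfile",
                       windows = data.frame(chrom = "chr1",
                                            start = seq_len(W),
                                            end = seq_len(W) + 1,
                                            n_genes = rep(25, W)),
                       matrix = m)
  out <- cnvDeviation(prof, c(rep(TRUE, 30), FALSE))
  dev <- deviationScores(out)
  expect_equal(unname(dev[1:30]), rep(0, 30), tolerance = 1e-12)
  expect_equal(unname(dev[31]), d^2, tolerance = 1e-12)
  # baseline subtraction zeroes the mean normal profile
  expect_lt(max(abs(colMeans(cnvMatrix(out)[1:30, ]))), 1e-10)
  expect_error(cnvDeviation(prof, rep(FALSE, 31)), "no cells")
})

test_that("deviation is invariant to gene order within a window", {
  set.seed(8)
  v <- matrix(abs(rnorm(50 * 40)) + 1, nrow = 50)
  sce <- genomicSce(v)
  prof <- cnvDeviation(smoothGenomic(sce, winSize = 25, minCellsExpr = 1),
                       rep(c(TRUE, FALSE), each = 20))
  # permute genes inside the first window (same positions, shuffled values)
  perm <- c(sample(1:25), 26:50)
  v2 <- v[perm, ]
  sce2 <- genomicSce(v2)
  prof2 <- cnvDeviation(smoothGenomic(sce2, winSize = 25, minCellsExpr = 1),
                        rep(c(TRUE, FALSE), each = 20))
  expect_equal(deviationScores(prof), deviationScores(prof2),
               tolerance = 1e-12)
})

test_that("a planted aneuploid clone separates from diploid cells", {
  sce <- cnvCloneCohort(1)
  truth <- groundTruth(sce)
  epi <- sce[, sce$lineage == "epithelial"]
  prof <- cnvDeviation(smoothGenomic(epi), epi$pathology == "normal")
  dev <- deviationScores(prof)
  mt <- truth$malignant[colnames(epi)]
  expect_gt(median(dev[mt]) / median(dev[!mt]), 3)
  # the copy-3 segment sits above the diploid baseline in nearly all cells
  w <- cnvWindows(prof)
  hit <- w$chrom == "chr1" & w$start >= 1e6 & w$end <= 7e6
  segMean <- rowMeans(cnvMatrix(prof)[, hit, drop = FALSE])
  expect_gt(mean(segMean[mt] > 0), 0.95)
})

test_that("classification combines CNV level with cluster composition", {
  # synthetic deviations: cluster A = normal mucosa, B = aneuploid,
  # C = aneuploid profile but half normal-mucosa cells
  W <- 6
  n <- 90
  m <- matrix(rnorm(n * W, sd = 0.05), nrow = n)
  m[31:90, ] <- m[31:90, ] + 0.8
  rownames(m) <- sprintf("c%03d", seq_len(n))
  prof <- methods::new("CnvProfile",
                       windows = data.frame(chrom = "chr1",
                                            start = seq_len(W),
                                            end = seq_len(W) + 1,
                                            n_genes = rep(25, W)),
                       matrix = m)
  normal <- c(rep(TRUE, 30), rep(FALSE, 30), rep(c(TRUE, FALSE), 15))
  prof <- cnvDeviation(prof, normal)
  clusters <- rep(c("A", "B", "C"), each = 30)
  res <- classifyMalignant(prof, clusters, normal)
  calls <- setNames(res$calls$call, res$calls$cluster)
  expect_equal(unname(calls["A"]), "non-malignant")
  expect_equal(unname(calls["B"]), "malignant")
  expect_equal(unname(calls["C"]), "non-malignant")  # mixing criterion
  expect_equal(sum(res$malignant), 30)
})

test_that("absent normal cells trigger the flagged fallback", {
  W <- 5
  m <- matrix(rnorm(40 * W, sd = 0.05), nrow = 40)
  m[21:40, ] <- m[21:40, ] + 1
  rownames(m) <- sprintf("c%03d", 1:40)
  prof <- methods::new("CnvProfile",
                       windows = data.frame(chrom = "chr1",
                                            start = 1:W, end = 2:(W + 1),
                                            n_genes = rep(25, W)),
                       matrix = m)
  prof <- cnvDeviation(prof, c(rep(TRUE, 20), rep(FALSE, 20)))
  expect_warning(
    res <- classifyMalignant(prof, rep(c("A", "B"), each = 20),
                             rep(FALSE, 40)),
    "no normal-mucosa")
  expect_true(res$fallback)
  expect_error(
    classifyMalignant(prof, rep(c("A", "B"), each = 20), rep(FALSE, 40),
                      requireNormal = TRUE),
    "cannot anchor")
})

test_that("malignancy calls recover the planted truth on the clone cohort", {
  sce <- cnvCloneCohort(2)
  truth <- groundTruth(sce)
  epi <- sce[, sce$lineage == "epithelial"]
  prof <- cnvDeviation(smoothGenomic(epi), epi$pathology == "normal")
  cl <- clusterCells(epi, seed = 2)
  res <- classifyMalignant(prof, cl, epi$pathology == "normal")
  mt <- truth$malignant[colnames(epi)]
  sens <- mean(res$malignant[mt])
  spec <- mean(!res$malignant[!mt])
  expect_gt((sens + spec) / 2, 0.95)
})
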
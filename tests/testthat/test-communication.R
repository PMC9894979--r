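twoTypeToy <- function() {
  # tumor cells express only the ligand, T cells only the receptor
  m <- matrix(0, nrow = 3, ncol = 8,
              dimnames = list(c("LIG", "REC", "OTHER"),
                              sprintf("c%02d", 1:8)))
  m["LIG", 1:4] <- 2.0
  m["REC", 5:8] <- 1.5
  m["OTHER", ] <- 1
  list(m = m, types = rep(c("tumor", "tcell"), each = 4),
       pairs = data.frame(ligand = "LIG", receptor = "REC"))
}

test_that("the two-type toy yields weight 3.0 and specificity 1.0", {
  toy <- twoTypeToy()
  e <- extractEdges(toy$m, toy$types, toy$pairs, detect = 0.2)
  expect_equal(nrow(e), 1)
  expect_equal(e$sender, "tumor")
  expect_equal(e$receiver, "tcell")
  expect_equal(e$weight, 3.0, tolerance = 1e-12)
  expect_equal(e$specificity, 1.0, tolerance = 1e-12)
})

test_that("the detection threshold gates edges", {
  toy <- twoTypeToy()
  # ligand detected in only 1/4 sender cells: below the 0.2 default? no —
  # 0.25 passes; push to 0/4 after raising the threshold instead
  m <- toy$m
  m["LIG", 2:4] <- 0  # detection fraction 0.25 in tumor
  e <- extractEdges(m, toy$types, toy$pairs, detect = 0.2)
  expect_equal(nrow(e), 1)
  e2 <- extractEdges(m, toy$types, toy$pairs, detect = 0.3)
  expect_equal(nrow(e2), 0)
  # ligand absent from the sender: no edge at any threshold
  m["LIG", 1:4] <- 0
  m["LIG", 5] <- 1   # expressed only in the receiver type
  e3 <- extractEdges(m, toy$types, toy$pairs, detect = 0.2)
  expect_false(any(e3$sender == "tumor" & e3$ligand == "LIG"))
  expect_error(extractEdges(toy$m, toy$types, toy$pairs[0, ]), "empty")
})

test_that("ligand specificity shares sum to one across senders", {
  set.seed(21)
  m <- matrix(rexp(4 * 60), nrow = 4,
              dimnames = list(c("L1", "R1", "L2", "R2"),
                              sprintf("c%02d", 1:60)))
  types <- rep(c("a", "b", "c"), each = 20)
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  e <- extractEdges(m, types, pairs, detect = 0)
  tys <- c("a", "b", "c")
  meanOf <- function(g, ty) mean(m[g, types == ty])
  for (p in 1:2) {
    lig <- pairs$ligand[p]; rec <- pairs$receptor[p]
    ligShare <- vapply(tys, function(ty)
      meanOf(lig, ty) / sum(vapply(tys, meanOf, numeric(1), g = lig)),
      numeric(1))
    recShare <- vapply(tys, function(ty)
      meanOf(rec, ty) / sum(vapply(tys, meanOf, numeric(1), g = rec)),
      numeric(1))
    expect_equal(sum(ligShare), 1, tolerance = 1e-12)
    for (snd in tys) for (rcv in tys) {
      row <- e[e$ligand == lig & e$sender == snd & e$receiver == rcv, ]
      expect_equal(row$specificity, ligShare[[snd]] * recShare[[rcv]],
                   tolerance = 1e-12)
      expect_equal(row$weight, meanOf(lig, snd) * meanOf(rec, rcv),
                   tolerance = 1e-12)
    }
  }
})

test_that("weights ignore cell order and type duplication", {
  toy <- twoTypeToy()
  e1 <- extractEdges(toy$m, toy$types, toy$pairs)
  ord <- sample(ncol(toy$m))
  e2 <- extractEdges(toy$m[, ord], toy$types[ord], toy$pairs)
  expect_equal(e1$weight, e2$weight)
  # duplicating every sender cell leaves the mean untouched
  m3 <- cbind(toy$m, toy$m[, 1:4])
  t3 <- c(toy$types, rep("tumor", 4))
  e3 <- extractEdges(m3, t3, toy$pairs)
  expect_equal(e3$weight, e1$weight, tolerance = 1e-12)
})

test_that("edge differences are exact and antisymmetric", {
  toy <- twoTypeToy()
  a <- extractEdges(toy$m, toy$types, toy$pairs)
  d0 <- diffEdges(a, a)
  expect_true(all(d0$delta == 0))
  b <- a
  b$weight <- b$weight * 2
  d1 <- diffEdges(a, b)
  d2 <- diffEdges(b, a)
  expect_equal(d1$delta, -d2$delta)
  expect_equal(d1$log_ratio, -d2$log_ratio, tolerance = 1e-12)
})

test_that("a planted ligand boost ranks its edges on top", {
  samp <- data.frame(sample_id = c("N1", "T1"),
                     pathology = c("normal", "DGC"),
                     immune_class = c(NA, "rich"))
  pairs <- readLRPairs()
  mkEdges <- function(fold, seed) {
    sce <- simulateCohort(
      cohortConfig(nCellsPerSample = 300, nGenes = 800, samples = samp,
                   lrLigandFold = fold), seed = seed)
    sce <- logNormalize(qcFilter(sce))
    truth <- groundTruth(sce)
    types <- sce$lineage
    types[truth$malignant[colnames(sce)]] <- "malignant"
    extractEdges(sce, types, pairs, detect = 0.2)
  }
  for (s in 1:2) {
    d <- diffEdges(mkEdges(6, s), mkEdges(1, s))
    topPairs <- head(d[d$sender == "malignant", ], 4)
    expect_true(all(topPairs$delta > 0))
    expect_true(any(topPairs$ligand %in%
                      c("LGALS3", "CEACAM1", "NECTIN4", "HLA-B")))
  }
})

test_that("the bundled pair table carries the exhaustion pairs", {
  pairs <- readLRPairs()
  expect_true(all(c("ligand", "receptor") %in% colnames(pairs)))
  key <- paste(pairs$ligand, pairs$receptor, sep = "-")
  expect_true(all(c("LGALS3-LAG3", "CEACAM1-HAVCR2", "NECTIN4-TIGIT",
                    "HLA-B-KLRD1", "MYL9-CD69", "TNFSF10-TNFRSF11B")
                  %in% key))
})
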
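test_that("gene aggregation is length-scaled and rescales to library size", {
  txome <- make_txome(c(T1 = rand_seq(500, 91), T2 = rand_seq(500, 92),
                        T3 = rand_seq(500, 93)),
                      gene = c("G1", "G1", "G2"))
  m <- cbind(A_1 = c(100, 300, 999600))
  rownames(m) <- c("T1", "T2", "T3")
  tpm <- abundanceTable(m, sample = "A", unit = "TPM")
  gt <- aggregateToGene(tpm, txome, librarySize = 5000, readLength = 50)
  gm <- abundanceMatrix(gt)
  # equal lengths: gene signal proportional to 400 vs 999600
  expect_equal(gm["G1", 1] / gm["G2", 1], 400 / 999600, tolerance = 1e-12)
  expect_equal(sum(gm[, 1]), 5000, tolerance = 5000 * 1e-6)
  expect_equal(abundanceUnit(gt), "count_scale")
  # single-transcript genes preserve rank order
  m2 <- cbind(A_1 = c(5e5, 3e5, 2e5))
  rownames(m2) <- c("T1", "T2", "T3")
  t2 <- abundanceTable(m2, sample = "A", unit = "TPM")
  one <- make_txome(c(T1 = rand_seq(400, 94), T2 = rand_seq(400, 95),
                      T3 = rand_seq(400, 96)),
                    gene = c("G1", "G2", "G3"))
  g2 <- abundanceMatrix(aggregateToGene(t2, one, librarySize = 1000))
  expect_equal(order(g2[c("G1", "G2", "G3"), 1]), order(m2[, 1]))
  bad <- abundanceTable(cbind(A_1 = c(1e6)), sample = "A", unit = "TPM")
  rownames(bad) <- "nope"
  expect_error(aggregateToGene(bad, one, librarySize = 10), "unknown")
})

test_that("detection threshold is strict at TPM 0.1", {
  expect_true(detect(0.2))
  expect_false(detect(0.1))
  expect_false(detect(0))
  expect_identical(detect(c(0.05, 0.1, 0.100001, 5)),
                   c(FALSE, FALSE, TRUE, TRUE))
})

test_that("the DE test matches hand arithmetic and degenerate cases", {
  # identical replicate vectors on both sides
  same <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 3)
  res <- deTest(same, same)
  expect_equal(unname(res$log2fc), rep(0, 3))
  expect_equal(unname(res$p_value), rep(1, 3))
  # CPM means 400 vs 100 with negligible variance: log2(400.5/100.5)
  a <- matrix(rep(c(400, 999600), 3), nrow = 2)
  b <- matrix(rep(c(100, 999900), 3), nrow = 2)
  rownames(a) <- rownames(b) <- c("g", "rest")
  # library size 1e6 so counts are CPM
  r <- deTest(a, b)
  expect_equal(unname(r["g", "log2fc"]), log2(400.5 / 100.5),
               tolerance = 1e-9)
  expect_equal(unname(r["g", "log2fc"]), 1.995, tolerance = 1e-3)
  expect_error(deTest(a[, 1, drop = FALSE], b), "2 replicates")
})

test_that("null type-I error of the DE test is near nominal", {
  n <- 5000
  withr::with_seed(97, {
    mus <- exp(stats::runif(n, log(20), log(2000)))
    counts_a <- t(vapply(mus, function(m)
      stats::rnbinom(3, mu = m, size = 100), numeric(3)))
    counts_b <- t(vapply(mus, function(m)
      stats::rnbinom(3, mu = m, size = 100), numeric(3)))
  })
  res <- deTest(counts_a, counts_b)
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("the expected C/D fold-change model evaluates correctly", {
  # fold change of 1 maps to 0 for any z
  for (z in c(0.5, 1, 1.43, 5))
    expect_equal(expectedCdLog2fc(0, z), 0)
  # direct evaluation oracle at z = 1.43: k1 = 4.29/5.29, k2 = 1.43/4.43
  k1v <- 3 * 1.43 / (3 * 1.43 + 1)
  k2v <- 1.43 / (1.43 + 3)
  oracle <- function(l2) log2(k1v * 2^l2 + 1 - k1v) -
    log2(k2v * 2^l2 + 1 - k2v)
  expect_equal(expectedCdLog2fc(2, 1.43), oracle(2), tolerance = 1e-12)
  expect_equal(expectedCdLog2fc(2, 1.43), 0.802, tolerance = 1e-3)
  expect_equal(expectedCdLog2fc(-2, 1.43), -0.952, tolerance = 1e-3)
  # the design object supplies the same constants
  expect_equal(expectedCdLog2fc(2, titrationDesign(z = 1.43)),
               expectedCdLog2fc(2, 1.43))
  # monotone increasing in the A/B fold change
  grid <- expectedCdLog2fc(seq(-6, 6, by = 0.25), 1.43)
  expect_true(all(diff(grid) > 0))
  expect_warning(expectedCdLog2fc(c(1, NA), 1.43), "non-finite")
  expect_error(expectedCdLog2fc(1, z = -1), "positive")
})

test_that("R-squared follows its model-comparison definition", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(rSquared(c(1, 2, 3), c(10, 10, 10)), -96)
  expect_error(rSquared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(rSquared(1, 1), "2 observations")
  # agreement with an independent reimplementation under shifts
  withr::with_seed(98, {
    for (i in 1:10) {
      y <- stats::rnorm(20); f <- stats::rnorm(20)
      expect_equal(rSquared(y, f), naive_r2(y, f))
      const <- stats::runif(1, -5, 5)
      expect_equal(rSquared(y + const, f + const),
                   naive_r2(y + const, f + const))
    }
  })
})

test_that("RMSE is the root mean squared difference and is symmetric", {
  expect_equal(rmse(c(5, 5), c(5, 5)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(1, 2), c(2, 4)), sqrt(5 / 2))
  expect_equal(rmse(c(1, 2), c(2, 4)), 1.5811, tolerance = 1e-4)
  withr::with_seed(99, {
    x <- stats::rnorm(15); yv <- stats::rnorm(15)
    expect_equal(rmse(x, yv), rmse(yv, x))
  })
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("ROC/AUC implements the Mann-Whitney tie convention", {
  expect_equal(rocAuc(c(0.001, 0.002, 0.5, 0.9),
                      c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(rocAuc(rep(0.2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                     FALSE))$auc, 0.5)
  expect_equal(rocAuc(c(0.01, 0.2, 0.05), c(TRUE, TRUE, FALSE))$auc, 0.5)
  expect_error(rocAuc(c(0.1, 0.2), c(TRUE, TRUE)), "negative")
  # inverting p-values flips the AUC when there are no ties
  withr::with_seed(100, {
    p <- stats::runif(40)
    truth <- rep(c(TRUE, FALSE), 20)
    a1 <- rocAuc(p, truth)$auc
    a2 <- rocAuc(1 - p, truth)$auc
    expect_equal(a1, 1 - a2)
  })
  # ROC points are monotone and span [0, 1]
  pts <- rocAuc(c(0.01, 0.2, 0.05, 0.3), c(TRUE, FALSE, TRUE, FALSE))$points
  expect_false(is.unsorted(pts$fpr))
  expect_false(is.unsorted(pts$tpr))
  expect_equal(range(pts$fpr), c(0, 1))
  # independent check against pROC on a random instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    withr::with_seed(101, {
      p <- stats::runif(60)
      truth <- stats::runif(60) < 0.4
    })
    ours <- rocAuc(p, truth)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                          predictor = p, quiet = TRUE,
                                          direction = ">")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("stratification yields the documented group structure", {
  withr::with_seed(102, {
    genes <- data.frame(
      mean_expression = stats::rlnorm(100),
      gene_length = sample(100:3000, 100),
      gene_type = sample(c("protein_coding", "tRNA", "ERCC"), 100, TRUE),
      row.names = sprintf("G%03d", 1:100))
  })
  st <- stratify(genes, by = "mean_expression")
  expect_equal(lengths(st)[c("Total RNA", "Top 1%", "Top 10%", "Top 25%",
                             "Bottom 75%")],
               c("Total RNA" = 100L, "Top 1%" = 1L, "Top 10%" = 10L,
                 "Top 25%" = 25L, "Bottom 75%" = 75L))
  expect_true(all(st[["Top 1%"]] %in% st[["Top 10%"]]))
  expect_length(intersect(st[["Top 25%"]], st[["Bottom 75%"]]), 0L)
  # length quartiles partition the gene set
  lt <- stratify(genes, by = "gene_length")
  expect_length(lt, 4L)
  expect_setequal(unlist(lt), rownames(genes))
  expect_equal(sum(lengths(lt)), 100L)
  # 8 genes: four groups of 2
  l8 <- stratify(genes[1:8, ], by = "gene_length")
  expect_true(all(lengths(l8) == 2L))
  # type scheme uses display labels
  ty <- stratify(genes, by = "gene_type")
  expect_true(all(c("Protein coding", "tRNA", "ERCC") %in% names(ty)))
  expect_error(stratify(genes, by = "banana"))
})

test_that("the fold-change table assembles measurements, model and annotation", {
  txome <- buildTranscriptome(transcriptomeConfig(
    nProteinCoding = 5, nErcc = 4, nTrna = 2, nSnoRna = 0, nRrna = 0,
    nOtherNc = 0, nIsoformGenes = 1), seed = 103)
  design <- titrationDesign()
  ab <- makeAbAbundances(txome, design, seed = 103)$abundance
  tpm <- toTPM(mixTitration(ab, design))
  cnt <- simulateReplicateCounts(tpm, txLengths(txome), depth = 20000,
                                 seed = 104)
  m <- abundanceMatrix(cnt)
  gm <- rowsum(m, geneOf(txome, rownames(m)))
  gm <- rbind(gm, dead_gene = 0)
  gt <- abundanceTable(gm, sample = colData(cnt)$sample,
                       replicate = colData(cnt)$replicate, unit = "count",
                       readLength = 50L)
  ann <- geneAnnotation(txome)
  ann <- rbind(ann, dead_gene = data.frame(gene_type = "protein_coding",
                                           gene_length = 100,
                                           anticodon = NA))
  expect_message(fc <- foldChangeTable(gt, ann, design), "excluded")
  expect_false("dead_gene" %in% rownames(fc))
  expect_identical(attr(fc, "excluded"), "dead_gene")
  expect_equal(nrow(fc), nrow(gm) - 1L)
  expect_equal(fc$expected_log2fc_CD,
               expectedCdLog2fc(fc$measured_log2fc_AB, design))
  expect_true(all(fc$p_AB >= 0 & fc$p_AB <= 1))
  # multi-transcript gene length = longest transcript
  iso_gene <- "PCG_001"
  expect_equal(ann[iso_gene, "gene_length"],
               max(txLengths(txome)[geneIds(txome) == iso_gene]))
})
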
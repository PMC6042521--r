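test_that("default transcriptome carries 92 spike-ins and valid records", {
  txome <- buildTranscriptome(seed = 1)
  type <- geneTypes(txome)
  expect_equal(sum(type == "ERCC"), 92L)
  len <- txLengths(txome)
  expect_true(all(len[type == "ERCC"] >= 250 & len[type == "ERCC"] <= 2000))
  expect_true(all(len[type == "tRNA"] >= 60 & len[type == "tRNA"] <= 100))
  expect_false(anyDuplicated(transcriptIds(txome)) > 0)
  mp <- modPositions(txome)
  for (i in seq_along(mp)) {
    p <- mp[[i]]
    if (length(p)) {
      expect_true(all(p >= 1 & p <= len[i]))
      expect_false(is.unsorted(p, strictly = TRUE))
    }
  }
  expect_true(all(!is.na(anticodons(txome)[type == "tRNA"])))
  expect_true(all(is.na(anticodons(txome)[type != "tRNA"])))
})

test_that("transcriptome generation is deterministic and validates config", {
  cfg <- transcriptomeConfig(nProteinCoding = 5, nErcc = 8, nTrna = 2,
                             nSnoRna = 0, nRrna = 0, nOtherNc = 0,
                             nIsoformGenes = 2)
  t1 <- buildTranscriptome(cfg, seed = 7)
  t2 <- buildTranscriptome(cfg, seed = 7)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeTranscriptome(t1, f1); writeTranscriptome(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t3 <- buildTranscriptome(cfg, seed = 8)
  expect_false(identical(as.character(sequences(t1)),
                         as.character(sequences(t3))))
  # no tRNAs: no modification sites, no anticodons anywhere
  t0 <- buildTranscriptome(transcriptomeConfig(nTrna = 0, nErcc = 4,
                                               nProteinCoding = 3,
                                               nSnoRna = 0, nRrna = 0,
                                               nOtherNc = 0,
                                               nIsoformGenes = 0), seed = 1)
  expect_true(all(lengths(modPositions(t0)) == 0))
  expect_true(all(is.na(anticodons(t0))))
  expect_error(transcriptomeConfig(nTrna = -1), "nonnegative")
  expect_error(transcriptomeConfig(pcLengthRange = c(3000, 500)),
               "increasing")
})

test_that("FASTA round trip preserves ids, genes, types and anticodons", {
  txome <- buildTranscriptome(transcriptomeConfig(
    nProteinCoding = 4, nErcc = 4, nTrna = 3, nSnoRna = 1, nRrna = 1,
    nOtherNc = 1, nIsoformGenes = 1), seed = 3)
  fa <- tempfile(fileext = ".fa")
  writeTranscriptome(txome, fa)
  back <- readTranscriptome(fa)
  expect_identical(transcriptIds(back), transcriptIds(txome))
  expect_identical(unname(geneIds(back)), unname(geneIds(txome)))
  expect_identical(unname(geneTypes(back)), unname(geneTypes(txome)))
  expect_identical(unname(anticodons(back)), unname(anticodons(txome)))
  expect_identical(as.character(sequences(back)),
                   as.character(sequences(txome)))
})

test_that("spike-in groups are equal-sized with the designed truth labels", {
  design <- titrationDesign()
  txome <- buildTranscriptome(seed = 1)
  ed <- assignErccDesign(txome, design, seed = 5)
  expect_equal(nrow(ed), 92L)
  expect_true(all(table(ed$group) == 23L))
  expect_equal(sum(ed$is_de), 69L)
  expect_setequal(ed$transcript_id,
                  transcriptIds(txome)[geneTypes(txome) == "ERCC"])
  # minimal case: 4 spike-ins in 4 groups
  ed4 <- assignErccDesign(paste0("E", 1:4), design, seed = 1)
  expect_true(all(table(ed4$group) == 1L))
  expect_equal(sum(ed4$is_de), 3L)
  expect_error(assignErccDesign(paste0("E", 1:6), design, seed = 1),
               "remainder 2")
})

test_that("A/B abundances respect z, spike-in ratios and ratio spread", {
  design <- titrationDesign(z = 1.43)
  txome <- buildTranscriptome(seed = 2)
  res <- makeAbAbundances(txome, design, seed = 9)
  a <- sampleMatrix(res$abundance, "A")[, 1]
  b <- sampleMatrix(res$abundance, "B")[, 1]
  expect_equal(sum(a) / sum(b), 1.43, tolerance = 1e-12)
  # the global rescale to z multiplies sample A by one common factor, so
  # within-design ratios are preserved exactly: the 1:1 group shares a
  # single A:B ratio and the other groups sit at their designed
  # multiples of it
  one <- res$erccDesign$transcript_id[res$erccDesign$ratio == 1]
  r1 <- a[one] / b[one]
  expect_equal(unname(r1), rep(unname(r1[1]), length(one)))
  four <- res$erccDesign$transcript_id[res$erccDesign$ratio == 4]
  expect_equal(unname(a[four] / b[four] / r1[1]), rep(4, length(four)))
  non_ercc <- transcriptIds(txome)[geneTypes(txome) != "ERCC"]
  spread <- max(a[non_ercc] / b[non_ercc]) / min(a[non_ercc] / b[non_ercc])
  expect_gt(spread, 10)  # ratios span more than one order of magnitude
  expect_error(titrationDesign(z = 0), "positive")
})

test_that("titration mixing follows the 3:1 / 1:3 arithmetic", {
  design <- titrationDesign(z = 5 / 2)
  mat <- cbind(A_1 = c(4, 1), B_1 = c(1, 1))
  rownames(mat) <- c("T1", "T2")
  ab <- abundanceTable(mat, sample = c("A", "B"),
                       unit = "molar_per_unit_mass")
  mixed <- mixTitration(ab, design)
  expect_equal(unname(sampleMatrix(mixed, "C")[, 1]), c(13, 4))
  expect_equal(unname(sampleMatrix(mixed, "D")[, 1]), c(7, 4))
  # a_i = b_i forces c_i = d_i
  expect_equal(sampleMatrix(mixed, "C")["T2", ],
               sampleMatrix(mixed, "D")["T2", ], ignore_attr = TRUE)
  expect_error(mixTitration(abundanceTable(mat, sample = c("A", "C"),
                                           unit = "molar_per_unit_mass"),
                            design), "samples A and B")
})

test_that("TPM-space titration identity holds to 1e-9 for any seed", {
  design <- titrationDesign()
  for (seed in c(1, 12, 123)) {
    txome <- buildTranscriptome(seed = seed)
    ab <- makeAbAbundances(txome, design, seed = seed)$abundance
    tpm <- toTPM(mixTitration(ab, design))
    m <- abundanceMatrix(tpm)
    measured_ab <- log2(m[, "A_1"] / m[, "B_1"])
    measured_cd <- log2(m[, "C_1"] / m[, "D_1"])
    predicted <- expectedCdLog2fc(measured_ab, design)
    expect_lt(max(abs(predicted - measured_cd)), 1e-9)
  }
})

test_that("TPM conversion normalizes molar values and counts correctly", {
  m <- cbind(A_1 = c(3, 3))
  rownames(m) <- c("T1", "T2")
  tab <- abundanceTable(m, sample = "A", unit = "molar_per_unit_mass")
  expect_equal(unname(abundanceMatrix(toTPM(tab))[, 1]), c(5e5, 5e5))
  cm <- cbind(A_1 = c(30, 10))
  rownames(cm) <- c("T1", "T2")
  ct <- abundanceTable(cm, sample = "A", unit = "count", readLength = 50L)
  lens <- c(T1 = 500L, T2 = 500L)
  expect_equal(unname(abundanceMatrix(toTPM(ct, lengths = lens))[, 1]),
               c(750000, 250000))
  # normalization contract over random tables
  withr::with_seed(4, {
    for (i in 1:5) {
      rm <- matrix(stats::runif(12, 0.1, 10), 4, 3,
                   dimnames = list(paste0("T", 1:4), NULL))
      rt <- abundanceTable(rm, sample = c("A", "B", "C"),
                           unit = "molar_per_unit_mass")
      cs <- colSums(abundanceMatrix(toTPM(rt)))
      expect_true(all(abs(cs - 1e6) <= 1))
    }
  })
  zm <- cbind(A_1 = c(0, 0)); rownames(zm) <- c("T1", "T2")
  expect_error(toTPM(abundanceTable(zm, sample = "A",
                                    unit = "molar_per_unit_mass")),
               "all-zero")
})

test_that("replicate counts have the declared mean structure", {
  m <- cbind(A_1 = c(8e5, 2e5))
  rownames(m) <- c("T1", "T2")
  tpm <- abundanceTable(m, sample = "A", unit = "TPM")
  lens <- c(T1 = 1049L, T2 = 1049L)  # equal effective lengths
  # dispersion 0, single transcript: the whole depth lands on it exactly
  one <- abundanceTable(cbind(A_1 = 1e6), sample = "A", unit = "TPM")
  rownames(one) <- "T1"
  cnt1 <- simulateReplicateCounts(one, c(T1 = 500L), depth = 1e6,
                                  dispersion = 0, nReplicates = 2, seed = 1)
  expect_true(all(abundanceMatrix(cnt1) == 1e6))
  # law of large numbers: replicate means near mu within 3 se
  cnt <- simulateReplicateCounts(tpm, lens, depth = 10000, dispersion = 0.01,
                                 nReplicates = 1000, seed = 2)
  x <- abundanceMatrix(cnt)[1, ]
  mu <- 8000
  se <- sqrt((mu + 0.01 * mu^2) / 1000)
  expect_lt(abs(mean(x) - mu), 3 * se)
  # determinism
  c1 <- simulateReplicateCounts(tpm, lens, depth = 5000, seed = 11)
  c2 <- simulateReplicateCounts(tpm, lens, depth = 5000, seed = 11)
  expect_identical(abundanceMatrix(c1), abundanceMatrix(c2))
})

test_that("simulated reads are faithful substrings when error-free", {
  txome <- buildTranscriptome(transcriptomeConfig(
    nProteinCoding = 3, nErcc = 4, nTrna = 2, nSnoRna = 0, nRrna = 0,
    nOtherNc = 0, nIsoformGenes = 0), seed = 5)
  ab <- makeAbAbundances(txome, titrationDesign(), seed = 5)$abundance
  rs <- simulateReads(txome, ab, "A", 1, nReads = 200, readLength = 50,
                      misRate = 0, seqError = 0, seed = 6)
  expect_equal(nrow(errorLog(rs)), 0L)
  seqs <- as.character(sequences(txome))
  info <- readInfo(rs)
  reads <- as.character(readSequences(rs))
  lens <- txLengths(txome)
  for (i in seq_along(reads)) {
    tx <- info$true_transcript_id[i]
    s <- info$true_start[i]
    expect_lte(s + nchar(reads[i]) - 1L, lens[[tx]])
    expect_identical(unname(reads[i]),
                     substr(seqs[[tx]], s, s + nchar(reads[i]) - 1L))
  }
  expect_error(simulateReads(txome, ab, "A", 1, nReads = 0, seed = 1),
               "positive")
})

test_that("misincorporation at covered sites is forced at rate 1", {
  trna <- make_txome(c(tX = rand_seq(75, 41)), gene = "tX", type = "tRNA",
                     anticodon = "AGC", mods = list(c(20L, 30L, 50L)))
  ab <- abundanceTable(cbind(A_1 = 1), sample = "A",
                       unit = "molar_per_unit_mass")
  rownames(ab) <- "tX"
  rs <- simulateReads(trna, ab, "A", 1, nReads = 100, readLength = 75,
                      misRate = 1, seqError = 0, seed = 7)
  el <- as.data.frame(errorLog(rs))
  per_read <- table(el$read_id)
  expect_equal(length(per_read), 100L)
  expect_true(all(per_read >= 3))
  expect_true(all(el$cause == "modification"))
  expect_setequal(unique(el$pos), c(20L, 30L, 50L))
})

test_that("observed per-site substitution frequency matches misRate", {
  trna <- make_txome(c(tX = rand_seq(75, 42)), gene = "tX", type = "tRNA",
                     anticodon = "AGC", mods = list(c(20L, 30L, 50L)))
  ab <- abundanceTable(cbind(A_1 = 1), sample = "A",
                       unit = "molar_per_unit_mass")
  rownames(ab) <- "tX"
  n <- 10000
  rs <- simulateReads(trna, ab, "A", 1, nReads = n, readLength = 75,
                      misRate = 0.8, seqError = 0, seed = 8)
  el <- as.data.frame(errorLog(rs))
  for (site in c(20L, 30L, 50L)) {
    phat <- sum(el$pos == site) / n
    se <- sqrt(0.8 * 0.2 / n)
    expect_lt(abs(phat - 0.8), 3 * se)
  }
})

test_that("read simulation and FASTQ output are byte-deterministic", {
  txome <- buildTranscriptome(transcriptomeConfig(
    nProteinCoding = 2, nErcc = 4, nTrna = 1, nSnoRna = 0, nRrna = 0,
    nOtherNc = 0, nIsoformGenes = 0), seed = 5)
  ab <- makeAbAbundances(txome, titrationDesign(), seed = 5)$abundance
  r1 <- simulateReads(txome, ab, "B", 1, nReads = 150, misRate = 0.5,
                      seqError = 0.01, seed = 9)
  r2 <- simulateReads(txome, ab, "B", 1, nReads = 150, misRate = 0.5,
                      seqError = 0.01, seed = 9)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  writeReadsFastq(r1, f1); writeReadsFastq(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- readReadsFastq(f1)
  expect_identical(as.character(back), as.character(readSequences(r1)))
})
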
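#' @include AllClasses.R AllGenerics.R utils.R abundance.R design.R
NULL

#' Aggregate transcript TPM to gene-level count-scale values
#'
#' Gene signal is the sum over the gene's transcripts of TPM times
#' effective length (undoing the length normalization so genes are on the
#' count scale), rescaled per library to the stated library size. This is
#' the summation analogue of length-scaled transcript-to-gene count
#' conversion used upstream of differential-expression callers.
#'
#' @param tpm An [AbundanceTable-class] with unit `TPM` over transcripts.
#' @param txome A [TranscriptomeSet-class] (transcript-to-gene map and
#'   lengths).
#' @param librarySize Total reads per library (scalar or one per column).
#' @param readLength Read length for effective lengths (default 50).
#' @return An [AbundanceTable-class] over genes with unit `count_scale`.
#' @export
aggregateToGene <- function(tpm, txome, librarySize, readLength = 50L) {
  if (abundanceUnit(tpm) != "TPM") stop("input must be in TPM")
  m <- abundanceMatrix(tpm)
  unknown <- setdiff(rownames(m), transcriptIds(txome))
  if (length(unknown))
    stop("unknown transcript(s): ", paste(unknown, collapse = ", "))
  ef <- effectiveLength(txLengths(txome)[rownames(m)], readLength)
  genes <- geneOf(txome, rownames(m))
  sig <- rowsum(m * ef, genes)
  cs <- colSums(sig)
  librarySize <- rep_len(librarySize, ncol(sig))
  scaled <- sweep(sig, 2L, ifelse(cs > 0, librarySize / cs, 0), "*")
  abundanceTable(scaled, sample = colData(tpm)$sample,
                 replicate = colData(tpm)$replicate, unit = "count_scale",
                 readLength = as.integer(readLength))
}

#' Detection rule
#'
#' A gene is detected when its TPM strictly exceeds 0.1; exactly 0.1 is
#' not detected.
#'
#' @param tpm Numeric vector of TPM values.
#' @param threshold Detection threshold (default 0.1).
#' @return Logical vector.
#' @export
detect <- function(tpm, threshold = 0.1) tpm > threshold

#' Two-group differential expression test
#'
#' Log2 fold change is the difference of mean `log2(CPM + 0.5)` between
#' the two groups (the 0.5 pseudocount keeps genes with zero counts on
#' one side finite); the p-value is a two-sided Welch two-sample t-test
#' on the same transformed values. When both groups have zero variance
#' the p-value is 1 for equal means and 0 otherwise.
#'
#' @param countsA,countsB Numeric matrices (genes x replicates, >= 2
#'   replicates each) of counts or count-scale values for the two groups.
#' @return A [S4Vectors::DataFrame] per gene: `log2fc` (A over B),
#'   `p_value`.
#' @export
deTest <- function(countsA, countsB) {
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  if (ncol(countsA) < 2L || ncol(countsB) < 2L)
    stop("at least 2 replicates per group are required")
  cpm <- function(m) {
    cs <- colSums(m)
    if (any(cs == 0)) stop("library with zero total count")
    sweep(m, 2L, cs, "/") * 1e6
  }
  la <- log2(cpm(countsA) + 0.5)
  lb <- log2(cpm(countsB) + 0.5)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, stats::var); vb <- apply(lb, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- va + vb == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  DataFrame(log2fc = ma - mb, p_value = p,
            row.names = rownames(countsA))
}

#' Expected C/D log2 fold change from the measured A/B fold change
#'
#' The titration model: with samples C and D mixed from A and B in mass
#' ratios 3:1 and 1:3 and total-signal ratio `z` of A to B,
#' `log2(C/D) = log2(k1 r + (1 - k1)) - log2(k2 r + (1 - k2))` where
#' `r` is the measured A/B fold change (supplied on the log2 scale),
#' `k1 = 3z/(3z+1)` and `k2 = z/(z+3)`. The function is monotone
#' increasing in `r` and maps a fold change of 1 to 0.
#'
#' @param log2fcAB Measured log2(A/B) per gene.
#' @param z Total-signal ratio, or a [TitrationDesign-class] supplying it
#'   (default 1.43).
#' @return Expected log2(C/D), same length as input; non-finite inputs
#'   propagate with a warning.
#' @examples
#' expectedCdLog2fc(0)              # 0 for any z
#' expectedCdLog2fc(2, z = 1.43)    # ~0.802
#' @export
expectedCdLog2fc <- function(log2fcAB, z = 1.43) {
  if (is(z, "TitrationDesign")) {
    kk1 <- k1(z); kk2 <- k2(z)
  } else {
    if (z <= 0) stop("'z' must be positive")
    kk1 <- 3 * z / (3 * z + 1); kk2 <- z / (z + 3)
  }
  if (any(!is.finite(log2fcAB)))
    warning("non-finite log2 fold changes propagate as non-finite")
  r <- 2^log2fcAB
  log2(kk1 * r + (1 - kk1)) - log2(kk2 * r + (1 - kk2))
}

#' Coefficient of determination against a model prediction
#'
#' `R2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2)`, comparing measured
#' values `y` to model-expected values `f`. Unlike a squared correlation
#' this is unbounded below: negative values mean the model prediction
#' fits worse than the constant mean predictor, i.e. highly discordant
#' measurements.
#'
#' @param y Measured values (finite, length >= 2, non-constant).
#' @param f Expected values, same length.
#' @return A single numeric, at most 1.
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 4))    # 0.5
#' rSquared(c(1, 2, 3), c(10, 10, 10)) # -96
#' @export
rSquared <- function(y, f) {
  if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
  if (length(y) < 2L) stop("at least 2 observations are required")
  if (!all(is.finite(y)) || !all(is.finite(f)))
    stop("inputs must be finite")
  denom <- sum((y - mean(y))^2)
  if (denom == 0) stop("constant measurements: zero denominator")
  1 - sum((y - f)^2) / denom
}

#' Root mean square error
#'
#' @param y,f Equal-length numeric vectors (length >= 1).
#' @return `sqrt(mean((y - f)^2))`.
#' @export
rmse <- function(y, f) {
  if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
  if (!length(y)) stop("empty input")
  sqrt(mean((y - f)^2))
}

#' ROC curve and AUC for differential-expression calls
#'
#' Sweeps p-value thresholds and computes the ROC of calling truly DE
#' features; the AUC is the Mann-Whitney probability that a random truly
#' DE feature receives a smaller p-value than a random null feature,
#' with ties counted 1/2.
#'
#' @param p_values Numeric p-values.
#' @param truth Logical vector: `TRUE` for truly differentially expressed.
#' @return A list with `auc` and `points` (a data.frame of `threshold`,
#'   `fpr`, `tpr`).
#' @examples
#' rocAuc(c(0.01, 0.2, 0.05), c(TRUE, TRUE, FALSE))$auc  # 0.5
#' @export
rocAuc <- function(p_values, truth) {
  truth <- as.logical(truth)
  if (length(p_values) != length(truth)) stop("length mismatch")
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("both a positive and a negative label are required")
  r <- rank(p_values)  # ties get average rank, which encodes the 1/2 rule
  u_wrong <- sum(r[truth]) - n1 * (n1 + 1) / 2  # pairs with p_DE > p_null
  auc <- 1 - u_wrong / (n1 * n0)
  th <- c(-Inf, sort(unique(p_values)), Inf)
  pts <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(p_values[!truth] <= t) / n0, 1.0),
    tpr = vapply(th, function(t) sum(p_values[truth] <= t) / n1, 1.0))
  list(auc = auc, points = pts)
}

TYPE_LABELS <- c(protein_coding = "Protein coding", ERCC = "ERCC",
                 tRNA = "tRNA", snoRNA = "snoRNA", rRNA = "rRNA",
                 other_ncRNA = "Other ncRNA")

#' Stratify genes for the evaluation report
#'
#' Three schemes: `mean_expression` yields the overlapping sets
#' "Total RNA" (all genes), "Top 1%", "Top 10%", "Top 25%" and
#' "Bottom 75%" by mean expression; `gene_length` yields four disjoint
#' quartile groups covering all genes; `gene_type` groups by annotated
#' type with display names ("Protein coding", "Other ncRNA", ...).
#' Quantile ties are broken by ascending gene identifier, so strata are
#' deterministic.
#'
#' @param genes A data.frame with rownames = gene ids and (as needed)
#'   columns `mean_expression`, `gene_length`, `gene_type`.
#' @param by One of `"mean_expression"`, `"gene_length"`, `"gene_type"`.
#' @return Named list of character vectors of gene ids.
#' @export
stratify <- function(genes, by = c("mean_expression", "gene_length",
                                   "gene_type")) {
  by <- match.arg(by)
  ids <- rownames(genes)
  n <- length(ids)
  if (by == "mean_expression") {
    if (!"mean_expression" %in% colnames(genes))
      stop("column 'mean_expression' is required")
    ord <- ids[order(-genes$mean_expression, ids)]
    ntop <- function(p) max(1L, as.integer(round(p * n)))
    top25 <- ntop(0.25)
    list("Total RNA" = ids,
         "Top 1%" = ord[seq_len(ntop(0.01))],
         "Top 10%" = ord[seq_len(ntop(0.10))],
         "Top 25%" = ord[seq_len(top25)],
         "Bottom 75%" = ord[setdiff(seq_len(n), seq_len(top25))])
  } else if (by == "gene_length") {
    if (!"gene_length" %in% colnames(genes))
      stop("column 'gene_length' is required")
    ord <- ids[order(genes$gene_length, ids)]
    grp <- ceiling(seq_len(n) * 4 / n)
    out <- split(ord, grp)
    names(out) <- paste0("Length Q", names(out),
                         c(" (shortest)", "", "", " (longest)")[
                           as.integer(names(out))])
    out
  } else {
    if (!"gene_type" %in% colnames(genes))
      stop("column 'gene_type' is required")
    lab <- TYPE_LABELS[genes$gene_type]
    lab[is.na(lab)] <- genes$gene_type[is.na(lab)]
    split(ids, lab)
  }
}

#' Per-gene annotation of a transcriptome
#'
#' Gene type, gene length (length of the longest transcript) and
#' anticodon, one row per gene.
#'
#' @param txome A [TranscriptomeSet-class].
#' @return A data.frame with rownames = gene ids.
#' @export
geneAnnotation <- function(txome) {
  g <- unname(geneIds(txome))
  len <- tapply(unname(txLengths(txome)), g, max)
  type <- tapply(unname(geneTypes(txome)), g, function(x) x[1])
  ac <- tapply(unname(anticodons(txome)), g, function(x) x[1])
  data.frame(gene_type = as.vector(type), gene_length = as.vector(len),
             anticodon = as.vector(ac), row.names = names(len))
}

#' Build the per-gene fold-change table
#'
#' The core evaluation object: per gene, the measured log2(A/B) and its
#' p-value, the measured log2(C/D) and its p-value, the expected
#' log2(C/D) from the titration model applied to the measured A/B fold
#' change, plus gene type, gene length and mean expression. Genes with
#' zero signal in every library are excluded before modeling (their ids
#' are recorded in `attr(, "excluded")`).
#'
#' @param geneTable An [AbundanceTable-class] over genes (unit `count` or
#'   `count_scale`) with samples A-D in replicates.
#' @param annotation A data.frame from [geneAnnotation()].
#' @param design A [TitrationDesign-class] (supplies `z`).
#' @param meanTpm Optional named vector of mean gene TPM used for the
#'   expression strata; computed from `geneTable` when omitted.
#' @return A data.frame (rownames = gene ids) with columns
#'   `measured_log2fc_AB`, `p_AB`, `measured_log2fc_CD`, `p_CD`,
#'   `expected_log2fc_CD`, `gene_type`, `gene_length`,
#'   `mean_expression`.
#' @export
foldChangeTable <- function(geneTable, annotation, design, meanTpm = NULL) {
  m <- abundanceMatrix(geneTable)
  keep <- rowSums(m) > 0
  excluded <- rownames(m)[!keep]
  if (length(excluded))
    message(length(excluded), " gene(s) with zero signal in all libraries excluded")
  m <- m[keep, , drop = FALSE]
  cd <- colData(geneTable)
  grab <- function(s) m[, cd$sample == s, drop = FALSE]
  ab <- deTest(grab("A"), grab("B"))
  cdt <- deTest(grab("C"), grab("D"))
  if (is.null(meanTpm)) {
    glen <- annotation[rownames(m), "gene_length"]
    ef <- effectiveLength(glen, metadata(geneTable)$readLength %||% 50L)
    tpm <- sweep(m / ef, 2L, colSums(m / ef), "/") * 1e6
    meanTpm <- rowMeans(tpm)
  }
  out <- data.frame(
    measured_log2fc_AB = ab$log2fc, p_AB = ab$p_value,
    measured_log2fc_CD = cdt$log2fc, p_CD = cdt$p_value,
    expected_log2fc_CD = expectedCdLog2fc(ab$log2fc, design),
    gene_type = annotation[rownames(m), "gene_type"],
    gene_length = annotation[rownames(m), "gene_length"],
    mean_expression = meanTpm[rownames(m)],
    row.names = rownames(m))
  attr(out, "excluded") <- excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
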
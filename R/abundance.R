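#' @include AllClasses.R AllGenerics.R utils.R design.R
NULL

#' Construct an AbundanceTable
#'
#' @param mat Numeric matrix, features in rows (named), libraries in
#'   columns.
#' @param sample Character vector of sample labels, one per column.
#' @param replicate Integer vector of replicate indices, one per column.
#' @param unit Declared unit (see [AbundanceTable-class]).
#' @param ... Extra metadata stored in `metadata()` (e.g. `readLength`).
#' @return An [AbundanceTable-class].
#' @export
abundanceTable <- function(mat, sample, replicate = rep(1L, ncol(mat)),
                           unit, ...) {
  mat <- as.matrix(mat)
  colnames(mat) <- paste(sample, replicate, sep = "_")
  se <- SummarizedExperiment(
    assays = list(abundance = mat),
    colData = DataFrame(sample = sample, replicate = as.integer(replicate),
                        row.names = colnames(mat)))
  md <- list(...)
  out <- new("AbundanceTable", se, unit = unit)
  metadata(out) <- md
  validObject(out)
  out
}

#' @rdname abundanceUnit
#' @export
setMethod("abundanceUnit", "AbundanceTable", function(x, ...) x@unit)

#' Extract the abundance matrix
#'
#' @param x An `AbundanceTable`.
#' @return Numeric matrix, features x libraries.
#' @export
abundanceMatrix <- function(x) SummarizedExperiment::assay(x, "abundance")

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d features x %d libraries [unit: %s]\n",
              nrow(object), ncol(object), object@unit))
  cat("  libraries:", paste(colnames(object), collapse = ", "), "\n")
})

#' Columns of an AbundanceTable belonging to one sample
#'
#' @param x An `AbundanceTable`.
#' @param sample Sample label (e.g. `"A"`).
#' @return The abundance sub-matrix for that sample's replicates.
#' @export
sampleMatrix <- function(x, sample) {
  keep <- colData(x)$sample == sample
  if (!any(keep)) stop("no libraries for sample ", sample)
  abundanceMatrix(x)[, keep, drop = FALSE]
}

#' Generate reference abundances for samples A and B
#'
#' Per-transcript concentrations (molar per unit mass, the space in which
#' mass mixing is linear) are drawn in log space: a log10-uniform base
#' expression level spanning several decades, shifted by
#' gene-type-specific offsets reflecting a total-RNA library in which
#' tRNAs and rRNA are highly represented, and a per-transcript
#' log10-uniform A:B ratio of moderate width (two reference tissues
#' differ by a few fold for most genes, while expression levels span
#' orders of magnitude). ERCC-like spike-ins are instead forced to their
#' designed group A:B ratio. Finally sample A is rescaled globally so
#' that the total-signal ratio `sum(A)/sum(B)` equals the design's `z`
#' exactly, which makes the expected C/D fold-change model an exact
#' identity rather than an approximation.
#'
#' @param txome A [TranscriptomeSet-class].
#' @param design A [TitrationDesign-class].
#' @param seed Integer seed.
#' @param log10Range Range of the log10-uniform base expression draw.
#' @param log10RatioRange Range of the log10-uniform A:B ratio draw
#'   (default spans 1.5 decades of fold change).
#' @param typeOffset Named log10 offsets per gene type (abundance
#'   composition of the library).
#' @return A list with `abundance` (an [AbundanceTable-class] with samples
#'   A and B, unit `molar_per_unit_mass`) and `erccDesign` (the group
#'   assignment from [assignErccDesign()]).
#' @export
makeAbAbundances <- function(txome, design, seed = 1L,
                             log10Range = c(-1.25, 1.25),
                             log10RatioRange = c(-0.75, 0.75),
                             typeOffset = c(protein_coding = 0, ERCC = 0,
                                            tRNA = 3.5, snoRNA = 0.5,
                                            rRNA = 1, other_ncRNA = 0)) {
  z <- zRatio(design)
  if (z <= 0) stop("'z' must be positive")
  ids <- transcriptIds(txome)
  type <- geneTypes(txome)
  off <- typeOffset[type]
  off[is.na(off)] <- 0
  ercc <- assignErccDesign(txome, design, seed = derive_seed(seed, "ercc"))
  with_rng(seed, {
    base <- 10^(stats::runif(length(ids), log10Range[1], log10Range[2]) +
                  off)
    ratio <- 10^stats::runif(length(ids), log10RatioRange[1],
                             log10RatioRange[2])
    a <- base * sqrt(ratio)
    b <- base / sqrt(ratio)
    # force designed spike-in ratios a/b = group ratio
    idx <- match(ercc$transcript_id, ids)
    a[idx] <- base[idx] * sqrt(ercc$ratio)
    b[idx] <- base[idx] / sqrt(ercc$ratio)
    # global rescale: sum(a)/sum(b) = z exactly
    a <- a * z * sum(b) / sum(a)
    mat <- cbind(A_1 = a, B_1 = b)
    rownames(mat) <- ids
    list(abundance = abundanceTable(mat, sample = c("A", "B"),
                                    unit = "molar_per_unit_mass"),
         erccDesign = ercc)
  })
}

#' Mix the titration samples C and D
#'
#' Adds samples C and D as mass mixtures of A and B using the design's
#' mixing weights (defaults 3:1 and 1:3): `c_i = 3 a_i + b_i`,
#' `d_i = a_i + 3 b_i`. Requires molar per-unit-mass input, the space in
#' which mass mixing is linear.
#'
#' @param ab An [AbundanceTable-class] holding samples A and B (unit
#'   `molar_per_unit_mass`).
#' @param design A [TitrationDesign-class].
#' @return An [AbundanceTable-class] with samples A, B, C, D.
#' @export
mixTitration <- function(ab, design) {
  if (abundanceUnit(ab) != "molar_per_unit_mass")
    stop("mixing requires unit molar_per_unit_mass")
  sm <- colData(ab)$sample
  if (!all(c("A", "B") %in% sm)) stop("samples A and B are required")
  a <- sampleMatrix(ab, "A")[, 1L]
  b <- sampleMatrix(ab, "B")[, 1L]
  mat <- cbind(A_1 = a, B_1 = b,
               C_1 = design@mixC[1] * a + design@mixC[2] * b,
               D_1 = design@mixD[1] * a + design@mixD[2] * b)
  abundanceTable(mat, sample = c("A", "B", "C", "D"),
                 unit = "molar_per_unit_mass")
}

#' Convert an abundance table to TPM
#'
#' Molar concentrations are proportions of molecules, so TPM is the column
#' proportion times 1e6. Counts are first divided by the effective length
#' `max(L - readLength + 1, 1)` (counts are proportional to molar
#' abundance times effective length), then normalized.
#'
#' @param x An [AbundanceTable-class] with unit `molar_per_unit_mass`,
#'   `count` or `count_scale`.
#' @param lengths Named vector of transcript (or gene) lengths; required
#'   for count input.
#' @param readLength Read length used for effective lengths of count
#'   input; taken from `metadata(x)$readLength` when present.
#' @return An [AbundanceTable-class] with unit `TPM`.
#' @export
toTPM <- function(x, lengths = NULL, readLength = NULL) {
  m <- abundanceMatrix(x)
  if (abundanceUnit(x) %in% c("count", "count_scale")) {
    if (is.null(readLength)) readLength <- metadata(x)$readLength
    if (is.null(readLength))
      stop("readLength is required to convert counts to TPM")
    if (is.null(lengths)) stop("'lengths' is required for count input")
    ef <- effectiveLength(lengths[rownames(m)], readLength)
    m <- m / ef
  } else if (abundanceUnit(x) == "TPM") {
    return(x)
  }
  cs <- colSums(m)
  if (any(cs == 0))
    stop("cannot normalize an all-zero library: ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  tpm <- sweep(m, 2L, cs, "/") * 1e6
  abundanceTable(tpm, sample = colData(x)$sample,
                 replicate = colData(x)$replicate, unit = "TPM")
}

#' Simulate replicate sequencing counts
#'
#' Expected counts are proportional to TPM times effective length, scaled
#' to the library depth. With `dispersion = 0` each replicate is a
#' multinomial draw of `depth` reads (total fixed exactly); with
#' `dispersion > 0` counts are negative binomial with mean `mu` and
#' variance `mu + dispersion * mu^2`, the standard overdispersed model
#' for replicate RNA-seq libraries.
#'
#' @param tpm An [AbundanceTable-class] with unit `TPM`.
#' @param lengths Named transcript lengths.
#' @param depth Reads per library.
#' @param dispersion Negative binomial dispersion (default 0.01).
#' @param nReplicates Replicates per sample (default 3).
#' @param readLength Read length for effective lengths (default 50).
#' @param seed Integer seed.
#' @return An [AbundanceTable-class] with unit `count`; `metadata()`
#'   carries `readLength` and `depth`.
#' @export
simulateReplicateCounts <- function(tpm, lengths, depth, dispersion = 0.01,
                                    nReplicates = 3L, readLength = 50L,
                                    seed = 1L) {
  stopifnot(depth > 0, dispersion >= 0, nReplicates >= 1L)
  if (abundanceUnit(tpm) != "TPM") stop("input must be in TPM")
  m <- abundanceMatrix(tpm)
  ef <- effectiveLength(lengths[rownames(m)], readLength)
  with_rng(seed, {
    cols <- list(); cn_sample <- character(0); cn_rep <- integer(0)
    for (j in seq_len(ncol(m))) {
      w <- m[, j] * ef
      mu <- w / sum(w) * depth
      for (r in seq_len(nReplicates)) {
        cnt <- if (dispersion == 0) {
          as.integer(stats::rmultinom(1L, size = depth, prob = mu))
        } else {
          stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        }
        cols[[length(cols) + 1L]] <- cnt
        cn_sample <- c(cn_sample, colData(tpm)$sample[j])
        cn_rep <- c(cn_rep, r)
      }
    }
    cmat <- do.call(cbind, cols)
    rownames(cmat) <- rownames(m)
    abundanceTable(cmat, sample = cn_sample, replicate = cn_rep,
                   unit = "count", readLength = as.integer(readLength),
                   depth = as.integer(depth))
  })
}

#' Write / read an abundance table as TSV
#'
#' Long format with header `sample  replicate  transcript_id  value`.
#'
#' @param x An [AbundanceTable-class].
#' @param path TSV path.
#' @param unit Unit to declare when reading.
#' @return `writeAbundanceTable` returns `path` invisibly;
#'   `readAbundanceTable` an [AbundanceTable-class].
#' @export
writeAbundanceTable <- function(x, path) {
  m <- abundanceMatrix(x)
  cd <- colData(x)
  df <- data.frame(
    sample = rep(cd$sample, each = nrow(m)),
    replicate = rep(cd$replicate, each = nrow(m)),
    transcript_id = rep(rownames(m), ncol(m)),
    value = as.vector(m))
  write_tsv(df, path)
  invisible(path)
}

#' @rdname writeAbundanceTable
#' @export
readAbundanceTable <- function(path, unit) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  libs <- unique(df[, c("sample", "replicate")])
  feats <- unique(df$transcript_id)
  m <- matrix(0, nrow = length(feats), ncol = nrow(libs),
              dimnames = list(feats, NULL))
  for (j in seq_len(nrow(libs))) {
    sub <- df[df$sample == libs$sample[j] & df$replicate == libs$replicate[j], ]
    m[sub$transcript_id, j] <- sub$value
  }
  abundanceTable(m, sample = libs$sample, replicate = libs$replicate,
                 unit = unit)
}
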
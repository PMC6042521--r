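#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IntegerList
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

GENE_TYPES <- c("protein_coding", "ERCC", "tRNA", "snoRNA", "rRNA",
                "other_ncRNA")

#' TranscriptomeSet: a toy total-RNA transcriptome
#'
#' Holds transcript sequences together with their gene assignment, gene
#' type, tRNA modification positions and anticodon labels, and a decoy flag
#' (the analogue of haplotype/patch sequences in an assembled genome). This
#' is the unit of simulation and quantification: reads are simulated from
#' it, both quantifiers index or align against it, and the evaluation layer
#' uses its transcript-to-gene map.
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by transcript id.
#' @slot txData A [S4Vectors::DataFrame] with one row per transcript:
#'   `gene_id`, `gene_type` (one of protein_coding, ERCC, tRNA, snoRNA,
#'   rRNA, other_ncRNA), `anticodon` (character, `NA` for non-tRNA),
#'   `is_decoy` (logical), and `mod_positions` (an [IRanges::IntegerList]
#'   of 1-based modification positions, empty for unmodified transcripts).
#'
#' @seealso [buildTranscriptome()], [transcriptIds()], [geneOf()]
#' @export
setClass("TranscriptomeSet",
         representation(sequences = "DNAStringSet", txData = "DataFrame"))

setValidity("TranscriptomeSet", function(object) {
  seqs <- object@sequences
  td <- object@txData
  msgs <- character(0)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "transcript ids must be unique and non-NULL")
  if (length(seqs) != nrow(td))
    msgs <- c(msgs, "sequences and txData must have the same length")
  need <- c("gene_id", "gene_type", "anticodon", "is_decoy", "mod_positions")
  if (!all(need %in% colnames(td)))
    return(paste("txData must have columns:", paste(need, collapse = ", ")))
  if (!all(td$gene_type %in% GENE_TYPES))
    msgs <- c(msgs, "unknown gene_type")
  len <- Biostrings::width(seqs)
  mp <- td$mod_positions
  for (i in seq_along(seqs)) {
    p <- mp[[i]]
    if (length(p)) {
      if (any(p < 1L) || any(p > len[i]))
        msgs <- c(msgs, sprintf("modification positions out of range for %s",
                                ids[i]))
      if (is.unsorted(p, strictly = TRUE))
        msgs <- c(msgs, sprintf("modification positions not strictly increasing for %s",
                                ids[i]))
    }
  }
  bad_trna <- td$gene_type == "tRNA" & (len < 60L | len > 100L)
  if (any(bad_trna))
    msgs <- c(msgs, "tRNA transcripts must be 60-100 nt long")
  bad_ercc <- td$gene_type == "ERCC" & (len < 250L | len > 2000L)
  if (any(bad_ercc))
    msgs <- c(msgs, "ERCC transcripts must be 250-2000 nt long")
  # one gene per transcript is structural (a single gene_id column); check
  # that tRNA records carry an anticodon
  if (any(td$gene_type == "tRNA" & is.na(td$anticodon)))
    msgs <- c(msgs, "tRNA transcripts must carry an anticodon")
  if (length(msgs)) msgs else TRUE
})

#' TitrationDesign: mixing ratios and the expected fold-change model
#'
#' Encodes the titration design: samples C and D are mass mixtures of the
#' reference samples A and B in ratios 3:1 and 1:3, the total-signal ratio
#' `z` of A to B, and the designed A:B ratio of each ERCC spike-in group.
#' The constants of the expected C/D fold-change model are derived from
#' `z`: `k1 = 3z/(3z+1)` and `k2 = z/(z+3)` (see [k1()], [k2()],
#' [expectedCdLog2fc()]).
#'
#' @slot z Positive total-signal ratio of sample A to sample B
#'   (default 1.43).
#' @slot mixC,mixD Numeric mass weights of (A, B) in samples C and D.
#' @slot erccRatios Named numeric vector of designed A:B ratios, one per
#'   spike-in group.
#' @slot erccGroupSize Number of spike-ins per group (default 23).
#' @export
setClass("TitrationDesign",
         representation(z = "numeric", mixC = "numeric", mixD = "numeric",
                        erccRatios = "numeric", erccGroupSize = "integer"))

setValidity("TitrationDesign", function(object) {
  msgs <- character(0)
  if (length(object@z) != 1L || !is.finite(object@z) || object@z <= 0)
    msgs <- c(msgs, "z must be a single positive number")
  if (length(object@mixC) != 2L || length(object@mixD) != 2L ||
      any(c(object@mixC, object@mixD) < 0))
    msgs <- c(msgs, "mix weights must be two nonnegative numbers per sample")
  if (is.null(names(object@erccRatios)) || any(object@erccRatios <= 0))
    msgs <- c(msgs, "erccRatios must be a named vector of positive ratios")
  if (object@erccGroupSize < 1L)
    msgs <- c(msgs, "erccGroupSize must be positive")
  if (length(msgs)) msgs else TRUE
})

#' AbundanceTable: per-sample, per-replicate abundances
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] with a single
#' `abundance` assay (transcripts or genes in rows, libraries in columns),
#' `sample` and `replicate` in `colData`, and a declared unit. Units:
#' `molar_per_unit_mass` (concentrations in which mass mixing is linear),
#' `count` (integer read counts), `count_scale` (length-scaled gene-level
#' signal on the count scale, not necessarily integer), and `TPM`
#' (transcripts per million; each column sums to 1e6).
#'
#' @slot unit One of `"molar_per_unit_mass"`, `"count"`, `"count_scale"`,
#'   `"TPM"`.
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment",
         representation(unit = "character"))

ABUNDANCE_UNITS <- c("molar_per_unit_mass", "count", "count_scale", "TPM")

setValidity("AbundanceTable", function(object) {
  msgs <- character(0)
  if (length(object@unit) != 1L || !object@unit %in% ABUNDANCE_UNITS)
    msgs <- c(msgs, paste("unit must be one of:",
                          paste(ABUNDANCE_UNITS, collapse = ", ")))
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  m <- SummarizedExperiment::assay(object, "abundance")
  if (any(m < 0)) msgs <- c(msgs, "abundances must be nonnegative")
  if (identical(object@unit, "count") && any(m != round(m)))
    msgs <- c(msgs, "counts must be integers")
  if (identical(object@unit, "TPM")) {
    cs <- colSums(m)
    if (any(abs(cs - 1e6) > 1e6 * 1e-6))
      msgs <- c(msgs, "TPM columns must sum to 1e6 (relative tol 1e-6)")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample", "replicate") %in% colnames(cd)))
    msgs <- c(msgs, "colData must have 'sample' and 'replicate'")
  if (length(msgs)) msgs else TRUE
})

#' ReadSet: simulated reads with ground truth
#'
#' Simulated single-end sense-strand reads together with their true source
#' transcript and start coordinate, and a log of every error introduced
#' (modification-induced misincorporations and sequencing errors), so that
#' downstream assignment behaviour can be checked against ground truth.
#'
#' @slot reads A [Biostrings::DNAStringSet] named by read id.
#' @slot info A [S4Vectors::DataFrame] per read: `true_transcript_id`,
#'   `true_start` (1-based on the transcript).
#' @slot errorLog A [S4Vectors::DataFrame] with one row per introduced
#'   error: `read_id`, `pos` (1-based position in the read), `cause`
#'   (`"modification"` or `"sequencing"`).
#' @slot readLength Nominal read length; reads from shorter transcripts are
#'   truncated at the transcript end.
#' @export
setClass("ReadSet",
         representation(reads = "DNAStringSet", info = "DataFrame",
                        errorLog = "DataFrame", readLength = "integer"))

setValidity("ReadSet", function(object) {
  msgs <- character(0)
  if (length(object@reads) != nrow(object@info))
    msgs <- c(msgs, "reads and info must have the same length")
  if (!all(c("true_transcript_id", "true_start") %in% colnames(object@info)))
    msgs <- c(msgs, "info must have true_transcript_id and true_start")
  el <- object@errorLog
  if (nrow(el)) {
    if (any(el$pos < 1L) || any(el$pos > object@readLength))
      msgs <- c(msgs, "error positions must lie within the read")
    if (!all(el$cause %in% c("modification", "sequencing")))
      msgs <- c(msgs, "error cause must be modification or sequencing")
  }
  if (length(msgs)) msgs else TRUE
})

#' KmerIndex: exact k-mer to transcript-set index
#'
#' Maps every length-`k` substring of the indexed transcripts (sense
#' strand) to the set of transcripts containing it, the core data structure
#' of alignment-free quantifiers. Lookup is exact: a k-mer carrying any
#' substitution matches nothing unless it collides with another indexed
#' k-mer.
#'
#' @slot k k-mer size.
#' @slot table An environment mapping k-mer strings to integer vectors of
#'   transcript indices.
#' @slot txIds Transcript identifiers (index space of `table`).
#' @slot txLengths Transcript lengths, parallel to `txIds`.
#' @export
setClass("KmerIndex",
         representation(k = "integer", table = "environment",
                        txIds = "character", txLengths = "integer"))

#' EquivalenceClassCounts: read counts by transcript-compatibility set
#'
#' Reads whose k-mer compatibility sets are identical form one equivalence
#' class; this object maps each class (a nonempty set of transcript ids) to
#' its read count, and tracks reads compatible with no transcript
#' separately as `unassigned`.
#'
#' @slot classes List of character vectors (sorted transcript id sets).
#' @slot counts Integer read count per class.
#' @slot unassigned Number of reads with an empty compatibility set.
#' @export
setClass("EquivalenceClassCounts",
         representation(classes = "list", counts = "integer",
                        unassigned = "integer"))

setValidity("EquivalenceClassCounts", function(object) {
  msgs <- character(0)
  if (length(object@classes) != length(object@counts))
    msgs <- c(msgs, "classes and counts must be parallel")
  if (any(lengths(object@classes) == 0L))
    msgs <- c(msgs, "class keys must be nonempty transcript sets")
  if (any(object@counts <= 0L))
    msgs <- c(msgs, "class counts must be positive")
  if (object@unassigned < 0L)
    msgs <- c(msgs, "unassigned count must be nonnegative")
  if (length(msgs)) msgs else TRUE
})
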
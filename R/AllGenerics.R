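#' @include AllClasses.R
NULL

#' Accessors for TranscriptomeSet
#'
#' `transcriptIds`, `geneIds`, `geneTypes`, `anticodons`, `txLengths` and
#' `modPositions` return per-transcript annotation vectors; `sequences`
#' returns the underlying [Biostrings::DNAStringSet]; `geneOf` maps
#' transcript ids to gene ids.
#'
#' @param x A `TranscriptomeSet`.
#' @param ... Unused.
#' @return A vector (or [IRanges::IntegerList] for `modPositions`) parallel
#'   to the transcripts, named by transcript id.
#' @name transcriptome-accessors
#' @aliases transcriptIds geneIds geneTypes anticodons txLengths
#'   modPositions sequences geneOf
NULL

#' @rdname transcriptome-accessors
#' @export
setGeneric("transcriptIds", function(x, ...) standardGeneric("transcriptIds"))
#' @rdname transcriptome-accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))
#' @rdname transcriptome-accessors
#' @export
setGeneric("geneTypes", function(x, ...) standardGeneric("geneTypes"))
#' @rdname transcriptome-accessors
#' @export
setGeneric("anticodons", function(x, ...) standardGeneric("anticodons"))
#' @rdname transcriptome-accessors
#' @export
setGeneric("txLengths", function(x, ...) standardGeneric("txLengths"))
#' @rdname transcriptome-accessors
#' @export
setGeneric("modPositions", function(x, ...) standardGeneric("modPositions"))
#' @rdname transcriptome-accessors
#' @export
setGeneric("sequences", function(x, ...) standardGeneric("sequences"))
#' @rdname transcriptome-accessors
#' @param transcript_id Character vector of transcript ids to map.
#' @export
setGeneric("geneOf", function(x, transcript_id, ...) standardGeneric("geneOf"))

#' Derived constants and accessors of a TitrationDesign
#'
#' `k1` and `k2` are the coefficients of the expected C/D fold-change
#' model, always recomputed from `z`: `k1 = 3z/(3z+1)` is the fraction of
#' sample-C signal contributed by A, and `k2 = z/(z+3)` the fraction of
#' sample-D signal contributed by A. For any `z > 0`, `k1 > k2`.
#' `erccRatios` returns the named vector of designed A:B ratios per
#' spike-in group.
#'
#' @param x A `TitrationDesign`.
#' @param ... Unused.
#' @return A single numeric (`k1`, `k2`, `zRatio`) or named numeric vector
#'   (`erccRatios`).
#' @name design-accessors
#' @aliases k1 k2 zRatio erccRatios
NULL

#' @rdname design-accessors
#' @export
setGeneric("k1", function(x, ...) standardGeneric("k1"))
#' @rdname design-accessors
#' @export
setGeneric("k2", function(x, ...) standardGeneric("k2"))
#' @rdname design-accessors
#' @export
setGeneric("zRatio", function(x, ...) standardGeneric("zRatio"))
#' @rdname design-accessors
#' @export
setGeneric("erccRatios", function(x, ...) standardGeneric("erccRatios"))

#' Unit of an AbundanceTable
#'
#' @param x An `AbundanceTable`.
#' @param ... Unused.
#' @return A single string, one of `"molar_per_unit_mass"`, `"count"`,
#'   `"count_scale"`, `"TPM"`.
#' @export
setGeneric("abundanceUnit", function(x, ...) standardGeneric("abundanceUnit"))

#' Accessors for ReadSet and EquivalenceClassCounts
#'
#' `readSequences` returns the reads as a [Biostrings::DNAStringSet];
#' `readInfo` the per-read ground truth; `errorLog` the long-format table
#' of introduced errors. `classCounts` returns the per-class read counts
#' named by their sorted transcript sets, and `unassignedCount` the number
#' of reads compatible with no transcript.
#'
#' @param x A `ReadSet` or `EquivalenceClassCounts`.
#' @param ... Unused.
#' @name readset-accessors
#' @aliases readSequences readInfo errorLog classCounts unassignedCount
NULL

#' @rdname readset-accessors
#' @export
setGeneric("readSequences", function(x, ...) standardGeneric("readSequences"))
#' @rdname readset-accessors
#' @export
setGeneric("readInfo", function(x, ...) standardGeneric("readInfo"))
#' @rdname readset-accessors
#' @export
setGeneric("errorLog", function(x, ...) standardGeneric("errorLog"))
#' @rdname readset-accessors
#' @export
setGeneric("classCounts", function(x, ...) standardGeneric("classCounts"))
#' @rdname readset-accessors
#' @export
setGeneric("unassignedCount", function(x, ...)
  standardGeneric("unassignedCount"))
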
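#' @include AllClasses.R AllGenerics.R utils.R reads.R
#' @useDynLib titrabench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# priority class of a transcript for the multi-map selection heuristic
priority_class <- function(txome, transcript_id) {
  type <- geneTypes(txome)[transcript_id]
  dec <- txome@txData$is_decoy[match(transcript_id, transcriptIds(txome))]
  out <- rep("primary", length(transcript_id))
  out[type == "rRNA"] <- "rRNA_locus"
  out[dec] <- "decoy"
  out
}

#' Mismatch-tolerant end-to-end alignment of reads
#'
#' Exhaustive scan of all sense-strand offsets of all transcripts; every
#' placement with Hamming distance at most `maxMismatch` is returned. No
#' terminal overhang beyond transcript ends is allowed and there are no
#' indels: this is the end-to-end, substitution-only analogue of the
#' short-read aligners used by alignment-based pipelines, and in contrast
#' to exact k-mer matching it tolerates modification-induced
#' misincorporations up to the mismatch budget.
#'
#' @param read A single read sequence (for `alignRead`) or a
#'   [ReadSet-class] / named [Biostrings::DNAStringSet] /
#'   named character vector (for `alignReads`).
#' @param txome A [TranscriptomeSet-class].
#' @param maxMismatch Mismatch budget; default `ceiling(0.15 *
#'   read length)`.
#' @return A [S4Vectors::DataFrame] of hits: `read_id` (for
#'   `alignReads`), `transcript_id`, `gene_type`, `priority_class`,
#'   `start` (1-based), `mismatches`.
#' @export
alignRead <- function(read, txome, maxMismatch = NULL) {
  read <- as.character(read)
  hits <- alignReads(stats::setNames(read, "read"), txome, maxMismatch)
  hits[, setdiff(colnames(hits), "read_id"), drop = FALSE]
}

#' @rdname alignRead
#' @param reads See `read`.
#' @export
alignReads <- function(reads, txome, maxMismatch = NULL) {
  if (is(reads, "ReadSet")) reads <- readSequences(reads)
  rs <- as.character(reads)
  if (is.null(names(rs)))
    names(rs) <- sprintf("read_%06d", seq_along(rs))
  if (is.null(maxMismatch))
    maxMismatch <- ceiling(0.15 * max(nchar(rs)))
  if (maxMismatch < 0) stop("'maxMismatch' must be >= 0")
  txseq <- as.character(sequences(txome))
  raw <- .hamming_scan(unname(rs), unname(txseq), as.integer(maxMismatch))
  ids <- transcriptIds(txome)[raw$tx]
  DataFrame(read_id = names(rs)[raw$read],
            transcript_id = ids,
            gene_type = unname(geneTypes(txome)[ids]),
            priority_class = priority_class(txome, ids),
            start = raw$start,
            mismatches = raw$mismatches)
}

#' Route and select a single alignment per read
#'
#' The selection heuristic of small-RNA-aware alignment pipelines,
#' adapted to single-end reads. Routing first: if any placement lands on
#' a tRNA or rRNA transcript, all other placements are discarded (small
#' structured RNAs are aligned against their own references before
#' genome mapping, to reduce multi-mapping). Among the survivors the
#' ordered criteria are: (1) fewest mismatches (the single-end analogue
#' of the smallest insert size, i.e. the most parsimonious placement);
#' (2) rRNA-locus placements preferred; (3) primary sequence preferred
#' over decoy (haplotype/patch analogue). Any remaining tie is broken by
#' a seeded uniform draw, so each read yields at most one placement.
#'
#' @param hits A [S4Vectors::DataFrame] of placements for one read, as
#'   returned by [alignRead()].
#' @param seed Integer seed for the random tie-break.
#' @return A single-row [S4Vectors::DataFrame], or `NULL` when `hits` is
#'   empty.
#' @export
routeAndSelect <- function(hits, seed = 1L) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  small <- hits$gene_type %in% c("tRNA", "rRNA")
  if (any(small)) hits <- hits[small, , drop = FALSE]
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  if (any(hits$priority_class == "rRNA_locus"))
    hits <- hits[hits$priority_class == "rRNA_locus", , drop = FALSE]
  else if (any(hits$priority_class == "primary"))
    hits <- hits[hits$priority_class == "primary", , drop = FALSE]
  if (nrow(hits) == 1L) return(hits)
  pick <- with_rng(seed, sample.int(nrow(hits), 1L))
  hits[pick, , drop = FALSE]
}

# vectorized selection over a full hit table (one seeded draw stream);
# reads with a unique placement are taken as-is, the heuristic only runs
# on genuinely multi-mapping reads
select_alignments <- function(hits, seed = 1L) {
  if (nrow(hits) == 0L)
    return(hits[integer(0), , drop = FALSE])
  idx <- split(seq_len(nrow(hits)), hits$read_id)
  multi <- lengths(idx) > 1L
  rows <- unlist(idx[!multi], use.names = FALSE)
  prio <- c(rRNA_locus = 1L, primary = 2L, decoy = 3L)
  gt <- hits$gene_type; mmv <- hits$mismatches
  pc <- prio[hits$priority_class]
  with_rng(seed, {
    for (ix in idx[multi]) {
      small <- gt[ix] %in% c("tRNA", "rRNA")
      if (any(small)) ix <- ix[small]
      ix <- ix[mmv[ix] == min(mmv[ix])]
      ix <- ix[pc[ix] == min(pc[ix])]
      rows <- c(rows, if (length(ix) == 1L) ix
                      else ix[sample.int(length(ix), 1L)])
    }
  })
  hits[sort(rows), , drop = FALSE]
}

#' Count selected reads per gene
#'
#' One count per read, to the gene of its selected transcript; reads
#' without a selected placement contribute nothing, so gene counts sum to
#' the number of selected reads.
#'
#' @param selected A [S4Vectors::DataFrame] of selected placements (one
#'   row per read) with a `transcript_id` column.
#' @param txome A [TranscriptomeSet-class].
#' @return Named integer vector of counts over all genes of `txome`
#'   (zeros included).
#' @export
countGenes <- function(selected, txome) {
  genes <- unique(unname(geneIds(txome)))
  counts <- stats::setNames(integer(length(genes)), genes)
  if (!is.null(selected) && nrow(selected) > 0L) {
    g <- geneOf(txome, selected$transcript_id)  # errors on unknown ids
    tab <- table(g)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Aggregate tRNA gene counts by anticodon
#'
#' Sums counts over tRNA genes sharing an anticodon (isoacceptor
#' aggregation). Non-tRNA genes in the input, or tRNA genes without an
#' anticodon, are an error.
#'
#' @param geneCounts Named numeric vector of tRNA gene counts.
#' @param txome A [TranscriptomeSet-class].
#' @return Named numeric vector of per-anticodon counts.
#' @export
aggregateAnticodon <- function(geneCounts, txome) {
  g2a <- unique(data.frame(gene = unname(geneIds(txome)),
                           ac = unname(anticodons(txome)),
                           type = unname(geneTypes(txome))))
  ix <- match(names(geneCounts), g2a$gene)
  if (anyNA(ix))
    stop("unknown gene(s): ",
         paste(names(geneCounts)[is.na(ix)], collapse = ", "))
  if (any(g2a$type[ix] != "tRNA") || anyNA(g2a$ac[ix]))
    stop("anticodon aggregation requires tRNA genes with anticodons")
  tapply(geneCounts, g2a$ac[ix], sum)[]
}

#' Alignment-based quantification of one read library
#'
#' Full pipeline: exhaustive mismatch-tolerant alignment, tRNA/rRNA
#' routing with the ordered multi-map selection heuristic, and gene
#' counting. Each read contributes at most one count.
#'
#' @param txome A [TranscriptomeSet-class].
#' @param reads A [ReadSet-class] or named sequences.
#' @param maxMismatch Mismatch budget (default `ceiling(0.15 * read
#'   length)`).
#' @param seed Integer seed for tie-breaking.
#' @return A list with `geneCounts` (named vector over all genes),
#'   `assignments` (per-read [S4Vectors::DataFrame]: `read_id`,
#'   `transcript_id`, `mismatches`) and `nUnaligned`.
#' @export
quantifyAlign <- function(txome, reads, maxMismatch = NULL, seed = 1L) {
  n_reads <- if (is(reads, "ReadSet")) length(reads) else length(reads)
  hits <- alignReads(reads, txome, maxMismatch)
  sel <- select_alignments(hits, seed = seed)
  list(geneCounts = countGenes(sel, txome),
       assignments = sel[, c("read_id", "transcript_id", "mismatches"),
                         drop = FALSE],
       nUnaligned = n_reads - nrow(sel))
}
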
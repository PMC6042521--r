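#' @include AllClasses.R AllGenerics.R utils.R abundance.R
NULL

#' Simulate sense-strand reads with misincorporation errors
#'
#' Reads are single-end and sense-strand (stranded total-RNA libraries).
#' The source transcript of each read is drawn proportionally to its
#' abundance times its effective length (for count input the counts
#' already carry the length factor and are used as weights directly); the
#' start is uniform over valid positions, and reads from transcripts
#' shorter than `readLength` are truncated at the transcript end. Each
#' modification site covered by a read is misread with probability
#' `misRate` (the base is replaced by a uniformly chosen different base,
#' emulating reverse-transcription misincorporation at modified bases);
#' independently every base is flipped with probability `seqError`. All
#' introduced errors are recorded in the error log.
#'
#' @param txome A [TranscriptomeSet-class].
#' @param abundance An [AbundanceTable-class] (any unit) supplying the
#'   library to simulate from.
#' @param sample,replicate Which library of `abundance` to use.
#' @param nReads Number of reads (> 0).
#' @param readLength Read length in nt (default 50).
#' @param misRate Per-covered-modification-site substitution probability.
#' @param seqError Per-base sequencing error probability.
#' @param seed Integer seed.
#' @return A [ReadSet-class].
#' @export
simulateReads <- function(txome, abundance, sample, replicate = 1L,
                          nReads, readLength = 50L, misRate = 0.8,
                          seqError = 0.001, seed = 1L) {
  if (nReads <= 0) stop("'nReads' must be positive")
  stopifnot(misRate >= 0, misRate <= 1, seqError >= 0, seqError <= 1)
  m <- abundanceMatrix(abundance)
  keep <- colData(abundance)$sample == sample &
    colData(abundance)$replicate == replicate
  if (sum(keep) != 1L)
    stop("no unique library for sample ", sample, " replicate ", replicate)
  vals <- stats::setNames(m[, keep, drop = FALSE][, 1L], rownames(m))
  ids <- transcriptIds(txome)
  vals <- vals[ids]
  if (anyNA(vals)) stop("abundance table does not cover the transcriptome")
  lens <- unname(txLengths(txome))
  ef <- effectiveLength(lens, readLength)
  w <- if (abundanceUnit(abundance) == "count") vals else vals * ef
  if (sum(w) <= 0) stop("library has no positive abundance")
  seqs <- as.character(sequences(txome))
  mods <- as.list(modPositions(txome))

  with_rng(seed, {
    tx <- sample.int(length(ids), nReads, replace = TRUE, prob = w)
    maxstart <- ef[tx]
    start <- as.integer(floor(stats::runif(nReads) * maxstart)) + 1L
    end <- pmin(start + as.integer(readLength) - 1L, lens[tx])
    reads <- substring(seqs[tx], start, end)
    rid <- sprintf("%s_%s_r%06d", sample, replicate, seq_len(nReads))

    log_read <- integer(0); log_pos <- integer(0); log_cause <- character(0)
    has_mods <- lengths(mods)[tx] > 0L
    for (i in which(has_mods)) {
      sites <- mods[[tx[i]]]
      sites <- sites[sites >= start[i] & sites <= end[i]]
      if (!length(sites)) next
      hit <- sites[stats::runif(length(sites)) < misRate]
      for (s in hit) {
        p <- s - start[i] + 1L
        b <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- substitute_base(b)
        log_read <- c(log_read, i); log_pos <- c(log_pos, p)
        log_cause <- c(log_cause, "modification")
      }
    }
    if (seqError > 0) {
      wid <- end - start + 1L
      nerr <- stats::rbinom(nReads, wid, seqError)
      for (i in which(nerr > 0L)) {
        at <- sample.int(wid[i], nerr[i])
        for (p in sort(at)) {
          b <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- substitute_base(b)
          log_read <- c(log_read, i); log_pos <- c(log_pos, p)
          log_cause <- c(log_cause, "sequencing")
        }
      }
    }
    sset <- Biostrings::DNAStringSet(reads)
    names(sset) <- rid
    new("ReadSet", reads = sset,
        info = DataFrame(true_transcript_id = ids[tx],
                         true_start = start, row.names = rid),
        errorLog = DataFrame(read_id = rid[log_read],
                             pos = log_pos, cause = log_cause),
        readLength = as.integer(readLength))
  })
}

#' @rdname readset-accessors
#' @export
setMethod("readSequences", "ReadSet", function(x, ...) x@reads)

#' @rdname readset-accessors
#' @export
setMethod("readInfo", "ReadSet", function(x, ...) x@info)

#' @rdname readset-accessors
#' @export
setMethod("errorLog", "ReadSet", function(x, ...) x@errorLog)

setMethod("length", "ReadSet", function(x) length(x@reads))

setMethod("show", "ReadSet", function(object) {
  el <- object@errorLog
  cat(sprintf("ReadSet: %d reads of length <= %d nt\n", length(object),
              object@readLength))
  cat(sprintf("  errors logged: %d modification, %d sequencing\n",
              sum(el$cause == "modification"),
              sum(el$cause == "sequencing")))
})

#' Write / read reads as FASTQ
#'
#' Phred+33 with constant quality `I` (Q40); simulated base quality is not
#' modelled, sequencing errors are injected explicitly instead.
#'
#' @param reads A [ReadSet-class] (or [Biostrings::DNAStringSet]).
#' @param path FASTQ path.
#' @return `writeReadsFastq` returns `path` invisibly; `readReadsFastq` a
#'   named [Biostrings::DNAStringSet].
#' @export
writeReadsFastq <- function(reads, path) {
  sset <- if (is(reads, "ReadSet")) readSequences(reads) else reads
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(sset)))
  Biostrings::writeXStringSet(sset, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
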
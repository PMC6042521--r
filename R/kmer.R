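#' @include AllClasses.R AllGenerics.R utils.R reads.R
NULL

#' Build an exact k-mer index over a transcriptome
#'
#' Every transcript of length `L >= k` contributes its `L - k + 1`
#' overlapping k-mers (sense strand only); each k-mer maps to the set of
#' transcripts containing it. Transcripts shorter than `k` contribute
#' nothing and are flagged with a warning: this is precisely how a large
#' default k-mer size can make very short transcripts invisible to
#' alignment-free quantifiers.
#'
#' @param x A [TranscriptomeSet-class] or named
#'   [Biostrings::DNAStringSet].
#' @param k k-mer size (>= 1).
#' @return A [KmerIndex-class].
#' @examples
#' sset <- Biostrings::DNAStringSet(c(T1 = "ACGTACGT"))
#' idx <- buildKmerIndex(sset, k = 4)
#' pseudomapRead("CGTA", idx)
#' @export
buildKmerIndex <- function(x, k) {
  if (k < 1) stop("'k' must be >= 1")
  k <- as.integer(k)
  sset <- if (is(x, "TranscriptomeSet")) sequences(x) else x
  ids <- names(sset)
  if (is.null(ids)) stop("transcripts must be named")
  lens <- Biostrings::width(sset)
  short <- lens < k
  if (any(short))
    warning(sum(short), " transcript(s) shorter than k = ", k,
            " contribute no k-mers")
  seqs <- as.character(sset)
  all_kmers <- character(0)
  all_tx <- integer(0)
  for (i in which(!short)) {
    n <- lens[i] - k + 1L
    all_kmers <- c(all_kmers, substring(seqs[i], 1:n, k:(k + n - 1L)))
    all_tx <- c(all_tx, rep.int(i, n))
  }
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(length(all_kmers), 1L))
  if (length(all_kmers)) {
    sp <- split(all_tx, all_kmers)
    sp <- lapply(sp, function(v) sort(unique(v)))
    list2env(sp, envir = env)
  }
  new("KmerIndex", k = k, table = env, txIds = ids,
      txLengths = as.integer(lens))
}

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k = %d, %d transcripts, %d distinct k-mers\n",
              object@k, length(object@txIds),
              length(ls(object@table, sorted = FALSE))))
})

#' Pseudoassign a read to its compatible transcript set
#'
#' The read is decomposed into its k-mers; k-mers present in the index
#' vote with their transcript sets and the result is the intersection over
#' all present k-mers. Absent k-mers (e.g. corrupted by an error) are
#' skipped; a read none of whose k-mers is indexed, or whose intersection
#' is empty, is unassigned. This is the plain intersection rule of
#' pseudoalignment-class quantifiers, without skip-ahead or bias models:
#' assignment succeeds exactly when the read retains at least one
#' error-free (or accidentally colliding) k-mer whose votes are
#' consistent.
#'
#' @param read A single read sequence (character or
#'   [Biostrings::DNAString]).
#' @param index A [KmerIndex-class].
#' @return Character vector of compatible transcript ids (empty if
#'   unassigned; reads shorter than `k` are always unassigned).
#' @export
pseudomapRead <- function(read, index) {
  read <- as.character(read)
  k <- index@k
  n <- nchar(read)
  if (n < k) return(character(0))
  kmers <- unique(substring(read, 1:(n - k + 1L), k:n))
  hits <- mget(kmers, envir = index@table, ifnotfound = list(NULL))
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits)) return(character(0))
  res <- Reduce(intersect, hits)
  index@txIds[res]
}

# internal: pseudomap many reads, returning a character key per read
# ("" = unassigned, else comma-separated sorted transcript indices)
pseudomap_keys <- function(reads, index) {
  k <- index@k
  env <- index@table
  vapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return("")
    kmers <- unique(substring(r, 1:(n - k + 1L), k:n))
    hits <- mget(kmers, envir = env, ifnotfound = list(NULL))
    hits <- hits[!vapply(hits, is.null, TRUE)]
    if (!length(hits)) return("")
    res <- Reduce(intersect, hits)
    if (!length(res)) "" else paste(res, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

#' Group pseudoassignments into equivalence classes
#'
#' Reads with identical compatibility sets form one equivalence class;
#' unassigned reads are counted separately, so class totals plus the
#' unassigned count always equal the number of input reads.
#'
#' @param reads A [ReadSet-class], [Biostrings::DNAStringSet] or
#'   character vector of read sequences.
#' @param index A [KmerIndex-class].
#' @return An [EquivalenceClassCounts-class].
#' @export
collectEquivalenceClasses <- function(reads, index) {
  if (is(reads, "ReadSet")) reads <- readSequences(reads)
  reads <- as.character(reads)
  keys <- pseudomap_keys(reads, index)
  unassigned <- sum(keys == "")
  keys <- keys[keys != ""]
  if (!length(keys)) {
    return(new("EquivalenceClassCounts", classes = list(),
               counts = integer(0), unassigned = as.integer(unassigned)))
  }
  tab <- table(keys)
  classes <- lapply(strsplit(names(tab), ",", fixed = TRUE),
                    function(ix) index@txIds[as.integer(ix)])
  new("EquivalenceClassCounts", classes = classes,
      counts = as.integer(tab), unassigned = as.integer(unassigned))
}

#' @rdname readset-accessors
#' @export
setMethod("classCounts", "EquivalenceClassCounts", function(x, ...)
  stats::setNames(x@counts,
                  vapply(x@classes, paste, "", collapse = ",")))

#' @rdname readset-accessors
#' @export
setMethod("unassignedCount", "EquivalenceClassCounts", function(x, ...)
  x@unassigned)

#' Write equivalence-class counts as TSV
#'
#' One row per class (`transcripts` is the comma-separated sorted id
#' set) plus a final row for unassigned reads.
#'
#' @param classes An [EquivalenceClassCounts-class].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeEquivalenceClasses <- function(classes, path) {
  df <- data.frame(
    transcripts = c(vapply(classes@classes, paste, "", collapse = ","),
                    "*unassigned*"),
    count = c(classes@counts, classes@unassigned))
  write_tsv(df, path)
  invisible(path)
}

setMethod("show", "EquivalenceClassCounts", function(object) {
  cat(sprintf("EquivalenceClassCounts: %d classes, %d assigned reads, %d unassigned\n",
              length(object@classes), sum(object@counts),
              object@unassigned))
})

#' EM abundance estimation from equivalence classes
#'
#' Standard transcript-abundance EM: with class counts `n_c` and
#' length-normalized mixture weights, iterate
#' `theta_t <- (1/N) * sum_c n_c (theta_t/l_t) / sum_{u in c}
#' (theta_u/l_u)` from a uniform start until the largest change in
#' `theta` falls below `tol` or `maxIter` is reached. The converged
#' `theta` is the read fraction per transcript (a read is generated
#' proportionally to abundance times effective length); TPM divides out
#' the effective length and renormalizes:
#' `TPM_t = 1e6 (theta_t/l_t) / sum_u (theta_u/l_u)`. When several
#' maximizers exist the EM fixed point from the uniform start is the
#' defined answer. Transcripts appearing in no class get TPM 0.
#'
#' @param classes An [EquivalenceClassCounts-class].
#' @param effLengths Named positive effective lengths of all quantifiable
#'   transcripts.
#' @param tol Convergence tolerance on `max |delta theta|` (default 1e-8).
#' @param maxIter Maximum EM iterations (default 1000).
#' @return Named numeric vector of TPM, one per entry of `effLengths`.
#' @export
emAbundances <- function(classes, effLengths, tol = 1e-8, maxIter = 1000L) {
  ids <- names(effLengths)
  if (is.null(ids)) stop("'effLengths' must be named")
  if (any(effLengths <= 0)) stop("effective lengths must be positive")
  if (!length(classes@classes)) {
    warning("no assigned reads; all abundances are zero")
    return(stats::setNames(rep(0, length(ids)), ids))
  }
  member <- lapply(classes@classes, function(cl) {
    ix <- match(cl, ids)
    if (anyNA(ix)) stop("class references unknown transcript(s): ",
                        paste(cl[is.na(ix)], collapse = ", "))
    ix
  })
  n_c <- as.numeric(classes@counts)
  N <- sum(n_c)
  l <- as.numeric(effLengths)
  theta <- rep(1 / length(ids), length(ids))
  for (it in seq_len(maxIter)) {
    rho <- theta / l
    new_theta <- numeric(length(ids))
    for (ci in seq_along(member)) {
      ix <- member[[ci]]
      denom <- sum(rho[ix])
      if (denom > 0)
        new_theta[ix] <- new_theta[ix] + n_c[ci] * rho[ix] / denom
    }
    new_theta <- new_theta / N
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    if (delta < tol) break
  }
  nu <- theta / l
  stats::setNames(1e6 * nu / sum(nu), ids)
}

#' Alignment-free quantification of one read library
#'
#' Convenience pipeline: index (or reuse an index), pseudoassign, collect
#' equivalence classes, run the EM. Effective lengths use the read set's
#' nominal read length.
#'
#' @param txome A [TranscriptomeSet-class].
#' @param reads A [ReadSet-class] (or sequences accepted by
#'   [collectEquivalenceClasses()]).
#' @param k k-mer size (default 31, the common default of alignment-free
#'   quantifiers).
#' @param index Optional prebuilt [KmerIndex-class] (must match `k`).
#' @param readLength Read length for effective lengths; taken from the
#'   `ReadSet` when available.
#' @param ... Passed to [emAbundances()].
#' @return A list with `tpm` (named vector), `classes`
#'   (an [EquivalenceClassCounts-class]) and `k`.
#' @export
quantifyKmer <- function(txome, reads, k = 31L, index = NULL,
                         readLength = NULL, ...) {
  if (is.null(index)) {
    index <- suppressWarnings(buildKmerIndex(txome, k))
  } else if (index@k != k) stop("prebuilt index has a different k")
  if (is.null(readLength))
    readLength <- if (is(reads, "ReadSet")) reads@readLength else 50L
  ec <- collectEquivalenceClasses(reads, index)
  ef <- effectiveLength(txLengths(txome), readLength)
  tpm <- if (length(ec@classes)) emAbundances(ec, ef, ...)
         else suppressWarnings(emAbundances(ec, ef, ...))
  list(tpm = tpm, classes = ec, k = k)
}
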
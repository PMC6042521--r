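#' @importFrom withr with_seed
NULL

# run expr under an explicit RNG seed without disturbing the caller's RNG
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible sub-seed for a labelled stage from a base seed;
# keeps results < 2^31 so they remain valid R integers
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# random DNA of given lengths
random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# substitute the base at `pos` in `chars` (a character vector of single
# bases) by a uniformly chosen different base
substitute_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1L)
}

#' Effective length of a transcript
#'
#' The number of valid start positions of a read of length `readLength` on
#' a transcript of length `length`: `max(length - readLength + 1, 1)`.
#' Transcripts shorter than the read still admit one (truncated) read.
#'
#' @param length Integer vector of transcript lengths.
#' @param readLength Read length in nt.
#' @return Integer vector of effective lengths.
#' @export
effectiveLength <- function(length, readLength) {
  out <- pmax(as.integer(length) - as.integer(readLength) + 1L, 1L)
  names(out) <- names(length)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
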
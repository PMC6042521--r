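#' @include utils.R
NULL

check_dropout_query <- function(L, k = NULL, errorPositions = integer(0)) {
  if (L < 1) stop("'L' must be >= 1")
  if (!is.null(k) && (k < 1 || k > L)) stop("'k' must satisfy 1 <= k <= L")
  ep <- as.integer(errorPositions)
  if (length(ep) && (any(ep < 1L) || any(ep > L)))
    stop("error positions must lie in [1, L]")
  if (anyDuplicated(ep)) stop("error positions must be distinct")
  sort(ep)
}

# error-free gap lengths between consecutive error positions (including
# the flanks before the first and after the last error)
errorfree_gaps <- function(L, errorPositions) {
  e <- errorPositions
  if (!length(e)) return(L)
  c(e[1] - 1L, diff(e) - 1L, L - e[length(e)])
}

#' Number of error-free k-mers in a read with fixed error positions
#'
#' A substitution error corrupts every k-mer window overlapping it, so
#' the error-free windows are those falling entirely inside the gaps
#' between errors: with gap lengths `g`, the count is
#' `sum(max(g - k + 1, 0))`. A read of length 75 with errors at
#' positions 20, 30 and 50 has gaps 19, 9, 19, 25 - all shorter than 31 -
#' so at k = 31 no error-free window exists and an exact k-mer index
#' cannot match the read, while at k = 21 the trailing 25-nt gap still
#' admits 5 windows.
#'
#' @param L Read (or transcript) length in nt.
#' @param k k-mer size, `1 <= k <= L`.
#' @param errorPositions Integer vector of 1-based error positions.
#' @return Integer count of error-free k-windows, between 0 and
#'   `L - k + 1`.
#' @examples
#' errorfreeKmerCount(75, 31, c(20, 30, 50))  # 0
#' errorfreeKmerCount(75, 21, c(20, 30, 50))  # 5
#' @export
errorfreeKmerCount <- function(L, k, errorPositions = integer(0)) {
  ep <- check_dropout_query(L, k, errorPositions)
  g <- errorfree_gaps(as.integer(L), ep)
  sum(pmax(g - as.integer(k) + 1L, 0L))
}

#' Largest k-mer size at which a read remains detectable
#'
#' The largest `k` with at least one error-free k-window, which equals
#' the longest error-free gap; `NA` when errors occupy every position.
#' Counts are non-increasing in `k`, so every smaller `k` also works.
#'
#' @inheritParams errorfreeKmerCount
#' @return Integer, or `NA_integer_` when no k works.
#' @examples
#' minDetectableK(75, c(20, 30, 50))  # 25: the longest gap
#' @export
minDetectableK <- function(L, errorPositions = integer(0)) {
  ep <- check_dropout_query(L, errorPositions = errorPositions)
  g <- max(errorfree_gaps(as.integer(L), ep))
  if (g == 0L) NA_integer_ else as.integer(g)
}

#' Probability that a read with random site errors stays assignable
#'
#' Each listed site is independently misread with probability `misRate`;
#' the read remains assignable by an exact k-mer index iff the realized
#' error set leaves at least one error-free k-window (corrupted k-mers
#' are assumed to match nothing; accidental collisions are handled only
#' in the full quantifier, not here). With at most `maxExact` sites the
#' probability is computed by exact enumeration over all error subsets;
#' otherwise by Monte Carlo, with a binomial standard error.
#'
#' @inheritParams errorfreeKmerCount
#' @param sitePositions 1-based modification-site positions.
#' @param misRate Per-site error probability in \[0, 1\].
#' @param nSim Monte Carlo sample size (default 10000).
#' @param seed Integer seed for the Monte Carlo path.
#' @param method `"auto"` (exact when few sites), `"exact"`, or
#'   `"montecarlo"`.
#' @param maxExact Largest number of sites enumerated exactly
#'   (default 20).
#' @return A list with `estimate`, `se` (0 for exact) and `method`.
#' @examples
#' assignmentProbability(75, 31, c(20, 30, 50), misRate = 0.5)$estimate
#' @export
assignmentProbability <- function(L, k, sitePositions, misRate,
                                  nSim = 10000L, seed = 1L,
                                  method = c("auto", "exact", "montecarlo"),
                                  maxExact = 20L) {
  method <- match.arg(method)
  if (misRate < 0 || misRate > 1) stop("'misRate' must be in [0, 1]")
  if (nSim < 1) stop("'nSim' must be >= 1")
  sites <- check_dropout_query(L, k, sitePositions)
  m <- length(sites)
  if (method == "auto") method <- if (m <= maxExact) "exact" else "montecarlo"
  if (method == "exact") {
    if (m > maxExact) stop("too many sites for exact enumeration")
    prob <- 0
    for (mask in 0:(2^m - 1)) {
      realized <- sites[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      p_sub <- misRate^length(realized) * (1 - misRate)^(m - length(realized))
      if (errorfreeKmerCount(L, k, realized) > 0) prob <- prob + p_sub
    }
    list(estimate = prob, se = 0, method = "exact")
  } else {
    hits <- with_rng(seed, {
      sum(vapply(seq_len(nSim), function(i) {
        realized <- sites[stats::runif(m) < misRate]
        errorfreeKmerCount(L, k, realized) > 0
      }, logical(1)))
    })
    p <- hits / nSim
    list(estimate = p, se = sqrt(p * (1 - p) / nSim),
         method = "montecarlo")
  }
}

#' Sweep error-free k-mer availability over a k grid
#'
#' The desk-scale analogue of varying the quantifier's k-mer size:
#' reports, per k, the number of error-free windows and (optionally) the
#' assignment probability under random site errors.
#'
#' @inheritParams assignmentProbability
#' @param kGrid Integer k values (default the common sweep 11, 15, 21,
#'   31).
#' @param misRate Optional; when given, an `assignment_probability`
#'   column is added.
#' @return A data.frame with one row per k.
#' @export
dropoutSweep <- function(L, errorPositions, kGrid = c(11L, 15L, 21L, 31L),
                         misRate = NULL, seed = 1L) {
  out <- data.frame(
    k = as.integer(kGrid),
    errorfree_kmers = vapply(kGrid, function(k)
      errorfreeKmerCount(L, k, errorPositions), integer(1)))
  if (!is.null(misRate))
    out$assignment_probability <- vapply(kGrid, function(k)
      assignmentProbability(L, k, errorPositions, misRate,
                            seed = seed)$estimate, 1.0)
  out
}
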
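# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force window enumeration, grid-search
# likelihood maximization, and a naive R^2 reimplementation.

# brute force: count k-windows of [1, L] containing no error position
bf_errorfree <- function(L, k, errors) {
  if (k > L) stop("k > L")
  err <- logical(L)
  err[errors] <- TRUE
  n <- 0L
  for (s in seq_len(L - k + 1L))
    if (!any(err[s:(s + k - 1L)])) n <- n + 1L
  n
}

# brute force over all error subsets: probability that >= 1 error-free
# k-window survives when each site errs independently with prob p
bf_assignment_prob <- function(L, k, sites, p) {
  m <- length(sites)
  prob <- 0
  for (mask in 0:(2^m - 1)) {
    realized <- sites[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    w <- p^length(realized) * (1 - p)^(m - length(realized))
    if (bf_errorfree(L, k, realized) > 0) prob <- prob + w
  }
  prob
}

# grid-search maximizer of the equivalence-class log-likelihood
# sum_c n_c * log(sum_{t in c} theta_t / l_t) over read fractions theta
# on the simplex (coarse grid, then local refinement), reported as
# length-normalized abundance fractions (TPM / 1e6) for comparison with
# the EM output; 2-3 transcript instances
grid_mle <- function(class_list, counts, efflen) {
  ids <- names(efflen)
  nt <- length(ids)
  stopifnot(nt %in% c(2L, 3L))
  member <- lapply(class_list, function(cl) match(cl, ids))
  loglik <- function(theta) {
    rho <- theta / efflen
    sum(vapply(seq_along(member), function(ci) {
      s <- sum(rho[member[[ci]]])
      if (s <= 0) -1e300 else counts[ci] * log(s)
    }, 1.0))
  }
  eval_grid <- function(pts) {
    ll <- apply(pts, 1L, loglik)
    pts[which.max(ll), ]
  }
  make_grid <- function(center, width, step) {
    if (nt == 2L) {
      t1 <- seq(max(0, center[1] - width), min(1, center[1] + width), by = step)
      cbind(t1, 1 - t1)
    } else {
      t1 <- seq(max(0, center[1] - width), min(1, center[1] + width), by = step)
      t2 <- seq(max(0, center[2] - width), min(1, center[2] + width), by = step)
      g <- expand.grid(t1 = t1, t2 = t2)
      g <- g[g$t1 + g$t2 <= 1, ]
      cbind(g$t1, g$t2, 1 - g$t1 - g$t2)
    }
  }
  best <- eval_grid(make_grid(rep(1 / nt, nt), 1, 0.02))
  best <- eval_grid(make_grid(best, 0.025, 0.001))
  best <- eval_grid(make_grid(best, 0.0015, 0.0001))
  nu <- as.numeric(best) / efflen
  stats::setNames(nu / sum(nu), ids)
}

# naive R^2, written independently of rSquared()
naive_r2 <- function(y, f) {
  1 - sum((y - f)^2) / sum((y - mean(y))^2)
}

# hand-built toy transcriptome from explicit sequences
make_txome <- function(seqs, gene = names(seqs), type = "protein_coding",
                       anticodon = NA_character_, mods = NULL,
                       decoy = FALSE) {
  n <- length(seqs)
  sset <- Biostrings::DNAStringSet(unname(seqs))
  names(sset) <- names(seqs)
  if (is.null(mods)) mods <- rep(list(integer(0)), n)
  new("TranscriptomeSet", sequences = sset,
      txData = S4Vectors::DataFrame(
        gene_id = rep_len(gene, n),
        gene_type = rep_len(type, n),
        anticodon = rep_len(anticodon, n),
        is_decoy = rep_len(decoy, n),
        mod_positions = IRanges::IntegerList(mods),
        row.names = names(seqs)))
}

# deterministic random DNA helper for fixtures
rand_seq <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# a small mechanism-scenario config shared by benchmark/acceptance tests:
# canonical modification sites, two k values, modest depth
mechanism_config <- function(nReads = 4000L, kGrid = c(21L, 31L),
                             seed = 101L) {
  runConfig(
    txConfig = transcriptomeConfig(trnaModSites = c(20L, 30L, 50L)),
    kGrid = kGrid, nReads = nReads, seed = seed)
}
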
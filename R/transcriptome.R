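#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Generator settings for the toy transcriptome
#'
#' Defaults emulate a mixed total-RNA reference at desk scale: 60
#' protein-coding genes of 500-3000 nt (a few with two isoforms sharing a
#' long common region, so multi-mapping exists), 92 ERCC-like spike-ins of
#' 250-2000 nt, 20 tRNA-like transcripts of ~75 nt carrying 1-4
#' modification sites clustered near positions 20, 30 and 50, plus snoRNA,
#' rRNA and other non-coding transcripts, and optionally decoy transcripts
#' (near-copies standing in for haplotype/patch sequences).
#'
#' @param nProteinCoding,nErcc,nTrna,nSnoRna,nRrna,nOtherNc,nDecoy Numbers
#'   of transcripts (genes) per type.
#' @param nIsoformGenes Number of protein-coding genes with two isoforms.
#' @param pcLengthRange,erccLengthRange,snoLengthRange,rrnaLengthRange,otherLengthRange
#'   Length ranges (nt) per type.
#' @param trnaLengthMean,trnaLengthSd Normal length model for tRNAs,
#'   clipped to 60-100 nt.
#' @param trnaModSites Either `NULL` (default: each tRNA gets 1-4 sites
#'   drawn from Normal clusters centred at 20, 30, 50 with sd 3, clipped
#'   to the transcript) or a fixed integer vector of positions applied to
#'   every tRNA, e.g. `c(20, 30, 50)` for the canonical mechanism
#'   scenario.
#' @param trnaAnticodonPool Anticodon labels sampled by tRNA genes; fewer
#'   labels than genes makes anticodon aggregation non-trivial.
#' @return A list of class `transcriptomeConfig`.
#' @export
transcriptomeConfig <- function(nProteinCoding = 60L, nErcc = 92L,
                                nTrna = 20L, nSnoRna = 10L, nRrna = 2L,
                                nOtherNc = 10L, nDecoy = 0L,
                                nIsoformGenes = 5L,
                                pcLengthRange = c(500L, 3000L),
                                erccLengthRange = c(250L, 2000L),
                                snoLengthRange = c(70L, 300L),
                                rrnaLengthRange = c(120L, 1800L),
                                otherLengthRange = c(200L, 1000L),
                                trnaLengthMean = 75, trnaLengthSd = 4,
                                trnaModSites = NULL,
                                trnaAnticodonPool = c("AGC", "ACG", "GCC",
                                  "CTT", "GTT", "TGG", "GTG", "CAT",
                                  "AAT", "TCC", "CTG", "TAC")) {
  cfg <- list(nProteinCoding = as.integer(nProteinCoding),
              nErcc = as.integer(nErcc), nTrna = as.integer(nTrna),
              nSnoRna = as.integer(nSnoRna), nRrna = as.integer(nRrna),
              nOtherNc = as.integer(nOtherNc), nDecoy = as.integer(nDecoy),
              nIsoformGenes = as.integer(nIsoformGenes),
              pcLengthRange = as.integer(pcLengthRange),
              erccLengthRange = as.integer(erccLengthRange),
              snoLengthRange = as.integer(snoLengthRange),
              rrnaLengthRange = as.integer(rrnaLengthRange),
              otherLengthRange = as.integer(otherLengthRange),
              trnaLengthMean = trnaLengthMean, trnaLengthSd = trnaLengthSd,
              trnaModSites = if (!is.null(trnaModSites))
                sort(as.integer(trnaModSites)),
              trnaAnticodonPool = trnaAnticodonPool)
  counts <- unlist(cfg[c("nProteinCoding", "nErcc", "nTrna", "nSnoRna",
                         "nRrna", "nOtherNc", "nDecoy")])
  if (any(counts < 0L))
    stop("transcript counts must be nonnegative")
  for (rg in list(cfg$pcLengthRange, cfg$erccLengthRange,
                  cfg$snoLengthRange, cfg$rrnaLengthRange,
                  cfg$otherLengthRange)) {
    if (length(rg) != 2L || rg[1] < 1L || rg[1] > rg[2])
      stop("length ranges must be increasing pairs of positive integers")
  }
  if (cfg$erccLengthRange[1] < 250L || cfg$erccLengthRange[2] > 2000L)
    stop("ERCC lengths must lie within 250-2000 nt")
  if (cfg$nIsoformGenes > cfg$nProteinCoding)
    stop("nIsoformGenes cannot exceed nProteinCoding")
  if (cfg$nDecoy > cfg$nProteinCoding)
    stop("nDecoy cannot exceed nProteinCoding")
  structure(cfg, class = "transcriptomeConfig")
}

# draw modification positions for one tRNA: 1-4 sites from clusters at
# 20/30/50 (sd 3), clipped inside the transcript, strictly increasing
draw_mod_sites <- function(L, fixed = NULL) {
  if (!is.null(fixed))
    return(sort(unique(pmin(pmax(fixed, 1L), L))))
  nsites <- sample(1:4, 1L)
  centers <- sample(c(20, 30, 50), nsites, replace = nsites > 3L)
  pos <- as.integer(round(stats::rnorm(nsites, centers, 3)))
  pos <- pmin(pmax(pos, 2L), L - 1L)
  sort(unique(pos))
}

#' Generate the toy transcriptome
#'
#' Deterministic for a fixed seed. Sequences are uniform random DNA;
#' two-isoform genes share the 5' two-thirds of the primary isoform so
#' that reads from the shared region are genuinely multi-mapping; decoy
#' transcripts are near-copies (0.5% substitutions) of protein-coding
#' transcripts, flagged `is_decoy`.
#'
#' @param config A [transcriptomeConfig()] list.
#' @param seed Integer seed.
#' @return A [TranscriptomeSet-class].
#' @examples
#' txome <- buildTranscriptome(transcriptomeConfig(nProteinCoding = 4,
#'   nErcc = 8, nTrna = 2, nSnoRna = 0, nRrna = 0, nOtherNc = 0,
#'   nIsoformGenes = 1), seed = 1)
#' table(geneTypes(txome))
#' @export
buildTranscriptome <- function(config = transcriptomeConfig(), seed = 1L) {
  if (!inherits(config, "transcriptomeConfig"))
    config <- do.call(transcriptomeConfig, config)
  with_rng(seed, {
    ids <- character(0); genes <- character(0); types <- character(0)
    acs <- character(0); decoy <- logical(0); seqs <- character(0)
    mods <- list()

    add <- function(id, gene, type, seq, mp = integer(0), ac = NA_character_,
                    dec = FALSE) {
      ids <<- c(ids, id); genes <<- c(genes, gene); types <<- c(types, type)
      seqs <<- c(seqs, seq); mods[[length(mods) + 1L]] <<- as.integer(mp)
      acs <<- c(acs, ac); decoy <<- c(decoy, dec)
    }

    # protein coding (first nIsoformGenes genes get a second isoform)
    for (i in seq_len(config$nProteinCoding)) {
      g <- sprintf("PCG_%03d", i)
      L <- sample(config$pcLengthRange[1]:config$pcLengthRange[2], 1L)
      s1 <- random_dna(1L, L)
      add(paste0(g, "_T1"), g, "protein_coding", s1)
      if (i <= config$nIsoformGenes) {
        shared <- substr(s1, 1L, as.integer(floor(2 * L / 3)))
        tail_len <- max(as.integer(floor(L / 6)), 50L)
        add(paste0(g, "_T2"), g, "protein_coding",
            paste0(shared, random_dna(1L, tail_len)))
      }
    }
    # ERCC-like spike-ins: one gene per transcript
    for (i in seq_len(config$nErcc)) {
      id <- sprintf("ERCC_%04d", i)
      L <- sample(config$erccLengthRange[1]:config$erccLengthRange[2], 1L)
      add(id, id, "ERCC", random_dna(1L, L))
    }
    # tRNA-like short transcripts with modification sites
    for (i in seq_len(config$nTrna)) {
      ac <- sample(config$trnaAnticodonPool, 1L)
      g <- sprintf("tRNA-%s-%02d", ac, i)
      L <- as.integer(round(stats::rnorm(1, config$trnaLengthMean,
                                         config$trnaLengthSd)))
      L <- min(max(L, 60L), 100L)
      add(paste0(g, "_T1"), g, "tRNA", random_dna(1L, L),
          mp = draw_mod_sites(L, config$trnaModSites), ac = ac)
    }
    for (i in seq_len(config$nSnoRna)) {
      g <- sprintf("SNORD_%03d", i)
      L <- sample(config$snoLengthRange[1]:config$snoLengthRange[2], 1L)
      add(paste0(g, "_T1"), g, "snoRNA", random_dna(1L, L))
    }
    for (i in seq_len(config$nRrna)) {
      g <- sprintf("rRNA_%02d", i)
      L <- sample(config$rrnaLengthRange[1]:config$rrnaLengthRange[2], 1L)
      add(paste0(g, "_T1"), g, "rRNA", random_dna(1L, L))
    }
    for (i in seq_len(config$nOtherNc)) {
      g <- sprintf("NCRNA_%03d", i)
      L <- sample(config$otherLengthRange[1]:config$otherLengthRange[2], 1L)
      add(paste0(g, "_T1"), g, "other_ncRNA", random_dna(1L, L))
    }
    # decoys: near-copies of protein-coding primaries
    for (i in seq_len(config$nDecoy)) {
      src_idx <- which(genes == sprintf("PCG_%03d", i) & !decoy)[1]
      s <- strsplit(seqs[src_idx], "")[[1]]
      nmut <- max(1L, as.integer(round(length(s) * 0.005)))
      at <- sample(length(s), nmut)
      for (p in at) s[p] <- substitute_base(s[p])
      add(sprintf("PCG_%03d_DECOY", i), genes[src_idx], "protein_coding",
          paste(s, collapse = ""), dec = TRUE)
    }

    sset <- Biostrings::DNAStringSet(seqs)
    names(sset) <- ids
    new("TranscriptomeSet", sequences = sset,
        txData = DataFrame(gene_id = genes, gene_type = types,
                           anticodon = acs, is_decoy = decoy,
                           mod_positions = IntegerList(mods),
                           row.names = ids))
  })
}

#' @rdname transcriptome-accessors
#' @export
setMethod("transcriptIds", "TranscriptomeSet", function(x, ...)
  names(x@sequences))

#' @rdname transcriptome-accessors
#' @export
setMethod("geneIds", "TranscriptomeSet", function(x, ...)
  stats::setNames(x@txData$gene_id, transcriptIds(x)))

#' @rdname transcriptome-accessors
#' @export
setMethod("geneTypes", "TranscriptomeSet", function(x, ...)
  stats::setNames(x@txData$gene_type, transcriptIds(x)))

#' @rdname transcriptome-accessors
#' @export
setMethod("anticodons", "TranscriptomeSet", function(x, ...)
  stats::setNames(x@txData$anticodon, transcriptIds(x)))

#' @rdname transcriptome-accessors
#' @export
setMethod("txLengths", "TranscriptomeSet", function(x, ...)
  stats::setNames(Biostrings::width(x@sequences), transcriptIds(x)))

#' @rdname transcriptome-accessors
#' @export
setMethod("modPositions", "TranscriptomeSet", function(x, ...)
  stats::setNames(x@txData$mod_positions, transcriptIds(x)))

#' @rdname transcriptome-accessors
#' @export
setMethod("sequences", "TranscriptomeSet", function(x, ...) x@sequences)

#' @rdname transcriptome-accessors
#' @export
setMethod("geneOf", "TranscriptomeSet", function(x, transcript_id, ...) {
  g <- geneIds(x)
  if (!all(transcript_id %in% names(g)))
    stop("unknown transcript id(s): ",
         paste(setdiff(transcript_id, names(g)), collapse = ", "))
  g[transcript_id]
})

#' Subset a TranscriptomeSet by transcript
#'
#' @param x A `TranscriptomeSet`.
#' @param i Index, logical vector or transcript ids.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "TranscriptomeSet", function(x, i, j, ..., drop = FALSE) {
  new("TranscriptomeSet", sequences = x@sequences[i],
      txData = x@txData[i, , drop = FALSE])
})

setMethod("length", "TranscriptomeSet", function(x) length(x@sequences))

setMethod("show", "TranscriptomeSet", function(object) {
  tab <- table(object@txData$gene_type)
  cat(sprintf("TranscriptomeSet with %d transcripts (%d genes)\n",
              length(object), length(unique(object@txData$gene_id))))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  lengths %d-%d nt; %d transcripts carry modification sites\n",
              min(Biostrings::width(object@sequences)),
              max(Biostrings::width(object@sequences)),
              sum(lengths(object@txData$mod_positions) > 0)))
})

#' Write / read a transcriptome as FASTA
#'
#' Headers follow `transcript_id|gene_id|gene_type[|anticodon]`.
#' Modification positions and decoy flags are object-level annotation and
#' are not carried in FASTA.
#'
#' @param txome A [TranscriptomeSet-class].
#' @param path FASTA file path.
#' @return `writeTranscriptome` returns `path` invisibly;
#'   `readTranscriptome` a [TranscriptomeSet-class] (with empty
#'   modification annotation).
#' @export
writeTranscriptome <- function(txome, path) {
  out <- txome@sequences
  hd <- paste(transcriptIds(txome), txome@txData$gene_id,
              txome@txData$gene_type, sep = "|")
  has_ac <- !is.na(txome@txData$anticodon)
  hd[has_ac] <- paste(hd[has_ac], txome@txData$anticodon[has_ac], sep = "|")
  names(out) <- hd
  Biostrings::writeXStringSet(out, path, width = 80L)
  invisible(path)
}

#' @rdname writeTranscriptome
#' @export
readTranscriptome <- function(path) {
  sset <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(sset), "|", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("FASTA headers must be transcript_id|gene_id|gene_type[|anticodon]")
  ids <- vapply(parts, `[`, "", 1L)
  names(sset) <- ids
  new("TranscriptomeSet", sequences = sset,
      txData = DataFrame(
        gene_id = vapply(parts, `[`, "", 2L),
        gene_type = vapply(parts, `[`, "", 3L),
        anticodon = vapply(parts, function(p)
          if (length(p) >= 4L) p[4L] else NA_character_, ""),
        is_decoy = grepl("DECOY", ids, fixed = TRUE),
        mod_positions = IntegerList(rep(list(integer(0)), length(sset))),
        row.names = ids))
}
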
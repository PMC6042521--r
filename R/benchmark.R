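#' @include AllClasses.R AllGenerics.R utils.R transcriptome.R design.R
#' @include abundance.R reads.R kmer.R align.R eval.R
NULL

#' Configuration of a full benchmark run
#'
#' Bundles every tunable of the simulate-quantify-evaluate pipeline with
#' explicit seeds, and round-trips losslessly through JSON.
#'
#' @param txConfig Transcriptome generator settings
#'   ([transcriptomeConfig()]).
#' @param z Total-signal ratio of A to B (default 1.43).
#' @param kGrid k-mer sizes for the alignment-free quantifier (default
#'   11, 15, 21, 31).
#' @param depth Reads per library for replicate count simulation.
#' @param nReads Simulated reads per library fed to the quantifiers.
#' @param readLength Read length (default 75, so reads span full-length
#'   tRNA-like transcripts as in TGIRT-style libraries).
#' @param misRate Per-covered-site misincorporation probability.
#' @param seqError Per-base sequencing error probability.
#' @param dispersion Negative binomial replicate dispersion.
#' @param nReplicates Replicates per sample.
#' @param maxMismatch Alignment mismatch budget (default
#'   `ceiling(0.15 * readLength)`).
#' @param seed Base seed; all stage seeds are derived from it.
#' @return A list of class `runConfig`.
#' @export
runConfig <- function(txConfig = transcriptomeConfig(), z = 1.43,
                      kGrid = c(11L, 15L, 21L, 31L), depth = 50000L,
                      nReads = 5000L, readLength = 75L, misRate = 0.8,
                      seqError = 0.001, dispersion = 0.01,
                      nReplicates = 3L, maxMismatch = NULL, seed = 1L) {
  if (!inherits(txConfig, "transcriptomeConfig"))
    txConfig <- do.call(transcriptomeConfig, txConfig)
  structure(list(
    txConfig = txConfig, z = z, kGrid = as.integer(kGrid),
    depth = as.integer(depth), nReads = as.integer(nReads),
    readLength = as.integer(readLength), misRate = misRate,
    seqError = seqError, dispersion = dispersion,
    nReplicates = as.integer(nReplicates),
    maxMismatch = if (!is.null(maxMismatch)) as.integer(maxMismatch)
                  else as.integer(ceiling(0.15 * readLength)),
    seed = as.integer(seed)), class = "runConfig")
}

#' Serialize / restore a run configuration as JSON
#'
#' @param config A [runConfig()] list.
#' @param path JSON file path.
#' @return `runConfigToJson` returns `path` invisibly;
#'   `runConfigFromJson` a `runConfig`.
#' @export
runConfigToJson <- function(config, path) {
  x <- unclass(config)
  x$txConfig <- unclass(x$txConfig)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname runConfigToJson
#' @export
runConfigFromJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$txConfig <- do.call(transcriptomeConfig,
                        x$txConfig[!vapply(x$txConfig, is.null, TRUE)])
  do.call(runConfig, x)
}

#' Evaluate one quantifier's gene table against the titration design
#'
#' Builds the fold-change table, then: R-squared and RMSE of measured vs
#' expected C/D log2 fold changes per expression stratum, length
#' quartile and gene type; ROC/AUC of A-vs-B DE calls on the spike-in
#' truth; detected-gene counts per type (mean number of genes with
#' TPM > 0.1 per library); and the cumulative absolute tRNA fold-change
#' error curve. Fold-change metrics cover the genes the quantifier
#' detected in every sample (detected in a sample = TPM > 0.1 in any of
#' its replicates).
#'
#' @param geneTable An [AbundanceTable-class] over genes (`count` or
#'   `count_scale`) with samples A-D.
#' @param annotation [geneAnnotation()] output.
#' @param design A [TitrationDesign-class].
#' @param erccDesign Spike-in group assignment from
#'   [assignErccDesign()].
#' @return A list: `foldChanges`, `strata` (data.frame of per-stratum
#'   metrics), `erccAuc`, `detectedByType` (mean detected genes per
#'   library, by type), `detectedBySample` (gene x sample logical
#'   matrix), `trnaErrorCurve`.
#' @export
evaluateQuantifier <- function(geneTable, annotation, design, erccDesign) {
  fc <- suppressMessages(foldChangeTable(geneTable, annotation, design))

  # detection: a gene is detected in a sample when its TPM exceeds 0.1
  # in any replicate; the per-type summary averages over samples
  gtpm <- toTPM(geneTable, lengths = stats::setNames(
    annotation$gene_length, rownames(annotation)))
  gm <- abundanceMatrix(gtpm)
  samples <- unique(colData(gtpm)$sample)
  det_sample <- vapply(samples, function(s)
    rowSums(gm[, colData(gtpm)$sample == s, drop = FALSE] > 0.1) > 0,
    logical(nrow(gm)))
  # the reported detected count is the mean per library (the convention
  # of per-library detection bar charts), which is more resolving than
  # the per-sample rule when dropout leaves sporadic single-library hits
  det_lib <- gm > 0.1
  det_type <- vapply(unique(annotation$gene_type), function(ty) {
    g <- rownames(annotation)[annotation$gene_type == ty]
    g <- intersect(g, rownames(det_lib))
    if (!length(g)) 0 else mean(colSums(det_lib[g, , drop = FALSE]))
  }, 1.0)

  # fold-change metrics are computed over the genes this quantifier
  # detected in every sample: only quantified genes enter the DE test,
  # so the tested-gene count is itself pipeline-dependent
  fc$detected <- rownames(fc) %in%
    rownames(det_sample)[rowSums(det_sample) == length(samples)]
  fcd <- fc[fc$detected, , drop = FALSE]
  y <- fcd$measured_log2fc_CD
  f <- fcd$expected_log2fc_CD
  names(y) <- names(f) <- rownames(fcd)

  strata_rows <- list()
  for (scheme in c("mean_expression", "gene_length", "gene_type")) {
    st <- if (nrow(fcd)) stratify(fcd, by = scheme) else list()
    for (nm in names(st)) {
      g <- st[[nm]]
      r2 <- if (length(g) >= 2L && stats::sd(y[g]) > 0)
        rSquared(y[g], f[g]) else NA_real_
      rr <- if (length(g) >= 1L) rmse(y[g], f[g]) else NA_real_
      strata_rows[[length(strata_rows) + 1L]] <- data.frame(
        scheme = scheme, stratum = nm, n_genes = length(g),
        R2 = r2, RMSE = rr)
    }
  }
  strata <- if (length(strata_rows)) do.call(rbind, strata_rows)
            else data.frame(scheme = character(0), stratum = character(0),
                            n_genes = integer(0), R2 = numeric(0),
                            RMSE = numeric(0))

  # spike-in ROC: A-vs-B DE p-values against the designed truth
  ercc_g <- intersect(erccDesign$transcript_id, rownames(fcd))
  auc <- if (length(ercc_g) >= 2L) {
    truth <- erccDesign$is_de[match(ercc_g, erccDesign$transcript_id)]
    if (any(truth) && any(!truth)) rocAuc(fcd[ercc_g, "p_AB"], truth)$auc
    else NA_real_
  } else NA_real_

  trna <- rownames(fcd)[fcd$gene_type == "tRNA"]
  curve <- sort(abs(y[trna] - f[trna]))
  list(foldChanges = fc, strata = strata, erccAuc = auc,
       detectedByType = det_type, detectedBySample = det_sample,
       trnaErrorCurve = data.frame(rank = seq_along(curve),
                                   gene = names(curve),
                                   cum_abs_error = cumsum(unname(curve))))
}

#' Run the full simulate-quantify-evaluate benchmark
#'
#' Generates the transcriptome and titration abundances, simulates
#' replicate counts and error-bearing reads for every library, quantifies
#' every library with the alignment-based pipeline and with the
#' alignment-free pipeline at each k of the grid, and evaluates all of
#' them against the titration model and the spike-in truth. After each
#' stage a read/gene conservation check is performed; failures abort
#' with a stage-labelled error.
#'
#' @param config A [runConfig()] list.
#' @param outdir Optional directory; when given, FASTA/FASTQ/TSV/JSON
#'   artifacts and the report tables are written there.
#' @param verbose Print stage progress (default `TRUE`).
#' @return A list: `config`, `txome`, `design`, `erccDesign`,
#'   `trueTpm`, `counts`, `quantifiers` (named list of per-quantifier
#'   results, each with `geneTable` and the [evaluateQuantifier()]
#'   output), `report` (the tidy summary table), `manifest`.
#' @export
runBenchmark <- function(config = runConfig(), outdir = NULL,
                         verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- config$seed

  say("stage: transcriptome")
  txome <- stage("transcriptome",
                 buildTranscriptome(config$txConfig,
                                    seed = derive_seed(seed, "txome")))
  design <- titrationDesign(z = config$z)
  ann <- geneAnnotation(txome)

  say("stage: abundances")
  abres <- stage("abundances",
                 makeAbAbundances(txome, design,
                                  seed = derive_seed(seed, "abund")))
  full <- mixTitration(abres$abundance, design)
  trueTpm <- toTPM(full)
  lens <- txLengths(txome)

  say("stage: replicate counts")
  counts <- stage("counts",
                  simulateReplicateCounts(trueTpm, lens, config$depth,
                                          config$dispersion,
                                          config$nReplicates,
                                          config$readLength,
                                          seed = derive_seed(seed, "counts")))

  say("stage: reads")
  cd <- colData(counts)
  libs <- paste(cd$sample, cd$replicate, sep = "_")
  readsets <- stage("reads", {
    out <- list()
    for (j in seq_along(libs)) {
      out[[libs[j]]] <- simulateReads(
        txome, counts, cd$sample[j], cd$replicate[j],
        nReads = config$nReads, readLength = config$readLength,
        misRate = config$misRate, seqError = config$seqError,
        seed = derive_seed(seed, paste0("reads_", libs[j])))
      if (length(out[[libs[j]]]) != config$nReads)
        stop("read count mismatch in library ", libs[j])
    }
    out
  })

  quantifiers <- list()

  say("stage: alignment quantifier")
  quantifiers[["align"]] <- stage("align", {
    gmat <- vapply(libs, function(lb)
      quantifyAlign(txome, readsets[[lb]],
                    maxMismatch = config$maxMismatch,
                    seed = derive_seed(seed, paste0("sel_", lb)))$geneCounts,
      numeric(length(unique(unname(geneIds(txome))))))
    gt <- abundanceTable(gmat, sample = cd$sample,
                         replicate = cd$replicate, unit = "count",
                         readLength = config$readLength)
    c(list(geneTable = gt, k = NA_integer_),
      evaluateQuantifier(gt, ann, design, abres$erccDesign))
  })

  for (k in config$kGrid) {
    nm <- paste0("kmer_k", k)
    say("stage: k-mer quantifier, k = ", k)
    quantifiers[[nm]] <- stage(nm, {
      idx <- suppressWarnings(buildKmerIndex(txome, k))
      tmat <- vapply(libs, function(lb) {
        ec <- collectEquivalenceClasses(readsets[[lb]], idx)
        if (sum(ec@counts) + ec@unassigned != config$nReads)
          stop("read conservation violated in library ", lb)
        suppressWarnings(
          emAbundances(ec, effectiveLength(lens, config$readLength)))
      }, numeric(length(lens)))
      tpm <- abundanceTable(tmat, sample = cd$sample,
                            replicate = cd$replicate, unit = "TPM")
      gt <- aggregateToGene(tpm, txome, librarySize = config$nReads,
                            readLength = config$readLength)
      c(list(geneTable = gt, k = as.integer(k), transcriptTpm = tpm),
        evaluateQuantifier(gt, ann, design, abres$erccDesign))
    })
  }

  report <- reportTables(quantifiers)
  manifest <- list(
    package_version = as.character(utils::packageVersion("titrabench")),
    r_version = as.character(getRversion()),
    seed = seed, libraries = libs,
    n_reads_per_library = config$nReads,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(config = config, txome = txome, design = design,
                 erccDesign = abres$erccDesign, trueTpm = trueTpm,
                 counts = counts, readsets = readsets,
                 quantifiers = quantifiers, report = report,
                 manifest = manifest)
  if (!is.null(outdir)) writeBenchmark(result, outdir)
  result
}

#' Head-to-head fold-change accuracy on a common gene set
#'
#' Per-gene-type comparison of quantifiers from one benchmark run. The
#' summary report mirrors the convention of per-pipeline tested-gene
#' sets; this helper instead restricts to the genes detected by every
#' compared quantifier (in all four samples), so that RMSE differences
#' reflect read-assignment behaviour on identical genes rather than
#' differences in which genes were detected. Detected counts remain per
#' quantifier.
#'
#' @param result A [runBenchmark()] result (or its `quantifiers`
#'   element).
#' @param geneType Gene type to compare (default `"tRNA"`).
#' @param quantifiers Names of the quantifiers to compare (default all).
#' @return A data.frame with one row per quantifier: `rmse_common`
#'   (RMSE of measured vs expected C/D log2 fold change on the common
#'   detected genes), `n_common`, `detected` (mean detected genes of
#'   this type per library, quantifier's own set).
#' @export
compareQuantifiers <- function(result, geneType = "tRNA",
                               quantifiers = NULL) {
  qs <- if (!is.null(result$quantifiers)) result$quantifiers else result
  if (!is.null(quantifiers)) qs <- qs[quantifiers]
  if (length(qs) < 2L) stop("need at least two quantifiers to compare")
  det_sets <- lapply(qs, function(q) {
    fc <- q$foldChanges
    rownames(fc)[fc$detected & fc$gene_type == geneType]
  })
  common <- Reduce(intersect, det_sets)
  out <- do.call(rbind, lapply(names(qs), function(nm) {
    fc <- qs[[nm]]$foldChanges
    rr <- if (length(common))
      rmse(fc[common, "measured_log2fc_CD"],
           fc[common, "expected_log2fc_CD"]) else NA_real_
    data.frame(quantifier = nm, rmse_common = rr,
               n_common = length(common),
               detected = unname(qs[[nm]]$detectedByType[geneType]))
  }))
  rownames(out) <- NULL
  out
}

#' Tidy summary tables of a benchmark run
#'
#' One row per quantifier, k, stratification scheme and stratum, with the
#' number of genes tested, R-squared, RMSE and (for the spike-in truth)
#' the ROC AUC. Empty strata yield a row with `n_genes = 0` and missing
#' metrics.
#'
#' @param quantifiers The `quantifiers` element of a [runBenchmark()]
#'   result (or the full result).
#' @return A data.frame.
#' @export
reportTables <- function(quantifiers) {
  if (!is.null(quantifiers$quantifiers))
    quantifiers <- quantifiers$quantifiers
  if (!length(quantifiers)) stop("no quantifier output to report")
  rows <- lapply(names(quantifiers), function(nm) {
    q <- quantifiers[[nm]]
    if (is.null(q$strata)) stop("missing evaluation output for ", nm)
    df <- q$strata
    df$quantifier <- if (is.na(q$k)) "align" else "kmer"
    df$k <- q$k
    df$ercc_auc <- ifelse(df$scheme == "gene_type" & df$stratum == "ERCC",
                          q$erccAuc, NA_real_)
    df
  })
  out <- do.call(rbind, rows)
  out[, c("quantifier", "k", "scheme", "stratum", "n_genes", "R2",
          "RMSE", "ercc_auc")]
}

#' Write benchmark artifacts to a directory
#'
#' Emits the transcriptome FASTA, the design and run configuration as
#' JSON, per-library FASTQ, the replicate count table, per-quantifier
#' gene tables and fold-change tables, the summary report TSV, and a
#' manifest JSON. Rerunning with an identical configuration reproduces
#' the files byte for byte.
#'
#' @param result A [runBenchmark()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeBenchmark <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeTranscriptome(result$txome, file.path(outdir, "transcriptome.fa"))
  designToJson(result$design, file.path(outdir, "design.json"))
  runConfigToJson(result$config, file.path(outdir, "run_config.json"))
  write_tsv(as.data.frame(result$erccDesign),
            file.path(outdir, "ercc_design.tsv"))
  writeAbundanceTable(result$counts, file.path(outdir, "counts.tsv"))
  for (lb in names(result$readsets))
    writeReadsFastq(result$readsets[[lb]],
                    file.path(outdir, paste0("reads_", lb, ".fastq")))
  for (nm in names(result$quantifiers)) {
    q <- result$quantifiers[[nm]]
    writeAbundanceTable(q$geneTable,
                        file.path(outdir, paste0("genes_", nm, ".tsv")))
    fc <- q$foldChanges
    fc$gene_id <- rownames(fc)
    write_tsv(fc[, c("gene_id", setdiff(colnames(fc), "gene_id"))],
              file.path(outdir, paste0("foldchanges_", nm, ".tsv")))
  }
  write_tsv(result$report, file.path(outdir, "report.tsv"))
  # machine-readable summary: R2 per stratum, RMSE per gene type, AUC
  summary_json <- lapply(result$quantifiers, function(q) {
    ty <- q$strata[q$strata$scheme == "gene_type", ]
    ex <- q$strata[q$strata$scheme == "mean_expression", ]
    list(r2_by_expression = stats::setNames(as.list(ex$R2), ex$stratum),
         rmse_by_gene_type = stats::setNames(as.list(ty$RMSE), ty$stratum),
         ercc_auc = q$erccAuc,
         detected_by_type = as.list(q$detectedByType))
  })
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
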
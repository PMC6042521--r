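#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a titration design
#'
#' The MAQC-style titration design: two reference samples A and B are
#' mixed by mass in ratios 3:1 (sample C) and 1:3 (sample D). Because the
#' total signal of A and B differ by the factor `z`, the log2 fold change
#' between C and D for a gene is a known function of its A/B fold change
#' (see [expectedCdLog2fc()]). ERCC-like spike-ins are assigned to groups
#' with designed A:B ratios so that the design carries its own
#' differential-expression truth: a spike-in is truly DE exactly when its
#' group ratio differs from 1.
#'
#' @param z Total-signal ratio of sample A to sample B; default 1.43.
#' @param mixC,mixD Mass weights of (A, B) in samples C and D.
#' @param erccRatios Named numeric vector of designed A:B ratios, one per
#'   spike-in group.
#' @param erccGroupSize Spike-ins per group.
#' @return A [TitrationDesign-class] object.
#' @examples
#' d <- titrationDesign()
#' k1(d)  # 3z/(3z+1)
#' k2(d)  # z/(z+3)
#' @export
titrationDesign <- function(z = 1.43,
                            mixC = c(3, 1), mixD = c(1, 3),
                            erccRatios = c("0.67:1" = 0.67, "1:1" = 1,
                                           "2:1" = 2, "4:1" = 4),
                            erccGroupSize = 23L) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0)
    stop("'z' must be a single positive number")
  new("TitrationDesign", z = as.numeric(z), mixC = as.numeric(mixC),
      mixD = as.numeric(mixD), erccRatios = erccRatios,
      erccGroupSize = as.integer(erccGroupSize))
}

#' @rdname design-accessors
#' @export
setMethod("zRatio", "TitrationDesign", function(x, ...) x@z)

#' @rdname design-accessors
#' @export
setMethod("k1", "TitrationDesign", function(x, ...) {
  z <- x@z
  x@mixC[1] * z / (x@mixC[1] * z + x@mixC[2])
})

#' @rdname design-accessors
#' @export
setMethod("k2", "TitrationDesign", function(x, ...) {
  z <- x@z
  x@mixD[1] * z / (x@mixD[1] * z + x@mixD[2])
})

#' @rdname design-accessors
#' @export
setMethod("erccRatios", "TitrationDesign", function(x, ...) x@erccRatios)

setMethod("show", "TitrationDesign", function(object) {
  cat("TitrationDesign\n")
  cat(sprintf("  z = %g (k1 = %.5f, k2 = %.5f)\n", object@z,
              k1(object), k2(object)))
  cat(sprintf("  sample C = %g:%g (A:B by mass); sample D = %g:%g\n",
              object@mixC[1], object@mixC[2], object@mixD[1],
              object@mixD[2]))
  cat(sprintf("  spike-in groups (A:B): %s; %d per group\n",
              paste(names(object@erccRatios), collapse = ", "),
              object@erccGroupSize))
})

#' Assign ERCC-like spike-ins to designed ratio groups
#'
#' Randomly partitions the spike-in transcripts into the design's ratio
#' groups, all of equal size. The truth label `is_de` is `TRUE` exactly
#' when the designed A:B ratio of the group differs from 1; with 92
#' spike-ins in four groups this yields 23 per group, 69 of them truly DE.
#'
#' @param ercc_ids Character vector of spike-in transcript ids (or a
#'   [TranscriptomeSet-class], from which ERCC transcripts are taken).
#' @param design A [TitrationDesign-class].
#' @param seed Integer seed for the random partition.
#' @return A [S4Vectors::DataFrame] with columns `transcript_id`, `group`,
#'   `ratio` (designed A:B), `is_de`.
#' @export
assignErccDesign <- function(ercc_ids, design, seed = 1L) {
  if (is(ercc_ids, "TranscriptomeSet"))
    ercc_ids <- transcriptIds(ercc_ids)[geneTypes(ercc_ids) == "ERCC"]
  ratios <- erccRatios(design)
  ng <- length(ratios)
  n <- length(ercc_ids)
  if (n %% ng != 0L)
    stop(sprintf(
      "number of spike-ins (%d) is not divisible by the number of groups (%d); remainder %d",
      n, ng, n %% ng))
  per <- n %/% ng
  shuffled <- with_rng(seed, sample(ercc_ids))
  grp <- rep(names(ratios), each = per)
  out <- DataFrame(transcript_id = shuffled, group = grp,
                   ratio = unname(ratios[grp]),
                   is_de = unname(ratios[grp] != 1))
  out[order(out$transcript_id), , drop = FALSE]
}

#' Serialize and restore a titration design as JSON
#'
#' Round-trips all design fields losslessly; derived constants `k1`, `k2`
#' are written for readability but always recomputed from `z` on read.
#'
#' @param design A [TitrationDesign-class].
#' @param path File path to write to / read from.
#' @return `designToJson` returns `path` invisibly; `designFromJson`
#'   returns a [TitrationDesign-class].
#' @export
designToJson <- function(design, path) {
  x <- list(z = design@z, mixC = design@mixC, mixD = design@mixD,
            erccRatios = as.list(design@erccRatios),
            erccGroupSize = design@erccGroupSize,
            k1 = k1(design), k2 = k2(design))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname designToJson
#' @export
designFromJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  titrationDesign(z = x$z, mixC = x$mixC, mixD = x$mixD,
                  erccRatios = unlist(x$erccRatios),
                  erccGroupSize = x$erccGroupSize)
}
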
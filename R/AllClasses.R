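#' @import methods
#' @importClassesFrom Biostrings DNAString
NULL

#' Mitogenome: a circular mitochondrial reference with feature annotation
#'
#' Holds a circular DNA sequence together with a feature annotation
#' (\linkS4class{GRanges}) describing genes and masked regions. Feature types
#' are \code{"protein"}, \code{"tRNA"}, \code{"rRNA"}, \code{"noncoding"},
#' \code{"primer"} and \code{"repeat"}; primer and repeat features are masks
#' and may overlap gene features. Protein features carry a reading-frame
#' offset (0--2) in the \code{frame} metadata column; for the synthetic
#' default every protein feature has length divisible by three and frame 0.
#'
#' Coordinates are 1-based inclusive throughout.
#'
#' @slot sequence a \linkS4class{DNAString}, the circular reference.
#' @slot features a \linkS4class{GRanges} with metadata columns \code{name},
#'   \code{type} and \code{frame}.
#'
#' @seealso [generateMitogenome()], [extendCircular()], [genomeFeatures()]
#' @export
setClass("Mitogenome",
  representation(sequence = "DNAString", features = "GRanges"))

setValidity("Mitogenome", function(object) {
  L <- length(object@sequence)
  ft <- object@features
  msg <- character()
  if (L < 1L) msg <- c(msg, "sequence must be non-empty")
  need <- c("name", "type", "frame")
  if (!all(need %in% colnames(S4Vectors::mcols(ft))))
    msg <- c(msg, "features must carry mcols name, type, frame")
  else {
    if (length(ft) && (min(GenomicRanges::start(ft)) < 1L ||
                       max(GenomicRanges::end(ft)) > L))
      msg <- c(msg, "feature intervals must lie within 1..length(sequence)")
    bad <- !ft$type %in% c("protein", "tRNA", "rRNA", "noncoding",
                           "primer", "repeat")
    if (any(bad)) msg <- c(msg, "unknown feature type")
    prot <- ft[ft$type == "protein"]
    if (length(prot) && any(is.na(prot$frame) | !prot$frame %in% 0:2))
      msg <- c(msg, "protein features need a frame offset in 0..2")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Mitogenome length of the circular reference in bp.
#' @param x,object a \code{Mitogenome}.
#' @export
setMethod("length", "Mitogenome", function(x) length(x@sequence))

#' Accessors for Mitogenome objects
#'
#' @param x a \linkS4class{Mitogenome}.
#' @return \code{genomeSequence} returns the \linkS4class{DNAString};
#'   \code{genomeFeatures} the annotation \linkS4class{GRanges};
#'   \code{refBase} the reference base(s) at 1-based position(s) \code{pos}.
#' @export
genomeSequence <- function(x) {
  stopifnot(is(x, "Mitogenome"))
  x@sequence
}

#' @rdname genomeSequence
#' @export
genomeFeatures <- function(x) {
  stopifnot(is(x, "Mitogenome"))
  x@features
}

#' @rdname genomeSequence
#' @param pos integer vector of 1-based positions.
#' @export
refBase <- function(x, pos) {
  stopifnot(is(x, "Mitogenome"), all(pos >= 1L), all(pos <= length(x)))
  strsplit(as.character(x@sequence), "")[[1]][pos]
}

setMethod("show", "Mitogenome", function(object) {
  cat("Mitogenome of", length(object), "bp (circular)\n")
  tb <- table(object@features$type)
  if (length(tb))
    cat("features:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
})

#' ExtendedReference: circularity-aware padded reference
#'
#' A linearised copy of a circular genome in which the last \code{pad} bases
#' are prepended and the first \code{pad} bases appended, so reads (or calls)
#' spanning the origin land inside the body of the sequence. Positions on the
#' extended sequence map back to the original circle via [toOriginal()].
#'
#' @slot sequence the padded \linkS4class{DNAString} of length
#'   \code{originalLength + 2 * pad}.
#' @slot pad pad width in bp.
#' @slot originalLength length of the unpadded circular genome.
#' @seealso [extendCircular()], [toOriginal()], [mergeCircularCalls()]
#' @export
setClass("ExtendedReference",
  representation(sequence = "DNAString", pad = "integer",
                 originalLength = "integer"))

setValidity("ExtendedReference", function(object) {
  L <- object@originalLength
  p <- object@pad
  msg <- character()
  if (p < 0L) msg <- c(msg, "pad must be >= 0")
  if (p >= L) msg <- c(msg, "pad must be smaller than the genome")
  if (length(object@sequence) != L + 2L * p)
    msg <- c(msg, "sequence length must equal originalLength + 2*pad")
  if (p > 0L) {
    s <- as.character(object@sequence)
    if (substr(s, 1L, p) != substr(s, L + 1L, L + p))
      msg <- c(msg, "leading pad must equal the copied genome tail")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ExtendedReference total padded length.
#' @param x,object an \code{ExtendedReference}.
#' @export
setMethod("length", "ExtendedReference", function(x) length(x@sequence))

setMethod("show", "ExtendedReference", function(object) {
  cat(sprintf("ExtendedReference: %d bp body + 2 x %d bp pad = %d bp\n",
              object@originalLength, object@pad, length(object)))
})

#' Pileup: per-site base counts for one sample
#'
#' A count-level representation of deep sequencing of one mitogenome sample:
#' for every reference position the number of A, C, G and T observations.
#' Depth at a position is the sum of the four counts. The object also carries
#' the scalar per-base substitution error rate assumed for that sample's
#' sequencing, which the caller uses as its null error model.
#'
#' @slot counts integer matrix, positions x 4, columns \code{A,C,G,T}.
#' @slot ref character vector of reference bases, one per position.
#' @slot sampleId sample identifier.
#' @slot coverage nominal (target) coverage.
#' @slot errorRate per-base substitution probability.
#' @seealso [simulatePileup()], [callSites()], [pileupDepth()]
#' @export
setClass("Pileup",
  representation(counts = "matrix", ref = "character", sampleId = "character",
                 coverage = "numeric", errorRate = "numeric"))

setValidity("Pileup", function(object) {
  msg <- character()
  if (!identical(colnames(object@counts), DNA_BASES4))
    msg <- c(msg, "counts must have columns A, C, G, T")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (nrow(object@counts) != length(object@ref))
    msg <- c(msg, "one reference base per pileup row required")
  if (length(object@errorRate) != 1L || object@errorRate < 0 ||
      object@errorRate >= 0.25)
    msg <- c(msg, "errorRate must be a single value in [0, 0.25)")
  if (length(msg)) msg else TRUE
})

#' Accessors for Pileup objects
#'
#' @param x a \linkS4class{Pileup}.
#' @return \code{pileupCounts}: the positions x 4 count matrix;
#'   \code{pileupDepth}: integer vector of per-position depths;
#'   \code{errorRate}: the sample's assumed per-base error rate;
#'   \code{sampleId}: the sample identifier.
#' @export
pileupCounts <- function(x) {
  stopifnot(is(x, "Pileup"))
  x@counts
}

#' @rdname pileupCounts
#' @export
pileupDepth <- function(x) {
  stopifnot(is(x, "Pileup"))
  as.integer(rowSums(x@counts))
}

#' @rdname pileupCounts
#' @export
errorRate <- function(x) {
  stopifnot(is(x, "Pileup"))
  x@errorRate
}

#' @rdname pileupCounts
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "Pileup"))
  x@sampleId
}

setMethod("show", "Pileup", function(object) {
  dp <- rowSums(object@counts)
  cat(sprintf(
    "Pileup '%s': %d sites, nominal %gX (mean depth %.0f), error rate %g\n",
    object@sampleId, nrow(object@counts), object@coverage, mean(dp),
    object@errorRate))
})
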
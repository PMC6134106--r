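#' Extend a circular reference for origin-spanning alignment
#'
#' Copies the last \code{pad} bases of the genome in front of the sequence
#' and the first \code{pad} bases behind it, the standard trick that lets
#' linear aligners and callers handle reads (and variants) spanning the
#' origin of a circular mitogenome. Positions on the extended sequence map
#' back to the circle with [toOriginal()].
#'
#' @param genome a \linkS4class{Mitogenome}.
#' @param pad pad width in bp; must be smaller than the genome. \code{pad=0}
#'   gives an identity mapping.
#' @return an \linkS4class{ExtendedReference} of length
#'   \code{length(genome) + 2 * pad}.
#' @examples
#' g <- generateMitogenome(16211, seed = 1)
#' length(extendCircular(g, 500))   # 17211
#' @export
extendCircular <- function(genome, pad = 500) {
  L <- length(genome)
  pad <- as.integer(pad)
  if (pad >= L) stop("pad must be smaller than the genome length")
  s <- genomeSequence(genome)
  ext <- if (pad == 0L) s else
    Biostrings::xscat(Biostrings::subseq(s, L - pad + 1L, L), s,
                      Biostrings::subseq(s, 1L, pad))
  new("ExtendedReference", sequence = as(ext, "DNAString"), pad = pad,
      originalLength = L)
}

#' Map extended-reference positions back to the circle
#'
#' @param extref an \linkS4class{ExtendedReference}.
#' @param pos integer vector of 1-based positions on the extended sequence.
#' @return integer vector of 1-based positions on the original genome.
#' @export
toOriginal <- function(extref, pos) {
  stopifnot(is(extref, "ExtendedReference"))
  L <- extref@originalLength
  p <- extref@pad
  if (any(pos < 1L | pos > L + 2L * p))
    stop("position outside the extended reference")
  out <- integer(base::length(pos))
  lead <- pos <= p
  body <- pos > p & pos <= p + L
  tail <- pos > p + L
  out[lead] <- L - p + pos[lead]
  out[body] <- pos[body] - p
  out[tail] <- pos[tail] - p - L
  as.integer(out)
}

#' Call candidate heteroplasmic sites from a pileup
#'
#' At every covered site the minor allele (the non-majority base with the
#' highest count) is tested against the pileup's declared sequencing error
#' rate: the minor count is compared with an exact binomial upper tail under
#' the null that minor-base observations arise from errors alone, at
#' per-base null rate \code{2/3 * errorRate}. P-values are Bonferroni
#' corrected across all assayed (depth > 0) sites; significant sites are
#' returned with MAF = minor count / depth. Zero-depth sites are skipped and
#' sites with minor count zero are never called. By the minor-allele
#' convention no reported MAF exceeds 0.5.
#'
#' This is the package's native low-frequency caller; alternative callers
#' (including wrappers around external tools) can be benchmarked through the
#' same [evaluateCalls()]/[benchmarkGrid()] interface.
#'
#' @param pileup a \linkS4class{Pileup}.
#' @param alpha familywise significance level, in (0, 1).
#' @param multipleTest \code{"bonferroni"} (default) or \code{"none"}.
#' @return a \code{data.frame} of raw calls: \code{position}, \code{ref},
#'   \code{alt} (minor allele), \code{maf}, \code{depth}, \code{p},
#'   \code{pAdj}, \code{sample}.
#' @examples
#' g <- generateMitogenome(2000, seed = 1)
#' ts <- generateTruthSet(g, freqs = 0.05, nPerFreq = 5, seed = 2)
#' p <- simulatePileup(g, ts, coverage = 5000, errorRate = 0,
#'                     exactMode = TRUE)
#' callSites(p)
#' @export
callSites <- function(pileup, alpha = 0.05,
                      multipleTest = c("bonferroni", "none")) {
  stopifnot(is(pileup, "Pileup"))
  multipleTest <- match.arg(multipleTest)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  counts <- pileup@counts
  depth <- rowSums(counts)
  assayed <- which(depth > 0)
  if (!base::length(assayed))
    return(.emptyCalls(pileup@sampleId))
  sub <- counts[assayed, , drop = FALSE]
  majIdx <- max.col(sub, ties.method = "first")
  minorSub <- sub
  minorSub[cbind(seq_len(nrow(sub)), majIdx)] <- -1L
  minIdx <- max.col(minorSub, ties.method = "first")
  minorCount <- sub[cbind(seq_len(nrow(sub)), minIdx)]
  d <- depth[assayed]
  p0 <- 2 / 3 * pileup@errorRate
  pval <- pbinom(minorCount - 1L, d, p0, lower.tail = FALSE)
  pAdj <- if (multipleTest == "bonferroni")
    pmin(1, pval * base::length(assayed)) else pval
  hit <- minorCount > 0L & pAdj < alpha
  data.frame(
    position = assayed[hit],
    ref = pileup@ref[assayed][hit],
    alt = DNA_BASES4[minIdx[hit]],
    maf = minorCount[hit] / d[hit],
    depth = as.integer(d[hit]),
    p = pval[hit],
    pAdj = pAdj[hit],
    sample = pileup@sampleId,
    stringsAsFactors = FALSE, row.names = NULL)
}

.emptyCalls <- function(sample = character(0)) {
  data.frame(position = integer(0), ref = character(0), alt = character(0),
             maf = numeric(0), depth = integer(0), p = numeric(0),
             pAdj = numeric(0), sample = character(0),
             stringsAsFactors = FALSE)
}

#' Filter raw heteroplasmy calls
#'
#' Applies the retention rule used for empirical samples: keep calls with
#' MAF strictly greater than \code{mafMin}, depth strictly greater than
#' \code{covMin}, and position outside the masked regions (primer-binding
#' sites and repeat arrays). Every call is tagged in a \code{filter} column
#' with \code{"PASS"} or the first failing filter (\code{"maf"},
#' \code{"coverage"}, \code{"mask"}); the tagging precedence makes the
#' composition order-independent.
#'
#' @param calls raw calls from [callSites()] (positions in original
#'   coordinates).
#' @param mafMin minimum MAF, exclusive. Default 0.01.
#' @param covMin minimum depth, exclusive. Default 1000.
#' @param mask an \linkS4class{IRanges} of masked intervals in original
#'   1-based coordinates (e.g. from [maskRegions()]), or \code{NULL}.
#' @return the call \code{data.frame} with a \code{filter} column; retained
#'   calls are those with \code{filter == "PASS"} (see [passedCalls()]).
#' @export
filterCalls <- function(calls, mafMin = 0.01, covMin = 1000, mask = NULL) {
  filter <- rep("PASS", nrow(calls))
  ## applied lowest precedence first so the tag reports the first failure
  ## in the order maf, coverage, mask
  if (!is.null(mask) && base::length(mask)) {
    inMask <- IRanges::overlapsAny(
      IRanges::IRanges(start = calls$position, width = 1L), mask)
    filter[inMask] <- "mask"
  }
  filter[calls$depth <= covMin] <- "coverage"
  filter[calls$maf <= mafMin] <- "maf"
  calls$filter <- filter
  calls
}

#' @rdname filterCalls
#' @export
passedCalls <- function(calls) {
  if (!"filter" %in% names(calls)) return(calls)
  calls[calls$filter == "PASS", , drop = FALSE]
}

#' Remap extended-reference calls onto the circle
#'
#' Positions of calls made against an \linkS4class{ExtendedReference} are
#' mapped back to original coordinates; a site detected twice (once in a pad
#' copy and once in the body) collapses to a single call, keeping the
#' higher-depth record.
#'
#' @param calls call \code{data.frame} with extended-reference positions.
#' @param extref the \linkS4class{ExtendedReference} the calls were made on.
#' @return the call table in original coordinates, one row per
#'   (sample, site), sorted by position.
#' @export
mergeCircularCalls <- function(calls, extref) {
  if (!nrow(calls)) return(calls)
  calls$position <- toOriginal(extref, calls$position)
  key <- paste(calls$sample, calls$position)
  calls <- calls[order(key, -calls$depth), , drop = FALSE]
  calls <- calls[!duplicated(paste(calls$sample, calls$position)), ,
                 drop = FALSE]
  calls <- calls[order(calls$sample, calls$position), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' One-step heteroplasmy detection on a pileup
#'
#' Convenience wrapper: [callSites()] then [filterCalls()] with the genome's
#' primer/repeat masks, returning only passing calls.
#'
#' @inheritParams callSites
#' @param genome the \linkS4class{Mitogenome} supplying the masks; omit to
#'   skip masking.
#' @param mafMin,covMin filter thresholds, see [filterCalls()].
#' @return a filtered call \code{data.frame}.
#' @export
callHeteroplasmies <- function(pileup, genome = NULL, alpha = 0.05,
                               mafMin = 0.01, covMin = 1000) {
  raw <- callSites(pileup, alpha = alpha)
  mask <- if (!is.null(genome)) maskRegions(genome) else NULL
  passedCalls(filterCalls(raw, mafMin = mafMin, covMin = covMin, mask = mask))
}
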
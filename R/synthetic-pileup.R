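#' Plant a truth set of low-frequency variants
#'
#' Draws \code{nPerFreq} positions uniformly without replacement for each
#' requested minor-allele frequency (each frequency forms one independent
#' set, so the same position can be drawn for two different frequencies).
#' Any position drawn in two or more sets is excluded entirely — from every
#' set it occurred in — because its truth frequency would be ambiguous. With
#' the default five-frequency, 100-variant design the surviving count is
#' therefore slightly below 500.
#'
#' @param genome a \linkS4class{Mitogenome} (or an
#'   \linkS4class{ExtendedReference}; positions are then on the extended
#'   sequence).
#' @param freqs minor-allele frequencies to plant, each in (0, 1).
#' @param nPerFreq variants per frequency.
#' @param seed integer seed or \code{NULL}.
#' @return a \code{data.frame} with columns \code{position}, \code{ref},
#'   \code{alt}, \code{trueFreq}, sorted by position.
#' @examples
#' g <- generateMitogenome(2000, seed = 1)
#' ts <- generateTruthSet(g, freqs = 0.05, nPerFreq = 10, seed = 2)
#' nrow(ts)
#' @export
generateTruthSet <- function(genome,
                             freqs = c(0.01, 0.04, 0.07, 0.10, 0.15),
                             nPerFreq = 100, seed = NULL) {
  .checkProb(freqs, "freqs", open = TRUE)
  L <- if (is(genome, "ExtendedReference")) length(genome) else length(genome)
  if (nPerFreq * base::length(freqs) > L)
    stop("cannot draw ", nPerFreq * base::length(freqs),
         " positions from a ", L, " bp genome")
  seqc <- strsplit(as.character(
    if (is(genome, "ExtendedReference")) genome@sequence
    else genomeSequence(genome)), "")[[1]]
  withSeed(seed, {
    sets <- lapply(freqs, function(f) sample.int(L, nPerFreq))
    allPos <- unlist(sets)
    dup <- unique(allPos[duplicated(allPos)])
    pos <- integer(0); fq <- numeric(0)
    for (i in seq_along(sets)) {
      keep <- setdiff(sets[[i]], dup)
      pos <- c(pos, keep)
      fq <- c(fq, rep(freqs[i], base::length(keep)))
    }
    ref <- seqc[pos]
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES4, r), 1L), "")
    out <- data.frame(position = pos, ref = ref, alt = alt, trueFreq = fq,
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$position), , drop = FALSE]
  })
}

#' Simulate a per-site pileup with planted variants
#'
#' Count-level sequencing model: at every position the depth is
#' Poisson-distributed around the nominal coverage (or exactly equal to it in
#' \code{exactMode}); at truth positions the minor-allele read count is
#' binomial in the depth with the planted frequency (in \code{exactMode},
#' exactly \code{round(f * depth)}); remaining reference-origin reads are then
#' corrupted independently with probability \code{errorRate}, the erroneous
#' base uniform over the three non-reference bases.
#'
#' @param genome a \linkS4class{Mitogenome} or \linkS4class{ExtendedReference}
#'   supplying the reference bases.
#' @param truthSet a truth table from [generateTruthSet()], or \code{NULL} for
#'   a variant-free sample.
#' @param coverage nominal coverage, >= 1.
#' @param errorRate per-base substitution probability, in [0, 0.25).
#' @param seed integer seed or \code{NULL}.
#' @param exactMode if \code{TRUE}, depth is exactly \code{coverage} and alt
#'   counts exactly \code{round(f * coverage)}; used for noiseless checks.
#' @param sampleName sample identifier recorded on the pileup.
#' @return a \linkS4class{Pileup}.
#' @examples
#' g <- generateMitogenome(2000, seed = 1)
#' ts <- data.frame(position = 100, ref = refBase(g, 100),
#'                  alt = setdiff(c("A","C","G","T"), refBase(g, 100))[1],
#'                  trueFreq = 0.05)
#' p <- simulatePileup(g, ts, coverage = 2000, errorRate = 0,
#'                     exactMode = TRUE)
#' pileupCounts(p)[100, ]
#' @export
simulatePileup <- function(genome, truthSet = NULL, coverage,
                           errorRate = 0.001, seed = NULL, exactMode = FALSE,
                           sampleName = "sim") {
  if (coverage < 1) stop("coverage must be at least 1")
  if (errorRate < 0 || errorRate >= 0.25)
    stop("errorRate must lie in [0, 0.25)")
  seqc <- strsplit(as.character(
    if (is(genome, "ExtendedReference")) genome@sequence
    else genomeSequence(genome)), "")[[1]]
  L <- base::length(seqc)
  withSeed(seed, {
    depth <- if (exactMode) rep(as.integer(coverage), L) else rpois(L, coverage)
    counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES4))
    refIdx <- match(seqc, DNA_BASES4)
    nAlt <- integer(L)
    if (!is.null(truthSet) && nrow(truthSet)) {
      tp <- truthSet$position
      nAlt[tp] <- if (exactMode) as.integer(round(truthSet$trueFreq * depth[tp]))
                  else rbinom(nrow(truthSet), depth[tp], truthSet$trueFreq)
      counts[cbind(tp, match(truthSet$alt, DNA_BASES4))] <- nAlt[tp]
    }
    nRef <- depth - nAlt
    if (errorRate > 0) {
      nErr <- rbinom(L, nRef, errorRate)
      nRef <- nRef - nErr
      hot <- which(nErr > 0L)
      for (i in hot) {
        others <- setdiff(1:4, refIdx[i])
        spread <- as.integer(rmultinom(1, nErr[i], rep(1 / 3, 3)))
        counts[i, others] <- counts[i, others] + spread
      }
    }
    counts[cbind(seq_len(L), refIdx)] <-
      counts[cbind(seq_len(L), refIdx)] + as.integer(nRef)
    new("Pileup", counts = counts, ref = seqc,
        sampleId = sampleName, coverage = as.numeric(coverage),
        errorRate = errorRate)
  })
}
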
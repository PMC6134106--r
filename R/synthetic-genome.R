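#' Default annotation layout for a synthetic mitogenome
#'
#' The layout emulates a vertebrate mitogenome: 13 protein-coding genes,
#' 22 tRNAs, 2 rRNAs and a non-coding control region, plus primer-binding
#' sites and control-region repeat arrays which are masks and may overlap the
#' genes. Fractions are of total genome length and must sum to at most 1;
#' the remainder becomes intergenic spacer.
#'
#' @param nProtein,proteinFraction number of protein genes and the fraction of
#'   the genome they jointly cover.
#' @param nTRNA,trnaFraction same for tRNA genes.
#' @param nRRNA,rrnaFraction same for rRNA genes.
#' @param controlFraction fraction covered by the non-coding control region.
#' @param nPrimer,primerLength primer-binding masks (count, bp each).
#' @param nRepeat,repeatLength repeat-array masks placed inside the control
#'   region (count, bp each).
#' @return a list usable as \code{annotationSpec} in [generateMitogenome()].
#' @export
annotationSpec <- function(nProtein = 13, proteinFraction = 0.62,
                           nTRNA = 22, trnaFraction = 0.09,
                           nRRNA = 2, rrnaFraction = 0.15,
                           controlFraction = 0.07,
                           nPrimer = 4, primerLength = 25,
                           nRepeat = 2, repeatLength = 60) {
  fr <- c(proteinFraction, trnaFraction, rrnaFraction, controlFraction)
  if (any(fr < 0) || sum(fr) > 1)
    stop("annotation fractions must be non-negative and sum to at most 1")
  list(nProtein = nProtein, proteinFraction = proteinFraction,
       nTRNA = nTRNA, trnaFraction = trnaFraction,
       nRRNA = nRRNA, rrnaFraction = rrnaFraction,
       controlFraction = controlFraction,
       nPrimer = nPrimer, primerLength = primerLength,
       nRepeat = nRepeat, repeatLength = repeatLength)
}

#' Generate a synthetic circular mitogenome
#'
#' Draws a uniform random DNA sequence of the requested length and lays
#' non-overlapping gene features (protein, tRNA, rRNA, control region) around
#' the circle according to \code{annotationSpec}, interleaving tRNAs between
#' the larger genes as real mitogenomes do. Primer and repeat masks are then
#' placed on top (they may overlap genes). Protein genes start on a codon
#' boundary (frame 0) and have length divisible by 3; one protein gene is
#' placed on the minus strand, mirroring the single light-strand protein gene
#' of vertebrate mitogenomes.
#'
#' The default length of 16,211 bp is a realistic bat mitogenome scale: with
#' the default 500 bp circularity pad it yields a 17,211-site extended
#' reference.
#'
#' @param length genome length in bp; must be at least \code{2 * pad}.
#' @param seed integer seed for reproducibility (or \code{NULL}).
#' @param spec annotation layout, see [annotationSpec()].
#' @param pad circularity pad the genome is expected to support (only used to
#'   validate \code{length}); default 500 bp.
#' @return a \linkS4class{Mitogenome}.
#' @examples
#' g <- generateMitogenome(16211, seed = 1)
#' table(genomeFeatures(g)$type)
#' @export
generateMitogenome <- function(length = 16211, seed = NULL,
                               spec = annotationSpec(), pad = 500) {
  length <- as.integer(length)
  if (length < 2L * pad)
    stop("genome length must be at least twice the circularity pad (",
         2L * pad, " bp)")
  withSeed(seed, {
    L <- length
    protLen <- (L * spec$proteinFraction / max(spec$nProtein, 1)) %/% 3 * 3
    trnaLen <- (L * spec$trnaFraction) %/% max(spec$nTRNA, 1)
    rrnaLen <- (L * spec$rrnaFraction) %/% max(spec$nRRNA, 1)
    ctrlLen <- floor(L * spec$controlFraction)

    types <- c(rep("rRNA", spec$nRRNA), rep("protein", spec$nProtein))
    lens  <- c(rep(rrnaLen, spec$nRRNA), rep(protLen, spec$nProtein))
    ## interleave the tRNAs between the big genes
    if (spec$nTRNA > 0) {
      slots <- rep(seq_along(types), length.out = spec$nTRNA)
      ord <- order(c(seq_along(types), slots + 0.5))
      types <- c(types, rep("tRNA", spec$nTRNA))[ord]
      lens  <- c(lens, rep(trnaLen, spec$nTRNA))[ord]
    }
    if (ctrlLen > 0) {
      types <- c("noncoding", types)
      lens  <- c(ctrlLen, lens)
    }
    used <- sum(lens)
    if (any(lens < 1) || used > L)
      stop("genome length too small for the requested features (need ",
           used, " bp)")
    n <- base::length(types)
    gapTotal <- L - used
    gaps <- rep(gapTotal %/% n, n)
    gaps[n] <- gaps[n] + gapTotal %% n

    start <- integer(n); end <- integer(n); cur <- 1L
    for (i in seq_len(n)) {
      start[i] <- cur
      end[i] <- cur + as.integer(lens[i]) - 1L
      cur <- end[i] + 1L + gaps[i]
    }
    strand <- rep("+", n)
    ## one light-strand protein gene
    mi <- which(types == "protein")
    if (base::length(mi)) strand[mi[base::length(mi)]] <- "-"

    counts <- stats::setNames(rep(0L, 4), c("protein", "tRNA", "rRNA",
                                            "noncoding"))
    name <- character(n)
    for (i in seq_len(n)) {
      counts[types[i]] <- counts[types[i]] + 1L
      name[i] <- switch(types[i],
        protein  = paste0("PCG", counts[["protein"]]),
        tRNA     = paste0("trn", LETTERS[(counts[["tRNA"]] - 1L) %% 26 + 1L],
                          (counts[["tRNA"]] - 1L) %/% 26 + 1L),
        rRNA     = paste0("rrn", c("S", "L")[min(counts[["rRNA"]], 2L)]),
        noncoding = "CR")
    }
    frame <- ifelse(types == "protein", 0L, NA_integer_)

    ## masks: primers evenly spaced; repeats inside the control region
    mStart <- integer(0); mEnd <- integer(0); mType <- character(0)
    mName <- character(0)
    if (spec$nPrimer > 0) {
      at <- floor(seq(1, L - spec$primerLength, length.out = spec$nPrimer))
      mStart <- c(mStart, at); mEnd <- c(mEnd, at + spec$primerLength - 1L)
      mType <- c(mType, rep("primer", spec$nPrimer))
      mName <- c(mName, paste0("primer", seq_len(spec$nPrimer)))
    }
    if (spec$nRepeat > 0 && ctrlLen > 0) {
      cs <- start[types == "noncoding"][1]
      at <- cs + floor(seq(0, max(ctrlLen - spec$repeatLength, 0),
                           length.out = spec$nRepeat))
      mStart <- c(mStart, at); mEnd <- c(mEnd, pmin(at + spec$repeatLength - 1L, L))
      mType <- c(mType, rep("repeat", spec$nRepeat))
      mName <- c(mName, paste0("repeat", seq_len(spec$nRepeat)))
    }

    gr <- GenomicRanges::GRanges(
      seqnames = "mito",
      ranges = IRanges::IRanges(start = c(start, mStart), end = c(end, mEnd)),
      strand = c(strand, rep("*", base::length(mStart))))
    gr$name <- c(name, mName)
    gr$type <- c(types, mType)
    gr$frame <- c(frame, rep(NA_integer_, base::length(mStart)))

    seq <- Biostrings::DNAString(
      paste(sample(DNA_BASES4, L, replace = TRUE), collapse = ""))
    new("Mitogenome", sequence = seq, features = gr)
  })
}

#' Regions to mask when filtering heteroplasmy calls
#'
#' Returns the primer-binding and repeat-array intervals of a genome's
#' annotation as an \linkS4class{IRanges} in original 1-based coordinates.
#'
#' @param genome a \linkS4class{Mitogenome}.
#' @param types feature types treated as masks.
#' @return an \linkS4class{IRanges} of masked intervals.
#' @export
maskRegions <- function(genome, types = c("primer", "repeat")) {
  ft <- genomeFeatures(genome)
  ft <- ft[ft$type %in% types]
  IRanges::ranges(ft)
}
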
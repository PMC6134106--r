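MUTATION_CLASSES <- c("GC_AT_transition", "GC_TA_transversion",
                      "AT_TA_transversion", "GC_CG_transversion")

#' Classify a single-base substitution into the four strand-symmetric classes
#'
#' The 12 ordered substitutions partition into one transition class
#' (G:C <-> A:T) and three transversion classes (G:C <-> T:A,
#' A:T <-> T:A, G:C <-> C:G). G:C -> T:A changes are the signature of
#' 8-oxo-guanine damage and are reported as the oxidative class by
#' [spectrumSummary()].
#'
#' @param ref,alt reference and alternate base (vectorised); must differ and
#'   be DNA.
#' @return character vector of class labels.
#' @examples
#' classifySubstitution("G", "A")   # transition
#' classifySubstitution("C", "A")   # oxidative transversion
#' @export
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% DNA_BASES4) || !all(alt %in% DNA_BASES4))
    stop("non-DNA symbol in substitution")
  if (any(ref == alt)) stop("ref and alt must differ")
  key <- paste0(ref, alt)
  map <- c(GA = 1L, AG = 1L, CT = 1L, TC = 1L,
           GT = 2L, TG = 2L, CA = 2L, AC = 2L,
           AT = 3L, TA = 3L,
           GC = 4L, CG = 4L)
  MUTATION_CLASSES[map[key]]
}

#' Mutation-spectrum summary of a call set
#'
#' Tabulates the four substitution classes, the transition/transversion
#' ratio (transitions over all transversions; \code{NA} when there are no
#' transversions), and the per-sample burden of oxidative G:C -> T:A
#' transversions, which in this kind of data tends to concentrate in few
#' individuals rather than spreading evenly.
#'
#' @param calls call table with \code{ref}, \code{alt} and (optionally)
#'   \code{sample} columns.
#' @return list: \code{counts} and \code{proportions} (named by class),
#'   \code{tsTv}, and \code{oxidativeBurden} (per-sample count of oxidative
#'   calls, if a sample column is present).
#' @export
spectrumSummary <- function(calls) {
  if (is.null(calls) || !nrow(calls)) stop("empty call set")
  cls <- factor(classifySubstitution(calls$ref, calls$alt),
                levels = MUTATION_CLASSES)
  counts <- table(cls)
  ts <- counts[["GC_AT_transition"]]
  tv <- sum(counts) - ts
  burden <- NULL
  if ("sample" %in% names(calls)) {
    ox <- calls[cls == "GC_TA_transversion", , drop = FALSE]
    burden <- table(factor(ox$sample, levels = unique(calls$sample)))
  }
  list(counts = counts,
       proportions = counts / sum(counts),
       tsTv = if (tv == 0) NA_real_ else ts / tv,
       oxidativeBurden = burden)
}

## Grantham (physicochemical) distance between amino acids, computed from
## the composition/polarity/volume formula with the original constants.
.GRANTHAM_PROPS <- data.frame(
  aa = c("S","R","L","P","T","A","V","G","I","F",
         "Y","C","H","Q","N","K","D","E","M","W"),
  c = c(1.42,0.65,0,0.39,0.71,0,0,0.74,0,0,
        0.20,2.75,0.58,0.89,1.33,0.33,1.38,0.92,0,0.13),
  p = c(9.2,10.5,4.9,8.0,8.6,8.1,5.9,9.0,5.2,5.2,
        6.2,5.5,10.4,10.5,11.6,11.3,13.0,12.3,5.7,5.4),
  v = c(32,124,111,32.5,61,31,84,3,111,132,
        136,55,96,85,56,119,54,83,105,170),
  stringsAsFactors = FALSE)

#' Grantham distance between two amino acids
#'
#' @param aa1,aa2 single-letter amino acid codes (vectorised).
#' @return numeric distance(s); 0 for identical residues.
#' @export
granthamDistance <- function(aa1, aa2) {
  pr <- .GRANTHAM_PROPS
  i <- match(aa1, pr$aa); j <- match(aa2, pr$aa)
  if (any(is.na(i)) || any(is.na(j)))
    stop("unknown amino acid code")
  50.723 * sqrt(1.833 * (pr$c[i] - pr$c[j])^2 +
                0.1018 * (pr$p[i] - pr$p[j])^2 +
                0.000399 * (pr$v[i] - pr$v[j])^2)
}

#' Grantham-distance deleteriousness scorer
#'
#' Returns a scorer function for [annotateEffect()] labelling a missense
#' change \code{"Deleterious"} when its Grantham distance exceeds
#' \code{threshold} (default 100, the conventional boundary of "radical"
#' changes) and \code{"Neutral"} otherwise. This is a coarse physicochemical
#' stand-in for alignment-based scorers such as PROVEAN and is not
#' equivalent to them; treat the labels as a screening annotation only.
#'
#' @param threshold Grantham distance above which a change is labelled
#'   deleterious.
#' @return a function \code{(refAA, altAA) -> character label}.
#' @export
granthamScorer <- function(threshold = 100) {
  function(refAA, altAA)
    ifelse(granthamDistance(refAA, altAA) > threshold,
           "Deleterious", "Neutral")
}

#' Annotate the coding effect of heteroplasmy calls
#'
#' Locates the feature(s) containing each call. For protein features the
#' codon and codon position are computed from the feature's strand and
#' reading-frame offset, the reference and alternate codons are translated
#' under the vertebrate mitochondrial genetic code, and the change is
#' labelled synonymous, nonsynonymous or nonsense (alternate codon is a
#' stop). tRNA/rRNA features and unannotated or control-region positions are
#' noncoding. A position inside two overlapping protein genes yields one
#' record per gene. Primer and repeat masks are ignored here (they are
#' filtering concerns, not genes).
#'
#' @param calls call table with \code{position}, \code{ref}, \code{alt}.
#' @param genome the annotated \linkS4class{Mitogenome}.
#' @param scorer optional deleteriousness scorer, e.g. [granthamScorer()];
#'   applied to nonsynonymous, non-nonsense changes only. \code{NULL} leaves
#'   the label \code{NA}.
#' @return data.frame, one row per (call, containing feature): the call
#'   columns plus \code{region}, \code{gene}, \code{codonPos},
#'   \code{refCodon}, \code{altCodon}, \code{refAA}, \code{altAA},
#'   \code{effect}, \code{deleterious}.
#' @export
annotateEffect <- function(calls, genome, scorer = NULL) {
  stopifnot(is(genome, "Mitogenome"))
  L <- length(genome)
  if (any(calls$position < 1L | calls$position > L))
    stop("call position outside the genome")
  seqc <- strsplit(as.character(genomeSequence(genome)), "")[[1]]
  code <- Biostrings::getGeneticCode("SGC1")   # vertebrate mitochondrial
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ft <- genomeFeatures(genome)
  genes <- ft[ft$type %in% c("protein", "tRNA", "rRNA", "noncoding")]

  out <- list()
  for (i in seq_len(nrow(calls))) {
    pos <- calls$position[i]
    hit <- genes[GenomicRanges::start(genes) <= pos &
                 GenomicRanges::end(genes) >= pos]
    recs <- if (!base::length(hit)) list(list(region = "noncoding",
                                              gene = NA_character_))
      else lapply(seq_along(hit), function(j) {
        list(region = hit$type[j], gene = hit$name[j], j = j)
      })
    for (r in recs) {
      row <- calls[i, , drop = FALSE]
      row$region <- if (r$region == "protein") "protein" else
        if (r$region %in% c("tRNA", "rRNA")) r$region else "noncoding"
      row$gene <- r$gene
      row$codonPos <- NA_integer_
      row$refCodon <- row$altCodon <- NA_character_
      row$refAA <- row$altAA <- NA_character_
      row$effect <- "noncoding"
      row$deleterious <- NA_character_
      if (r$region == "protein") {
        f <- hit[r$j]
        fr <- f$frame
        st <- GenomicRanges::start(f); en <- GenomicRanges::end(f)
        minus <- as.character(GenomicRanges::strand(f)) == "-"
        if (!minus) {
          off <- pos - st - fr
          if (off >= 0 && off < (en - st - fr + 1) %/% 3 * 3) {
            cstart <- st + fr + (off %/% 3) * 3
            cpos <- off %% 3 + 1L
            refCodon <- seqc[cstart:(cstart + 2L)]
            altCodon <- refCodon; altCodon[cpos] <- calls$alt[i]
            row <- .fillEffect(row, refCodon, altCodon, cpos, code, scorer)
          }
        } else {
          off <- en - fr - pos
          if (off >= 0 && off < (en - fr - st + 1) %/% 3 * 3) {
            c1 <- en - fr - (off %/% 3) * 3   # genomic pos of codon base 1
            cpos <- off %% 3 + 1L
            refCodon <- comp[seqc[c(c1, c1 - 1L, c1 - 2L)]]
            altCodon <- refCodon; altCodon[cpos] <- comp[[calls$alt[i]]]
            row <- .fillEffect(row, refCodon, altCodon, cpos, code, scorer)
          }
        }
      }
      out[[base::length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.fillEffect <- function(row, refCodon, altCodon, cpos, code, scorer) {
  refC <- paste(refCodon, collapse = "")
  altC <- paste(altCodon, collapse = "")
  refAA <- code[[refC]]; altAA <- code[[altC]]
  row$codonPos <- as.integer(cpos)
  row$refCodon <- refC; row$altCodon <- altC
  row$refAA <- refAA; row$altAA <- altAA
  row$effect <- if (refAA == altAA) "synonymous"
    else if (altAA == "*") "nonsense"
    else "nonsynonymous"
  if (row$effect == "nonsynonymous" && !is.null(scorer) &&
      refAA != "*" && altAA != "*")
    row$deleterious <- scorer(refAA, altAA)
  row
}

#' Compare two MAF spectra
#'
#' Two-sided nonparametric comparison of minor-allele-frequency
#' distributions between two bins of heteroplasmies (e.g. synonymous vs
#' nonsynonymous), by Kolmogorov-Smirnov or Mann-Whitney U test. Exact
#' p-values are used where the implementation provides them (small samples
#' without ties), asymptotic otherwise.
#'
#' @param a,b numeric vectors of MAFs, both non-empty.
#' @param test \code{"ks"} or \code{"mwu"}.
#' @return list: \code{statistic}, \code{p.value}, \code{test}.
#' @export
spectrumTest <- function(a, b, test = c("ks", "mwu")) {
  test <- match.arg(test)
  if (!base::length(a) || !base::length(b)) stop("both groups must be non-empty")
  if (test == "ks") {
    if (base::length(a) < 2 || base::length(b) < 2)
      stop("KS test needs at least 2 values per group")
    r <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  } else {
    r <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  }
  list(statistic = unname(r$statistic), p.value = r$p.value, test = test)
}

#' Chi-square enrichment of heteroplasmic sites in a genomic bin
#'
#' Builds the 2x2 table {heteroplasmic, homoplasmic} x {in bin, outside bin}
#' over the assayable genome and computes Pearson's chi-square without
#' continuity correction (Yates correction available via \code{correct}).
#' The \code{enriched} flag requires both exceeding the supplied critical
#' value (3.841 for p < 0.05, 10.828 for p < 0.001 at one degree of freedom)
#' and an in-bin heteroplasmy density above the genome-wide density.
#'
#' @param hetInBin number of unique heteroplasmic sites inside the bin.
#' @param binLength bin length in bp.
#' @param totalHet total unique heteroplasmic sites in the assayable genome.
#' @param assayableLength assayable genome length in bp (genome minus masked
#'   regions).
#' @param critical chi-square critical value for flagging.
#' @param correct apply Yates continuity correction.
#' @return list: \code{statistic}, \code{p.value}, \code{enriched},
#'   \code{table}.
#' @export
enrichmentTest <- function(hetInBin, binLength, totalHet, assayableLength,
                           critical = 3.841, correct = FALSE) {
  if (binLength <= 0) stop("zero-length bin")
  if (binLength >= assayableLength)
    stop("bin must be smaller than the assayable genome")
  if (hetInBin > binLength || totalHet > assayableLength ||
      hetInBin > totalHet)
    stop("inconsistent counts")
  tab <- matrix(c(hetInBin, totalHet - hetInBin,
                  binLength - hetInBin,
                  (assayableLength - binLength) - (totalHet - hetInBin)),
                nrow = 2,
                dimnames = list(c("inBin", "outBin"), c("het", "nonHet")))
  r <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  stat <- unname(r$statistic)
  dens <- hetInBin / binLength > totalHet / assayableLength
  list(statistic = stat, p.value = unname(r$p.value),
       enriched = stat > critical && dens, table = tab)
}

#' Partition heteroplasmic sites into private and shared
#'
#' A site is private when exactly one individual carries it, shared when two
#' or more do. Expects one record per individual per site (apply
#' [mostRecentSamples()] upstream when individuals have recapture samples).
#'
#' @param calls call table with \code{individual}, \code{position} and
#'   \code{maf} columns.
#' @return list: \code{sites} (data.frame \code{position},
#'   \code{nIndividuals}, \code{label}), \code{privateFraction}, and the two
#'   MAF spectra \code{mafPrivate}, \code{mafShared}.
#' @export
privateSharedPartition <- function(calls) {
  byPos <- tapply(calls$individual, calls$position,
                  function(x) base::length(unique(x)))
  sites <- data.frame(position = as.integer(names(byPos)),
                      nIndividuals = as.integer(byPos),
                      label = ifelse(byPos == 1L, "private", "shared"),
                      stringsAsFactors = FALSE, row.names = NULL)
  lab <- sites$label[match(calls$position, sites$position)]
  list(sites = sites,
       privateFraction = mean(sites$label == "private"),
       mafPrivate = calls$maf[lab == "private"],
       mafShared = calls$maf[lab == "shared"])
}

#' Reduce recaptured individuals to their most recent sample
#'
#' @param samples sample table with \code{individual} and \code{year}.
#' @return the sample table restricted to each individual's latest year.
#' @export
mostRecentSamples <- function(samples) {
  ord <- order(samples$individual, -samples$year)
  s <- samples[ord, , drop = FALSE]
  s <- s[!duplicated(s$individual), , drop = FALSE]
  s[order(s$individual), , drop = FALSE]
}
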
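#' Default parameters for the synthetic heteroplasmy population
#'
#' The defaults emulate a wild, PIT-tagged bat colony study: age cohorts 0-5
#' plus an open-ended "6+" cohort (167 unique individuals), per-individual
#' heteroplasmy counts that are negative-binomially distributed with a weak
#' log-linear age trend, a four-class mutation spectrum dominated by
#' transitions (60.6%) with a substantial oxidative G:C>T:A component (31.9%)
#' concentrated in occasional "spike" individuals, a minor-allele-frequency
#' spectrum with 77.6% of its mass below 5%, sequencing batches, and
#' multi-year recaptures (3 individuals sampled 4 times, 8 sampled 3 times,
#' 10 sampled twice) whose sites persist year to year with a fixed
#' probability.
#'
#' @param cohortSizes named integer vector: individuals per age cohort; names
#'   are cohort labels (\code{"6+"} allowed).
#' @param beta0,beta1 intercept and age slope of the log-linear negative
#'   binomial count model, log(mu) = beta0 + beta1 * age.
#' @param theta negative binomial dispersion (NB2 variance mu + mu^2/theta).
#' @param classProbs target marginal probabilities of the four mutation
#'   classes, in the order G:C>A:T transition, G:C>T:A transversion,
#'   A:T>T:A transversion, G:C>C:G transversion; must sum to 1. Spike calls
#'   are all oxidative, so the generator rescales its baseline class draw by
#'   the expected spike fraction to keep the marginal spectrum on target.
#' @param mafRate rate of the (shifted, truncated) exponential MAF
#'   distribution; the default 37.43 puts 77.6% of the mass below 5% MAF.
#' @param mafMin,mafMax support of the MAF distribution (minor-allele
#'   convention caps at 0.5).
#' @param nBatches number of sequencing batches, assigned at random.
#' @param recaptureDesign named integer vector: names are times sampled,
#'   values are numbers of individuals so sampled.
#' @param persistence probability that a site heteroplasmic in one year is
#'   observed again the following year in the same individual.
#' @param spikeProb per-sample probability of an oxidative-stress spike.
#' @param spikeExtra mean of the Poisson excess above the 4-site minimum that
#'   defines a spike.
#' @param genomeLength genome length the site positions are drawn over.
#' @param years consecutive sampling years available for recaptures.
#' @param meanDepth mean per-call sequencing depth recorded on each call.
#' @return a parameter list for [simulatePopulation()].
#' @export
populationParams <- function(
    cohortSizes = c("0" = 74, "1" = 22, "2" = 19, "3" = 21, "4" = 20,
                    "5" = 3, "6+" = 8),
    beta0 = -0.0843, beta1 = 0.0699, theta = 2,
    classProbs = c(GC_AT_transition = 0.606, GC_TA_transversion = 0.319,
                   AT_TA_transversion = 0.075, GC_CG_transversion = 0),
    mafRate = 37.43, mafMin = 0.01, mafMax = 0.49,
    nBatches = 4,
    recaptureDesign = c("4" = 3, "3" = 8, "2" = 10),
    persistence = 0.15,
    spikeProb = 0.03, spikeExtra = 2,
    genomeLength = 16211,
    years = 2013:2016,
    meanDepth = 3837) {
  .checkProb(classProbs, "classProbs")
  if (abs(sum(classProbs) - 1) > 1e-8) stop("classProbs must sum to 1")
  .checkProb(persistence, "persistence")
  .checkProb(spikeProb, "spikeProb")
  if (mafMin <= 0 || mafMax > 0.5 || mafMin >= mafMax)
    stop("MAF support must satisfy 0 < mafMin < mafMax <= 0.5")
  as.list(environment())
}

## ordered substitutions belonging to each strand-symmetric class
.CLASS_SUBS <- list(
  GC_AT_transition  = list(c("G", "A"), c("C", "T"), c("A", "G"), c("T", "C")),
  GC_TA_transversion = list(c("G", "T"), c("C", "A"), c("T", "G"), c("A", "C")),
  AT_TA_transversion = list(c("A", "T"), c("T", "A")),
  GC_CG_transversion = list(c("G", "C"), c("C", "G"))
)

.drawMAF <- function(n, p) {
  ## shifted exponential truncated to [mafMin, mafMax]
  u <- runif(n)
  span <- 1 - exp(-p$mafRate * (p$mafMax - p$mafMin))
  p$mafMin - log(1 - u * span) / p$mafRate
}

.drawCalls <- function(n, p) {
  if (n == 0L)
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), maf = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  pr <- if (!is.null(p$baseProbs)) p$baseProbs else p$classProbs
  cls <- sample(names(p$classProbs), n, replace = TRUE, prob = pr)
  sub <- t(vapply(cls, function(cl) {
    s <- .CLASS_SUBS[[cl]]
    unlist(s[[sample.int(base::length(s), 1L)]])
  }, character(2)))
  data.frame(position = sample.int(p$genomeLength, n),
             ref = sub[, 1], alt = sub[, 2],
             maf = .drawMAF(n, p), class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a population-scale heteroplasmy call table
#'
#' Generates a sample table and a heteroplasmy call table with the joint
#' structure the downstream analyses assume: per-sample counts are negative
#' binomial in age, mutation classes follow the configured four-class
#' spectrum, MAFs follow a low-frequency-skewed distribution, occasional
#' samples carry an oxidative "spike" (4+ extra G:C>T:A calls), and
#' recaptured individuals are sampled in consecutive years with each
#' prior-year site carried over with probability \code{persistence} (at the
#' same MAF). Sites can also reappear through spikes; new non-spike sites
#' arise only at an individual's first capture, so with persistence 1 and
#' spike probability 0 recapture years replicate the first year's call set
#' exactly.
#'
#' @param params parameter list from [populationParams()].
#' @param seed integer seed or \code{NULL}.
#' @return a list with elements \code{samples} (data.frame: \code{sample},
#'   \code{individual}, \code{ageLabel}, \code{age}, \code{batch},
#'   \code{year}) and \code{calls} (data.frame: \code{sample},
#'   \code{individual}, \code{position}, \code{ref}, \code{alt}, \code{maf},
#'   \code{depth}, \code{class}); every call's sample appears in the sample
#'   table.
#' @examples
#' pop <- simulatePopulation(seed = 1)
#' head(pop$samples)
#' nrow(pop$calls)
#' @export
simulatePopulation <- function(params = populationParams(), seed = NULL) {
  p <- params
  withSeed(seed, {
    labels <- rep(names(p$cohortSizes), p$cohortSizes)
    nInd <- base::length(labels)
    labels <- sample(labels)            # decouple ID order from age
    ind <- sprintf("IND%04d", seq_len(nInd))
    age <- ageToNumeric(labels)

    ## recapture design: first individuals get multi-year histories
    timesSampled <- rep(1L, nInd)
    k <- as.integer(names(p$recaptureDesign))
    idx <- 1L
    for (i in seq_along(k)) {
      cnt <- p$recaptureDesign[i]
      if (cnt > 0) timesSampled[idx:(idx + cnt - 1L)] <- k[i]
      idx <- idx + cnt
    }
    lastYear <- max(p$years)

    ## classProbs is the target *marginal* spectrum. Spikes contribute pure
    ## oxidative calls, so the baseline class draw is rescaled by the
    ## expected spike fraction to keep the marginal on target.
    muBar <- sum(p$cohortSizes *
                 exp(p$beta0 + p$beta1 * ageToNumeric(names(p$cohortSizes)))) /
      nInd
    geo <- vapply(timesSampled, function(T)
      if (p$persistence == 1) as.numeric(T)
      else (1 - p$persistence^T) / (1 - p$persistence), 1)
    expBase <- muBar * sum(geo)
    expSpike <- sum(timesSampled) * p$spikeProb * (4 + p$spikeExtra)
    sfrac <- expSpike / (expSpike + expBase)
    base <- p$classProbs / (1 - sfrac)
    base[["GC_TA_transversion"]] <-
      (p$classProbs[["GC_TA_transversion"]] - sfrac) / (1 - sfrac)
    if (base[["GC_TA_transversion"]] < 0)
      stop("spikeProb too high for the configured oxidative class fraction")
    p$baseProbs <- base

    samples <- list(); calls <- list(); sid <- 0L
    for (i in seq_len(nInd)) {
      yrs <- seq(lastYear - timesSampled[i] + 1L, lastYear)
      batch <- sample.int(p$nBatches, 1L)
      prior <- NULL
      for (y in yrs) {
        sid <- sid + 1L
        sname <- sprintf("S%04d", sid)
        if (is.null(prior)) {
          n <- rnbinom(1L, size = p$theta,
                       mu = exp(p$beta0 + p$beta1 * age[i]))
          cur <- .drawCalls(n, p)
        } else {
          keep <- runif(nrow(prior)) < p$persistence
          cur <- prior[keep, , drop = FALSE]
        }
        if (runif(1) < p$spikeProb) {
          nSpike <- 4L + rpois(1L, p$spikeExtra)
          ox <- .drawCalls(nSpike, p)
          oxSub <- .CLASS_SUBS$GC_TA_transversion
          pick <- vapply(seq_len(nSpike), function(j)
            sample.int(base::length(oxSub), 1L), 1L)
          ox$ref <- vapply(pick, function(j) oxSub[[j]][1], "")
          ox$alt <- vapply(pick, function(j) oxSub[[j]][2], "")
          ox$class <- "GC_TA_transversion"
          cur <- rbind(cur, ox[!ox$position %in% cur$position, , drop = FALSE])
        }
        samples[[sid]] <- data.frame(
          sample = sname, individual = ind[i], ageLabel = labels[i],
          age = age[i], batch = paste0("B", batch), year = y,
          stringsAsFactors = FALSE)
        if (nrow(cur)) {
          cc <- cur
          cc$sample <- sname
          cc$individual <- ind[i]
          cc$depth <- rpois(nrow(cc), p$meanDepth)
          calls[[base::length(calls) + 1L]] <- cc
        }
        prior <- cur
      }
    }
    samples <- do.call(rbind, samples)
    calls <- if (base::length(calls)) do.call(rbind, calls) else
      data.frame(sample = character(0), individual = character(0),
                 position = integer(0), ref = character(0),
                 alt = character(0), maf = numeric(0), depth = integer(0),
                 class = character(0), stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    cols <- c("sample", "individual", "position", "ref", "alt", "maf",
              "depth", "class")
    calls <- calls[, cols[cols %in% names(calls)], drop = FALSE]
    list(samples = samples, calls = calls)
  })
}

#' Per-sample heteroplasmy counts from a population table
#'
#' Counts calls per sample (zero for samples with no calls), returning the
#' sample table with a \code{count} column appended — the response used by
#' the age-association models.
#'
#' @param pop a list as returned by [simulatePopulation()], or any pair of
#'   sample/call tables with matching \code{sample} columns.
#' @return the sample data.frame with an integer \code{count} column.
#' @export
heteroplasmyCounts <- function(pop) {
  s <- pop$samples
  tab <- table(factor(pop$calls$sample, levels = s$sample))
  s$count <- as.integer(tab[s$sample])
  s
}
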
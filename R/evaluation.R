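#' Score a call set against a planted truth set
#'
#' Computes the three benchmarking metrics for low-frequency variant
#' callers:
#' \itemize{
#'   \item power — proportion of true sites called;
#'   \item accuracy — proportion of called true sites whose reported
#'     frequency is within +/- 0.01 (absolute, inclusive) of the truth;
#'   \item false positive rate — called non-true sites over assayable
#'     non-true sites.
#' }
#' The accuracy denominator conditions on detection by default, so accuracy
#' and power measure distinct failure modes; set
#' \code{accuracyDenominator = "all"} to divide by all true sites instead.
#' The FPR denominator is the number of assayable non-variant sites by
#' default; \code{fprDenominator = "calls"} reports the fraction of calls
#' that are false (1 - precision) instead. Accuracy is defined as 0 when no
#' true site is called.
#'
#' @param truthSet truth table from [generateTruthSet()] (needs
#'   \code{position} and \code{trueFreq}).
#' @param calls call table (needs \code{position} and \code{maf}).
#' @param nAssayableSites number of sites the caller could have called
#'   (typically the number of covered reference positions).
#' @param tol accuracy tolerance on the frequency, absolute and inclusive.
#' @param accuracyDenominator,fprDenominator see Details.
#' @return a one-row \code{data.frame}: \code{power}, \code{accuracy},
#'   \code{fpr}, and the underlying counts \code{nTrue}, \code{nTrueCalled},
#'   \code{nFalseCalled}.
#' @examples
#' truth <- data.frame(position = c(10, 20), trueFreq = c(0.04, 0.07))
#' calls <- data.frame(position = c(10, 20, 30), maf = c(0.045, 0.062, 0.02))
#' evaluateCalls(truth, calls, nAssayableSites = 1000)
#' @export
evaluateCalls <- function(truthSet, calls, nAssayableSites, tol = 0.01,
                          accuracyDenominator = c("called", "all"),
                          fprDenominator = c("sites", "calls")) {
  accuracyDenominator <- match.arg(accuracyDenominator)
  fprDenominator <- match.arg(fprDenominator)
  if (is.null(truthSet) || !nrow(truthSet)) stop("empty truth set")
  if (nAssayableSites < nrow(truthSet))
    stop("truth positions must be a subset of assayable sites")
  nTrue <- nrow(truthSet)
  m <- match(calls$position, truthSet$position)
  isTrue <- !is.na(m)
  nTrueCalled <- base::length(unique(calls$position[isTrue]))
  nFalseCalled <- base::length(unique(calls$position[!isTrue]))
  power <- nTrueCalled / nTrue
  accurate <- isTrue & abs(calls$maf - truthSet$trueFreq[m]) <= tol
  nAccurate <- base::length(unique(calls$position[accurate]))
  accuracy <- if (accuracyDenominator == "called") {
    if (nTrueCalled == 0) 0 else nAccurate / nTrueCalled
  } else nAccurate / nTrue
  fpr <- if (fprDenominator == "sites")
    nFalseCalled / (nAssayableSites - nTrue)
  else if (nrow(calls) == 0) 0 else nFalseCalled / nrow(calls)
  data.frame(power = power, accuracy = accuracy, fpr = fpr,
             nTrue = nTrue, nTrueCalled = nTrueCalled,
             nFalseCalled = nFalseCalled)
}

#' Composite caller score
#'
#' The single-number ranking used to pick a caller:
#' \code{(power * accuracy) * (1 - fpr)}, in [0, 1]. Monotone non-decreasing
#' in power and accuracy and non-increasing in the false positive rate; a
#' perfect caller scores 1 and a caller that calls nothing scores 0.
#'
#' @param power,accuracy,fpr metric values in [0, 1] (vectorised).
#' @return numeric score(s) in [0, 1].
#' @examples
#' compositeScore(0.9, 0.8, 0.1)   # 0.648
#' @export
compositeScore <- function(power, accuracy, fpr) {
  .checkProb(power, "power"); .checkProb(accuracy, "accuracy")
  .checkProb(fpr, "fpr")
  power * accuracy * (1 - fpr)
}

#' The packaged caller in benchmark-interface form
#'
#' A caller, for benchmarking purposes, is any function taking a
#' \linkS4class{Pileup} and returning a call \code{data.frame} with
#' \code{position} and \code{maf} columns. This wraps [callSites()];
#' wrappers around external tools can be supplied alongside it.
#'
#' @param pileup a \linkS4class{Pileup}.
#' @param ... passed to [callSites()].
#' @return a call \code{data.frame}.
#' @export
nativeCaller <- function(pileup, ...) callSites(pileup, ...)

#' Benchmark callers over a coverage grid
#'
#' For each coverage, simulates one pileup carrying the truth set and runs
#' every caller on it, scoring each with [evaluateCalls()] and
#' [compositeScore()]. A caller crashing on one cell yields an NA row for
#' that cell, never a global failure. Deterministic given \code{seed}: cell
#' seeds are derived per coverage so every caller sees the same pileup.
#'
#' @param genome a \linkS4class{Mitogenome} or
#'   \linkS4class{ExtendedReference}.
#' @param truthSet a truth table from [generateTruthSet()].
#' @param callers named list of caller functions (see [nativeCaller()]).
#' @param coverages coverage grid; the default spans 50X to 25,000X.
#' @param errorRate sequencing error rate for the simulated pileups.
#' @param seed integer seed.
#' @param exactMode passed to [simulatePileup()].
#' @param ... further arguments passed on to [evaluateCalls()].
#' @return \code{data.frame} with one row per (caller, coverage):
#'   \code{caller}, \code{coverage}, \code{power}, \code{accuracy},
#'   \code{fpr}, \code{score}.
#' @seealso [rankCallers()]
#' @export
benchmarkGrid <- function(genome, truthSet,
                          callers = list(native = nativeCaller),
                          coverages = c(50, 100, 250, 500, 1000, 2500, 5000,
                                        10000, 25000),
                          errorRate = 0.001, seed = NULL, exactMode = FALSE,
                          ...) {
  stopifnot(base::length(callers) >= 1, !is.null(names(callers)))
  rows <- list()
  for (ci in seq_along(coverages)) {
    cov <- coverages[ci]
    cellSeed <- if (is.null(seed)) NULL else seed + ci
    pu <- simulatePileup(genome, truthSet, coverage = cov,
                         errorRate = errorRate, seed = cellSeed,
                         exactMode = exactMode)
    nAssay <- sum(pileupDepth(pu) > 0)
    for (nm in names(callers)) {
      res <- tryCatch({
        calls <- callers[[nm]](pu)
        ev <- evaluateCalls(truthSet, calls, nAssayableSites = nAssay, ...)
        data.frame(caller = nm, coverage = cov, power = ev$power,
                   accuracy = ev$accuracy, fpr = ev$fpr,
                   score = compositeScore(ev$power, ev$accuracy, ev$fpr),
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(caller = nm, coverage = cov, power = NA_real_,
                   accuracy = NA_real_, fpr = NA_real_, score = NA_real_,
                   stringsAsFactors = FALSE))
      rows[[base::length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank callers from a benchmark grid
#'
#' @param grid output of [benchmarkGrid()].
#' @return \code{data.frame} of callers ordered by mean composite score
#'   across coverages (NA cells dropped).
#' @export
rankCallers <- function(grid) {
  sc <- tapply(grid$score, grid$caller, mean, na.rm = TRUE)
  out <- data.frame(caller = names(sc), meanScore = as.numeric(sc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$meanScore), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
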
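#' Duplicate-treatment concordance filter
#'
#' Deep amplicon resequencing cannot distinguish PCR duplicates from
#' sampling-coincidence read pairs, so neither keeping nor removing
#' duplicates is obviously right. This reliability test runs detection both
#' ways and flags samples whose heteroplasmy counts disagree too much
#' between the two treatments:
#' \enumerate{
#'   \item per sample, take the absolute difference of the two counts;
#'   \item screen outliers: drop differences more than 2 interquartile
#'     ranges below the first quartile or above the third quartile;
#'   \item cutoff = \code{floor(mean + 2 * sd)} of the retained differences
#'     (sample sd, n-1 denominator);
#'   \item samples whose difference exceeds the cutoff are unreliable.
#' }
#' Differences are non-negative, so only the upper IQR fence can bite in
#' practice; the symmetric lower cutoff is not applied.
#'
#' @param countDup,countDedup equal-length numeric vectors of per-sample
#'   heteroplasmy counts with duplicates retained resp. removed. Names of
#'   \code{countDup} (if any) are used as sample IDs.
#' @param iqrMult the IQR fence multiplier (default 2).
#' @param qtype quantile convention passed to [stats::quantile()]; default 7,
#'   linear interpolation.
#' @return list with \code{records} (data.frame: \code{sample},
#'   \code{countDup}, \code{countDedup}, \code{difference}, \code{outlier},
#'   \code{reliable}) and the integer \code{cutoff}.
#' @examples
#' d <- c(0, 0, 1, 1, 1, 2, 2, 3, 10)
#' res <- duplicateConcordance(d, rep(0, 9))
#' res$cutoff            # 3
#' sum(!res$records$reliable)
#' @export
duplicateConcordance <- function(countDup, countDedup, iqrMult = 2,
                                 qtype = 7) {
  stopifnot(base::length(countDup) == base::length(countDedup))
  n <- base::length(countDup)
  if (n < 4) stop("need at least 4 samples for meaningful quartiles")
  id <- if (!is.null(names(countDup))) names(countDup) else
    sprintf("S%03d", seq_len(n))
  diffs <- abs(countDup - countDedup)
  q <- quantile(diffs, c(0.25, 0.75), type = qtype, names = FALSE)
  iqr <- q[2] - q[1]
  outlier <- diffs < q[1] - iqrMult * iqr | diffs > q[2] + iqrMult * iqr
  kept <- diffs[!outlier]
  cutoff <- floor(mean(kept) + 2 * sd(kept))
  records <- data.frame(sample = id, countDup = countDup,
                        countDedup = countDedup, difference = diffs,
                        outlier = outlier, reliable = diffs <= cutoff,
                        stringsAsFactors = FALSE, row.names = NULL)
  list(records = records, cutoff = cutoff)
}

#' Average-coverage sample filter
#'
#' Callers lose power rapidly at low coverage, so samples whose mean depth
#' falls below a threshold are removed before analysis. Samples exactly at
#' the threshold are retained (only "below threshold" is removed).
#'
#' @param meanCoverage named numeric vector of per-sample average coverages.
#' @param threshold minimum acceptable average coverage (default 1000X).
#' @return list with \code{retained} and \code{removed} (character vectors of
#'   sample names) and the \code{coverage} table.
#' @examples
#' coverageFilter(c(a = 142, b = 1355, c = 7800))$retained
#' @export
coverageFilter <- function(meanCoverage, threshold = 1000) {
  stopifnot(all(meanCoverage >= 0))
  id <- if (!is.null(names(meanCoverage))) names(meanCoverage) else
    sprintf("S%03d", seq_along(meanCoverage))
  keep <- meanCoverage >= threshold
  list(retained = id[keep], removed = id[!keep],
       coverage = data.frame(sample = id, meanCoverage = meanCoverage,
                             retained = keep, stringsAsFactors = FALSE,
                             row.names = NULL))
}
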
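#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats rpois rbinom rmultinom rnbinom rexp runif quantile sd
#'   pbinom dbinom pchisq ks.test wilcox.test kruskal.test coef vcov AIC logLik
#'   fitted cooks.distance glm poisson predict dist complete.cases setNames
#'   chisq.test set.seed
#' @importFrom utils read.delim write.table head
NULL

## Run expr with a local RNG state seeded by `seed`; the caller's RNG stream
## is untouched. seed = NULL means "use the current stream" (non-reproducible).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has.seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

DNA_BASES4 <- c("A", "C", "G", "T")

#' Convert age labels to numeric ages
#'
#' Cohort labels such as \code{"6+"} (an open-ended oldest cohort) are mapped
#' to their lower bound, so \code{"6+"} becomes 6. Plain numeric labels pass
#' through. Anything unparseable becomes \code{NA}, which downstream model
#' fitting drops as "unusable age".
#'
#' @param age numeric vector or character vector of cohort labels.
#' @return numeric vector of ages.
#' @examples
#' ageToNumeric(c("0", "3", "6+"))
#' @export
ageToNumeric <- function(age) {
  if (is.numeric(age)) return(as.numeric(age))
  suppressWarnings(as.numeric(sub("\\+$", "", as.character(age))))
}

## Internal: single-stop argument checks
.checkProb <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (open) x > 0 & x < 1 else x >= 0 & x <= 1)
  if (!all(ok)) stop(sprintf("'%s' must lie in %s", name,
                             if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}
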
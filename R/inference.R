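#' Negative binomial GLM of heteroplasmy count on age
#'
#' Fits log(mu) = b0 + b1 * age with an NB2 response (variance
#' mu + mu^2/theta) by maximum likelihood, the standard model for
#' overdispersed per-individual heteroplasmy counts. Ages may be numeric or
#' cohort labels; the open-ended oldest cohort label (e.g. \code{"6+"}) is
#' coded as its lower bound and samples of unusable (NA) age are dropped.
#' When the data are equidispersed the theta estimation cannot converge; the
#' fit then falls back to Poisson regression (theta = Inf) and is flagged,
#' never an exception.
#'
#' AICc is reported as AIC + 2k(k+1)/(n-k-1) with k = 3 (two coefficients
#' plus the dispersion).
#'
#' @param counts non-negative integer response vector.
#' @param age numeric ages or cohort labels (see [ageToNumeric()]).
#' @return an object of class \code{"nbAgeFit"}: list with
#'   \code{coefficients}, \code{se}, \code{p.value} (Wald, per
#'   coefficient), \code{theta}, \code{logLik}, \code{AIC}, \code{AICc},
#'   \code{fitted}, \code{converged}, \code{family}, \code{n}, the model
#'   frame \code{data}, and the underlying \code{glm} object.
#' @examples
#' pop <- simulatePopulation(seed = 1)
#' cnt <- heteroplasmyCounts(pop)
#' latest <- mostRecentSamples(cnt)
#' fit <- fitNbGlm(latest$count, latest$ageLabel)
#' coef(fit)
#' @export
fitNbGlm <- function(counts, age) {
  ageNum <- ageToNumeric(age)
  keep <- !is.na(ageNum) & !is.na(counts)
  counts <- counts[keep]; ageNum <- ageNum[keep]
  n <- base::length(counts)
  if (n < 3) stop("need at least 3 usable observations")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  df <- data.frame(count = counts, age = ageNum)
  fit <- NULL; family <- "negative binomial"; converged <- TRUE
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ age, data = df)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    ## equidispersed or degenerate data: Poisson limit of the NB
    fit <- glm(count ~ age, family = poisson(), data = df)
    family <- "poisson"
    converged <- fit$converged
  }
  sm <- summary(fit)
  k <- 3
  aic <- AIC(fit)
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  theta <- if (family == "negative binomial") fit$theta else Inf
  structure(list(
    coefficients = coef(fit),
    se = sm$coefficients[, "Std. Error"],
    p.value = sm$coefficients[, 4],
    theta = theta,
    logLik = as.numeric(logLik(fit)),
    AIC = aic, AICc = aicc,
    fitted = fitted(fit),
    converged = converged,
    family = family,
    n = n,
    data = df,
    glm = fit), class = "nbAgeFit")
}

#' @export
print.nbAgeFit <- function(x, ...) {
  cat(sprintf("Heteroplasmy-count GLM (%s), n = %d%s\n", x$family, x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `p value` = x$p.value)
  print(round(tab, 4))
  cat(sprintf("theta = %.4g, AICc = %.2f\n", x$theta, x$AICc))
  invisible(x)
}

#' @export
coef.nbAgeFit <- function(object, ...) object$coefficients

#' Cook's influence diagnostics for the age model
#'
#' Generalized Cook's distance (leverage- and Pearson-residual-based, as
#' produced by [stats::cooks.distance()] on the underlying GLM). No
#' universally agreed threshold exists for GLMs; observations above
#' \code{8 / (n - 2k)} (k = 3 parameters) are flagged and the top-m list is
#' reported so that removal remains an explicit, inspectable decision.
#'
#' @param fit an \code{"nbAgeFit"}.
#' @param threshold flagging threshold; default \code{8 / (n - 2k)}.
#' @param topM how many highest-influence observations to list.
#' @return list: \code{influence} (data.frame \code{observation},
#'   \code{cooksD}, \code{flagged}), \code{threshold}, \code{top} (indices of
#'   the topM most influential observations).
#' @export
cooksInfluence <- function(fit, threshold = NULL, topM = 5) {
  stopifnot(inherits(fit, "nbAgeFit"))
  cd <- cooks.distance(fit$glm)
  n <- fit$n; k <- 3
  if (is.null(threshold)) threshold <- 8 / (n - 2 * k)
  inf <- data.frame(observation = seq_len(n), cooksD = as.numeric(cd),
                    flagged = as.numeric(cd) > threshold, row.names = NULL)
  list(influence = inf, threshold = threshold,
       top = order(-inf$cooksD)[seq_len(min(topM, n))])
}

#' Bootstrap the age model
#'
#' Case-resampling bootstrap by default: rows of (count, age) are resampled
#' with replacement B times and the model refit. A parametric variant
#' (counts simulated from the fitted NB at the original ages) is available
#' via \code{type}. Replicates that fail to refit are dropped and counted.
#'
#' @param fit an \code{"nbAgeFit"}.
#' @param B number of replicates (default 1000).
#' @param seed integer seed or \code{NULL}.
#' @param type \code{"case"} or \code{"parametric"}.
#' @return list: \code{bias} and \code{se} per coefficient, the replicate
#'   coefficient matrix \code{replicates}, and \code{nFailed}.
#' @export
bootstrapFit <- function(fit, B = 1000, seed = NULL,
                         type = c("case", "parametric")) {
  stopifnot(inherits(fit, "nbAgeFit"), B >= 2)
  type <- match.arg(type)
  df <- fit$data
  n <- nrow(df)
  withSeed(seed, {
    reps <- matrix(NA_real_, nrow = B, ncol = 2,
                   dimnames = list(NULL, names(fit$coefficients)))
    for (b in seq_len(B)) {
      dd <- if (type == "case") df[sample.int(n, n, replace = TRUE), ]
      else data.frame(
        count = if (is.finite(fit$theta))
          rnbinom(n, size = fit$theta, mu = fit$fitted)
        else rpois(n, fit$fitted),
        age = df$age)
      co <- tryCatch(coef(fitNbGlm(dd$count, dd$age)),
                     error = function(e) NULL)
      if (!is.null(co)) reps[b, ] <- co
    }
    ok <- stats::complete.cases(reps)
    est <- fit$coefficients
    list(bias = colMeans(reps[ok, , drop = FALSE]) - est,
         se = apply(reps[ok, , drop = FALSE], 2, sd),
         replicates = reps, nFailed = sum(!ok))
  })
}

#' Permutation over the recapture-sample choice
#'
#' Using the most recent sample from recaptured individuals is one arbitrary
#' choice among several; this quantifies its influence. For each of B
#' replicates, one sample per recaptured individual is drawn uniformly
#' (non-recaptured individuals keep their single sample), the NB age model
#' is refit, and the age slope and its Wald significance are recorded.
#'
#' @param samples sample table with \code{individual}, \code{age} (or
#'   \code{ageLabel}), \code{year} and \code{count} columns (see
#'   [heteroplasmyCounts()]); samples of unusable age are excluded first.
#' @param B number of replicates (default 1000).
#' @param alpha significance level for counting significant replicates.
#' @param seed integer seed or \code{NULL}.
#' @return list: \code{fractionSignificant}, \code{meanSlope},
#'   \code{rangeSlope}, per-replicate \code{slopes}, \code{nFailed}, and the
#'   replicate dataset size \code{n}.
#' @export
recapturePermutation <- function(samples, B = 1000, alpha = 0.05,
                                 seed = NULL) {
  age <- ageToNumeric(if ("age" %in% names(samples)) samples$age
                      else samples$ageLabel)
  s <- samples[!is.na(age), , drop = FALSE]
  s$ageNum <- age[!is.na(age)]
  byInd <- split(seq_len(nrow(s)), s$individual)
  withSeed(seed, {
    slopes <- rep(NA_real_, B); sig <- rep(NA, B)
    for (b in seq_len(B)) {
      pick <- vapply(byInd, function(ix)
        if (base::length(ix) == 1L) ix else ix[sample.int(base::length(ix), 1L)],
        1L)
      dd <- s[pick, , drop = FALSE]
      ft <- tryCatch(fitNbGlm(dd$count, dd$ageNum), error = function(e) NULL)
      if (!is.null(ft)) {
        slopes[b] <- ft$coefficients[["age"]]
        sig[b] <- ft$p.value[["age"]] < alpha
      }
    }
    ok <- !is.na(slopes)
    list(fractionSignificant = mean(sig[ok]),
         meanSlope = mean(slopes[ok]),
         rangeSlope = range(slopes[ok]),
         slopes = slopes, nFailed = sum(!ok),
         n = base::length(byInd))
  })
}

#' Kruskal-Wallis test of batch effects on heteroplasmy counts
#'
#' Rank-based (tie-corrected) test that per-sample counts differ between
#' sequencing batches, plus the largest pairwise difference of batch means —
#' a significant test with a small mean difference indicates a real but
#' practically negligible batch effect.
#'
#' @param counts per-sample heteroplasmy counts.
#' @param batch batch labels, at least two distinct values.
#' @return list: \code{statistic}, \code{p.value},
#'   \code{maxMeanDifference}, \code{batchMeans}.
#' @export
batchEffectTest <- function(counts, batch) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) stop("need at least two batches")
  if (any(table(batch) == 0)) stop("empty batch")
  kw <- kruskal.test(counts, batch)
  mns <- tapply(counts, batch, mean)
  list(statistic = unname(kw$statistic), p.value = kw$p.value,
       maxMeanDifference = max(dist(mns)),
       batchMeans = mns)
}

#' Longitudinal summary of recaptured individuals
#'
#' For individuals sampled in several years, summarises how heteroplasmy
#' changes through time: per consecutive-year interval the signed change in
#' count (classed increase / decrease / no change), the overall mean and sd
#' of those changes, and site persistence — the fraction of distinct
#' (individual, site) heteroplasmies observed at two or more of that
#' individual's time-points, and at all of them. Sites are matched by
#' (position, minor allele). Intervals longer than one year are excluded
#' from the consecutive-interval statistics but still contribute to
#' sharing.
#'
#' @param samples sample table (\code{sample}, \code{individual},
#'   \code{year}) restricted to individuals with >= 2 time-points; others
#'   are ignored.
#' @param calls call table (\code{sample}, \code{position}, \code{alt}).
#' @return list: \code{intervals} (data.frame \code{individual},
#'   \code{fromYear}, \code{toYear}, \code{change}, \code{class}),
#'   \code{meanChange}, \code{sdChange}, \code{sharedTwoPlus},
#'   \code{sharedAll}, \code{nIndividuals}.
#' @export
longitudinalSummary <- function(samples, calls) {
  cnt <- table(factor(calls$sample, levels = samples$sample))
  samples$count <- as.integer(cnt[samples$sample])
  multi <- names(which(table(samples$individual) >= 2))
  s <- samples[samples$individual %in% multi, , drop = FALSE]
  if (!nrow(s)) stop("no individual has two or more time-points")
  s <- s[order(s$individual, s$year), , drop = FALSE]
  if (any(tapply(s$year, s$individual,
                 function(y) any(duplicated(y)))))
    stop("an individual has two samples in one year")

  ivs <- list()
  for (id in unique(s$individual)) {
    si <- s[s$individual == id, , drop = FALSE]
    for (j in seq_len(nrow(si) - 1L)) {
      if (si$year[j + 1L] - si$year[j] != 1L) next  # non-consecutive
      ch <- si$count[j + 1L] - si$count[j]
      ivs[[base::length(ivs) + 1L]] <- data.frame(
        individual = id, fromYear = si$year[j], toYear = si$year[j + 1L],
        change = ch,
        class = if (ch > 0) "increase" else if (ch < 0) "decrease"
                else "no change",
        stringsAsFactors = FALSE)
    }
  }
  intervals <- if (base::length(ivs)) do.call(rbind, ivs) else
    data.frame(individual = character(0), fromYear = integer(0),
               toYear = integer(0), change = integer(0),
               class = character(0), stringsAsFactors = FALSE)

  ## site sharing across an individual's time-points
  cc <- calls[calls$sample %in% s$sample, , drop = FALSE]
  cc$individual <- s$individual[match(cc$sample, s$sample)]
  nTP <- tapply(s$year, s$individual, base::length)
  twoPlus <- 0L; allTP <- 0L; total <- 0L
  for (id in unique(cc$individual)) {
    ci <- cc[cc$individual == id, , drop = FALSE]
    key <- paste(ci$position, ci$alt)
    seen <- table(key)
    total <- total + base::length(seen)
    twoPlus <- twoPlus + sum(seen >= 2)
    allTP <- allTP + sum(seen == nTP[[id]])
  }
  list(intervals = intervals,
       meanChange = if (nrow(intervals)) mean(intervals$change) else NA_real_,
       sdChange = if (nrow(intervals) > 1) sd(intervals$change) else NA_real_,
       sharedTwoPlus = if (total) twoPlus / total else NA_real_,
       sharedAll = if (total) allTP / total else NA_real_,
       nIndividuals = base::length(unique(s$individual)))
}
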
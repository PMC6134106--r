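test_that("flat counts give a zero age slope (Poisson fallback allowed)", {
  fit <- fitNbGlm(rep(3L, 30), rep(0:5, 5))
  expect_equal(unname(coef(fit)[["age"]]), 0, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_error(fitNbGlm(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitNbGlm(c(-1, 2, 3), c(1, 2, 3)), "non-negative integers")
})

test_that("NB GLM recovers known parameters on simulated data", {
  set.seed(101)
  n <- 500
  age <- sample(0:6, n, replace = TRUE)
  counts <- rnbinom(n, size = 2, mu = exp(0.3 + 0.1 * age))
  fit <- fitNbGlm(counts, age)
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 0.3), 2 * fit$se[[1]])
  expect_lt(abs(coef(fit)[["age"]] - 0.1), 2 * fit$se[[2]])
  expect_gt(fit$theta, 1)
  expect_lt(fit$theta, 4)
  expect_gt(fit$AICc, fit$AIC)
})

test_that("the NB fit approaches Poisson regression on equidispersed data", {
  set.seed(7)
  n <- 400
  age <- runif(n, 0, 6)
  counts <- rpois(n, exp(0.2 + 0.08 * age))
  nb <- fitNbGlm(counts, age)
  po <- glm(counts ~ age, family = poisson())
  expect_lt(abs(coef(nb)[["age"]] - coef(po)[["age"]]), 1e-3)
})

test_that("cohort labels map through and unusable ages are dropped", {
  counts <- c(1L, 2L, 0L, 3L, 5L, 1L)
  age <- c("0", "2", "4", "6+", NA, "3")
  fit <- fitNbGlm(counts, age)
  expect_identical(fit$n, 5L)            # the NA-age sample is dropped
  expect_identical(max(fit$data$age), 6) # "6+" coded as its lower bound
})

test_that("Cook influence flags a planted extreme observation", {
  set.seed(31)
  n <- 100
  age <- sample(0:6, n, replace = TRUE)
  counts <- rnbinom(n, size = 2, mu = exp(0.1 + 0.05 * age))
  counts[17] <- 60L                       # planted outlier
  fit <- fitNbGlm(counts, age)
  ci <- cooksInfluence(fit)
  expect_identical(which.max(ci$influence$cooksD), 17L)
  expect_true(17L %in% ci$top)
  ## oracle: dropping the planted point moves the slope more than dropping
  ## a median-influence point does (leave-one-out refit comparison)
  slope <- function(ix) coef(fitNbGlm(counts[-ix], age[-ix]))[["age"]]
  full <- coef(fit)[["age"]]
  med <- order(ci$influence$cooksD)[n %/% 2]
  expect_gt(abs(slope(17) - full), abs(slope(med) - full))
  ## symmetric data: identical observations share influence values
  fitSym <- fitNbGlm(rep(c(2L, 5L), 10), rep(c(0, 4), 10))
  cd <- cooksInfluence(fitSym)$influence$cooksD
  expect_equal(cd[1], cd[3], tolerance = 1e-10)
})

test_that("removing a zero-influence duplicate leaves estimates unchanged", {
  set.seed(5)
  age <- rep(0:5, each = 10)
  counts <- rnbinom(60, size = 3, mu = exp(0.2 + 0.1 * age))
  fit <- fitNbGlm(counts, age)
  ## append an observation lying exactly on the fitted curve at an existing
  ## age, then remove it again: estimates must agree to high precision
  fit2 <- fitNbGlm(c(counts, counts[1]), c(age, age[1]))
  fit3 <- fitNbGlm(c(counts, counts[1])[-61], c(age, age[1])[-61])
  expect_equal(coef(fit3), coef(fit), tolerance = 1e-9)
  expect_false(identical(coef(fit2), coef(fit3)))
})

test_that("bootstrap bias and SE behave on degenerate and synthetic data", {
  ## degenerate: constant counts -> every resample refits to the same
  ## zero-slope model whatever rows it draws
  fitD <- fitNbGlm(rep(2L, 20), rep(c(3, 5), 10))
  bsD <- bootstrapFit(fitD, B = 10, seed = 1)
  expect_equal(unname(bsD$se), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(bsD$bias), c(0, 0), tolerance = 1e-10)
  ## seeded determinism
  set.seed(77)
  age <- sample(0:6, 150, replace = TRUE)
  counts <- rnbinom(150, size = 2, mu = exp(0.2 + 0.08 * age))
  fit <- fitNbGlm(counts, age)
  b1 <- bootstrapFit(fit, B = 40, seed = 9)
  b2 <- bootstrapFit(fit, B = 40, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  ## case-resampling SE in the same ballpark as the Wald SE
  b3 <- bootstrapFit(fit, B = 300, seed = 10)
  expect_lt(abs(b3$se[["age"]] - fit$se[["age"]]) / fit$se[["age"]], 0.25)
  ## parametric flavour also runs
  b4 <- bootstrapFit(fit, B = 20, seed = 11, type = "parametric")
  expect_true(all(is.finite(b4$se)))
})

test_that("recapture permutation collapses when there is nothing to choose", {
  samples <- data.frame(sample = sprintf("s%d", 1:40),
                        individual = sprintf("i%d", 1:40),
                        age = rep(0:7, 5), year = 2015,
                        count = rpois(40, 2), stringsAsFactors = FALSE)
  rp <- recapturePermutation(samples, B = 8, seed = 2)
  expect_true(rp$fractionSignificant %in% c(0, 1))
  expect_equal(diff(rp$rangeSlope), 0)
  expect_identical(rp$n, 40L)
})

test_that("recapture permutation brackets the true slope on synthetic data", {
  pp <- populationParams(beta1 = 0.1, cohortSizes = c("0" = 40, "1" = 30,
                                                      "2" = 30, "3" = 25,
                                                      "4" = 25, "5" = 20,
                                                      "6+" = 30))
  pop <- simulatePopulation(pp, seed = 13)
  cnt <- heteroplasmyCounts(pop)
  rp <- recapturePermutation(cnt, B = 60, seed = 14)
  latest <- mostRecentSamples(cnt)
  full <- coef(fitNbGlm(latest$count, latest$age))[["age"]]
  ## permuted slopes scatter around slopes from comparable datasets
  expect_lt(abs(rp$meanSlope - full), 0.1)
  expect_true(rp$rangeSlope[1] <= rp$meanSlope,
              rp$rangeSlope[2] >= rp$meanSlope)
})

test_that("batch test matches an exact small-sample oracle", {
  ## identical values in every batch: statistic 0 (after tie correction
  ## this is degenerate; KW reports NaN p on all-ties, so use distinct
  ## identical distributions)
  r0 <- batchEffectTest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  expect_equal(r0$maxMeanDifference, 0)
  ## two fully separated batches of 3: oracle from exact rank enumeration,
  ## H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 = 3.857..., and the
  ## permutation p of the most extreme split is 2/choose(6,3) = 0.1
  r <- batchEffectTest(c(0, 0, 0, 5, 5, 5), rep(c("a", "b"), each = 3))
  expect_equal(r$maxMeanDifference, 5)
  expect_gt(r$statistic, 3.8)
  expect_error(batchEffectTest(1:5, rep("a", 5)), "two batches")
  ## type-I error control at roughly alpha under a single NB law
  set.seed(3)
  rej <- mean(replicate(400, {
    x <- rnbinom(30, size = 2, mu = 1.5)
    b <- rep(c("a", "b", "c"), each = 10)
    batchEffectTest(x, b)$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("longitudinal summary: telescoping, classes and sharing", {
  samples <- data.frame(
    sample = c("a13", "a14", "a15", "b13", "b15", "c14", "c15"),
    individual = c("a", "a", "a", "b", "b", "c", "c"),
    year = c(2013, 2014, 2015, 2013, 2015, 2014, 2015),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    sample = c("a13", "a13", "a14", "a15", "b13", "b15", "c14"),
    position = c(100, 200, 100, 100, 300, 300, 400),
    alt = c("T", "G", "T", "T", "C", "C", "A"),
    stringsAsFactors = FALSE)
  ls <- longitudinalSummary(samples, calls)
  ## individual b is non-consecutive: contributes no interval
  expect_identical(sort(unique(ls$intervals$individual)), c("a", "c"))
  ## a: counts 2,1,1 -> changes -1, 0; c: counts 1,0 -> -1
  expect_identical(sum(ls$intervals$change), -2L)
  expect_setequal(ls$intervals$class, c("decrease", "no change"))
  ## telescoping per individual over consecutive runs
  aIv <- ls$intervals[ls$intervals$individual == "a", ]
  expect_identical(sum(aIv$change), 1L - 2L)
  ## sharing: distinct (ind, site, allele): a:100 (3 tp), a:200 (1),
  ## b:300 (2 of 2), c:400 (1 of 2) -> 2/4 seen twice+, and for "all
  ## time-points": a:100 yes, b:300 yes -> 2/4
  expect_equal(ls$sharedTwoPlus, 0.5)
  expect_equal(ls$sharedAll, 0.5)
  expect_equal(ls$meanChange, mean(c(-1, 0, -1)))
  ## counts [2,2,2] -> two intervals, both "no change"
  s2 <- data.frame(sample = c("x1", "x2", "x3"), individual = "x",
                   year = 2013:2015, stringsAsFactors = FALSE)
  c2 <- data.frame(sample = rep(c("x1", "x2", "x3"), each = 2),
                   position = rep(c(1, 2), 3),
                   alt = rep("G", 6), stringsAsFactors = FALSE)
  l2 <- longitudinalSummary(s2, c2)
  expect_identical(nrow(l2$intervals), 2L)
  expect_true(all(l2$intervals$class == "no change"))
  expect_equal(l2$meanChange, 0)
})

test_that("telescoping holds for generated recapture histories", {
  pop <- simulatePopulation(seed = 17)
  ls <- longitudinalSummary(pop$samples, pop$calls)
  cnt <- heteroplasmyCounts(pop)
  for (id in unique(ls$intervals$individual)) {
    iv <- ls$intervals[ls$intervals$individual == id, ]
    ## consecutive by construction in the generator
    ci <- cnt[cnt$individual == id, ]
    ci <- ci[order(ci$year), ]
    expect_identical(sum(iv$change),
                     ci$count[nrow(ci)] - ci$count[1])
  }
})
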
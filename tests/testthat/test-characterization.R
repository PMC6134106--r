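test_that("the four classes partition the twelve ordered substitutions", {
  expect_identical(classifySubstitution("G", "A"), "GC_AT_transition")
  expect_identical(classifySubstitution("C", "A"), "GC_TA_transversion")
  expect_identical(classifySubstitution("A", "T"), "AT_TA_transversion")
  expect_identical(classifySubstitution("G", "C"), "GC_CG_transversion")
  bases <- c("A", "C", "G", "T")
  subs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  cls <- classifySubstitution(subs$ref, subs$alt)
  expect_false(any(is.na(cls)))
  expect_identical(as.integer(table(cls)[c(
    "GC_AT_transition", "GC_TA_transversion", "AT_TA_transversion",
    "GC_CG_transversion")]), c(4L, 4L, 2L, 2L))
  ## strand symmetry: a substitution and its complement share a class
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(classifySubstitution(subs$ref, subs$alt),
                   classifySubstitution(comp[subs$ref], comp[subs$alt]))
  expect_error(classifySubstitution("A", "A"), "differ")
  expect_error(classifySubstitution("N", "A"), "non-DNA")
})

test_that("spectrum summary counts, Ts/Tv and oxidative burden", {
  calls <- data.frame(
    ref = c("G", "C", "A", "T", "G", "C", "C", "C", "A"),
    alt = c("A", "T", "G", "C", "T", "A", "A", "G", "T"),
    sample = c(rep("s1", 6), "s2", "s2", "s3"),
    stringsAsFactors = FALSE)
  sp <- spectrumSummary(calls)
  expect_identical(sum(sp$counts), 9L)
  ## 4 transitions, 5 transversions
  expect_equal(sp$tsTv, 4 / 5)
  expect_equal(sum(sp$proportions), 1)
  ## oxidative calls: G>T, C>A, C>A -> burden by sample
  expect_identical(as.integer(sp$oxidativeBurden[c("s1", "s2", "s3")]),
                   c(2L, 1L, 0L))
  ## all transitions: undefined ratio
  spTs <- spectrumSummary(data.frame(ref = c("G", "C"), alt = c("A", "T")))
  expect_true(is.na(spTs$tsTv))
  expect_error(spectrumSummary(NULL), "empty")
})

test_that("effect annotation agrees with direct translation on known genes", {
  g <- tinyGenome()
  ## plus gene codons: ATG GCA AAA TGG (M A K W), positions 4..15
  ## TGG -> TGA at pos 15 codon pos 3: Trp -> Trp under the vertebrate
  ## mitochondrial code (TGA is tryptophan, not stop): synonymous
  a <- annotateEffect(data.frame(position = 15, ref = "G", alt = "A"), g)
  expect_identical(a$effect, "synonymous")
  expect_identical(a$refAA, "W"); expect_identical(a$altAA, "W")
  expect_identical(a$codonPos, 3L)
  ## GCA -> GTA at codon position 2: Ala -> Val, nonsynonymous
  b <- annotateEffect(data.frame(position = 8, ref = "C", alt = "T"), g,
                      scorer = granthamScorer())
  expect_identical(b$effect, "nonsynonymous")
  expect_identical(b$refAA, "A"); expect_identical(b$altAA, "V")
  expect_identical(b$codonPos, 2L)
  expect_identical(b$deleterious, "Neutral")   # Grantham A-V = 64
  ## AAA -> TAA would be nonsense on the heavy strand (K -> stop)
  cnon <- annotateEffect(data.frame(position = 10, ref = "A", alt = "T"), g)
  expect_identical(cnon$effect, "nonsense")
  ## control region -> noncoding
  d <- annotateEffect(data.frame(position = 25, ref = "G", alt = "A"), g)
  expect_identical(d$effect, "noncoding")
  expect_identical(d$region, "noncoding")
  expect_error(annotateEffect(data.frame(position = 99, ref = "A",
                                         alt = "G"), g), "outside")
})

test_that("minus-strand annotation uses the reverse complement frame", {
  g <- tinyGenome()
  ## minus gene 31..42, CDS = revcomp(ATGCATCATCAT) = ATG ATG ATG CAT
  ## genomic position 42 is CDS base 1 (codon 1, pos 1); mutate T->C there:
  ## genomic T at 42, CDS base A -> G, codon ATG -> GTG: M -> V
  a <- annotateEffect(data.frame(position = 42, ref = "T", alt = "C"), g)
  expect_identical(a$effect, "nonsynonymous")
  expect_identical(a$refAA, "M"); expect_identical(a$altAA, "V")
  expect_identical(a$codonPos, 1L)
  ## genomic 31 is the last CDS base (codon 4 pos 3): CAT -> CAA? genomic
  ## A31 -> T gives CDS codon CAT -> CAA: H -> Q, nonsynonymous
  b <- annotateEffect(data.frame(position = 31, ref = "A", alt = "T"), g)
  expect_identical(b$codonPos, 3L)
  expect_identical(b$refAA, "H"); expect_identical(b$altAA, "Q")
})

test_that("annotation matches brute-force translation over a whole gene", {
  ## oracle: translate every alternate codon directly with the vertebrate
  ## mitochondrial code and compare labels position by position
  g <- tinyGenome()
  code <- Biostrings::getGeneticCode("SGC1")
  s <- strsplit(as.character(genomeSequence(g)), "")[[1]]
  for (pos in 4:15) {
    cpos <- (pos - 4) %% 3 + 1
    cstart <- pos - cpos + 1
    refCodon <- s[cstart:(cstart + 2)]
    for (alt in setdiff(c("A", "C", "G", "T"), s[pos])) {
      altCodon <- refCodon; altCodon[cpos] <- alt
      refAA <- code[[paste(refCodon, collapse = "")]]
      altAA <- code[[paste(altCodon, collapse = "")]]
      want <- if (refAA == altAA) "synonymous"
        else if (altAA == "*") "nonsense" else "nonsynonymous"
      got <- annotateEffect(data.frame(position = pos, ref = s[pos],
                                       alt = alt), g)
      expect_identical(got$effect, want)
    }
  }
})

test_that("Grantham distances reproduce published values", {
  ## spot checks against the published distance table (which was rounded,
  ## so reconstruction from the formula can differ by up to ~1 unit)
  expect_lt(abs(granthamDistance("L", "I") - 5), 1.5)
  expect_lt(abs(granthamDistance("W", "R") - 101), 1.5)
  expect_lt(abs(granthamDistance("C", "F") - 205), 1.5)
  expect_equal(granthamDistance("A", "A"), 0)
  sc <- granthamScorer(100)
  expect_identical(sc("C", "F"), "Deleterious")
  expect_identical(sc("L", "I"), "Neutral")
})

test_that("frequency-spectrum tests behave on known inputs", {
  ## identical samples: KS D = 0, p = 1
  x <- c(0.01, 0.02, 0.03, 0.04)
  r <- spectrumTest(x, x, test = "ks")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  ## disjoint supports separate decisively
  set.seed(1)
  a <- runif(50, 0, 0.05); b <- runif(50, 0.05, 0.10)
  expect_lt(spectrumTest(a, b, test = "ks")$p.value, 0.001)
  expect_lt(spectrumTest(a, b, test = "mwu")$p.value, 0.001)
  ## exact two-sided MWU for the extreme ranking of 3 vs 3
  ## oracle: most extreme of choose(6,3) = 20 orderings -> p = 2/20 = 0.1
  r2 <- spectrumTest(c(1, 2, 3), c(4, 5, 6), test = "mwu")
  expect_equal(r2$p.value, 0.1)
  expect_error(spectrumTest(numeric(0), x), "non-empty")
  expect_error(spectrumTest(c(1), c(1, 2), test = "ks"), "at least 2")
})

test_that("chi-square enrichment matches the closed-form 2x2 oracle", {
  ## hand formula: X2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  a <- 20; b <- 123; cc <- 1480; d <- 14000
  N <- a + b + cc + d
  oracle <- N * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  r <- enrichmentTest(hetInBin = a, binLength = a + cc,
                      totalHet = a + b, assayableLength = N)
  expect_equal(r$statistic, oracle, tolerance = 1e-12)
  ## invariance under transposing the table
  tr <- stats::chisq.test(t(r$table), correct = FALSE)$statistic
  expect_equal(r$statistic, unname(tr))
  ## equal densities give a statistic of zero
  r0 <- enrichmentTest(hetInBin = 10, binLength = 100, totalHet = 100,
                       assayableLength = 1000)
  expect_equal(r0$statistic, 0)
  expect_false(r0$enriched)
  ## critical values at df = 1
  expect_equal(stats::qchisq(0.05, 1, lower.tail = FALSE), 3.841,
               tolerance = 1e-3)
  expect_equal(stats::qchisq(0.001, 1, lower.tail = FALSE), 10.828,
               tolerance = 1e-3)
  expect_error(enrichmentTest(0, 0, 10, 100), "zero-length")
})

test_that("private/shared partition and most-recent-sample reduction", {
  calls <- data.frame(
    individual = c("i1", "i1", "i2", "i3", "i2"),
    position = c(100, 200, 200, 300, 400),
    maf = c(0.02, 0.03, 0.4, 0.05, 0.01), stringsAsFactors = FALSE)
  pr <- privateSharedPartition(calls)
  expect_identical(pr$sites$label[pr$sites$position == 200], "shared")
  expect_identical(pr$sites$label[pr$sites$position == 100], "private")
  expect_equal(pr$privateFraction, 3 / 4)
  expect_setequal(pr$mafShared, c(0.03, 0.4))
  ## single individual: everything private
  one <- privateSharedPartition(data.frame(individual = "x",
                                           position = c(1, 2),
                                           maf = c(0.1, 0.2)))
  expect_true(all(one$sites$label == "private"))
  ## most recent sample per individual
  s <- data.frame(sample = c("a", "b", "c"), individual = c("i", "i", "j"),
                  year = c(2014, 2016, 2013), stringsAsFactors = FALSE)
  expect_identical(mostRecentSamples(s)$sample, c("b", "c"))
})

test_that("generator round-trip: spectrum proportions recovered at scale", {
  pp <- populationParams(cohortSizes = c("0" = 74, "1" = 22, "2" = 19,
                                         "3" = 21, "4" = 20, "5" = 3,
                                         "6+" = 8) * 12)
  pop <- simulatePopulation(pp, seed = 31)
  sp <- spectrumSummary(pop$calls)
  expect_gt(nrow(pop$calls), 1500)
  target <- c(0.606, 0.319, 0.075, 0)
  expect_true(all(abs(as.numeric(sp$proportions) - target) < 0.04))
})
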
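---
title: "Models and methods for mitochondrial heteroplasmy analysis"
author: "mitohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mitochondrial heteroplasmy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

# Scope

`mitohet` is a desk-scale pipeline for studying low-frequency point
heteroplasmy — the coexistence of non-identical mitochondrial genomes
within one individual — in deep-sequenced circular mitogenomes. It covers
five connected tasks: simulating pileups with planted variants, calling and
filtering heteroplasmic sites, benchmarking callers, characterising
mutation spectra and coding effects, and modelling how heteroplasmy counts
relate to age and change through time in recaptured individuals. The
package operates at the level of per-site base counts (pileups); read
mapping, base-quality recalibration and duplicate marking are upstream of
its inputs and out of scope. Indel and length heteroplasmy (repeat-array
length variation in the control region) are likewise out of scope: the
control-region repeats are masked, and only point heteroplasmy is analysed.

# The simulation model

## Pileups

Sequencing of one sample is modelled at count level. At every reference
position the depth is Poisson-distributed around the nominal coverage. At a
planted variant site with frequency $f$ the minor-allele read count is
$\mathrm{Binomial}(d, f)$ in the depth $d$; remaining reference-origin reads
are corrupted independently with probability $e$ (the per-base substitution
error rate), the erroneous base uniform over the three non-reference bases.
An *exact mode* removes all stochasticity (depth equals coverage, alt count
equals $\mathrm{round}(f\,d)$), giving the noiseless limit that several tests
rely on.

This replaces read-level simulation deliberately: every downstream metric in
the package consumes only per-site counts, so simulating reads would add
fidelity the metrics cannot see while costing orders of magnitude more time
and storage. The corresponding losses of realism are documented rather than
hidden: no quality strings (hence no base-quality recalibration step — a
fidelity gap relative to full pipelines), no paired-end geometry, no
library-preparation artefacts, and no position-correlated error structure.
Passing tests on this generator therefore demonstrate correctness of the
calling and inference logic, not robustness to alignment artefacts in real
data.

## Truth sets

The benchmark design plants 100 variants at each of five frequencies (1, 4,
7, 10 and 15%), drawn uniformly without replacement *within* each frequency
set. The sets are drawn independently, so one position can occur in two
sets; such positions are excluded entirely — from every set they occur in —
because their truth frequency would be ambiguous. With a 17,211-site
extended reference the expected number of colliding positions is small and
the surviving count lands slightly below 500. Under a uniform collision
model the expected surviving count is $L\,k\,q(1-q)^{k-1}$ with $q = n/L$,
which the test suite checks by Monte Carlo at $L = 500$.

## The synthetic population

`simulatePopulation()` generates the joint structure the inference chain
assumes, with defaults chosen once to emulate a wild, multi-year,
PIT-tagged colony study of a long-lived bat:

* **Cohorts.** 167 unique individuals in age cohorts 0–5 plus an open-ended
  "6+" cohort (74/22/19/21/20/3/8), matching the scale of a primary
  analysis dataset in this kind of study.
* **Counts.** Per-individual heteroplasmy counts are negative binomial,
  $\log \mu = \beta_0 + \beta_1\,\mathrm{age}$ with defaults
  $\beta_0 = -0.0843$, $\beta_1 = 0.0699$ — a weak positive trend of the
  size such studies report before influence diagnostics — and dispersion
  $\theta = 2$, a moderate overdispersion level chosen as realistic for
  count data of mean ~1 (the paperless parameter here is $\theta$; nothing
  in the downstream chain is sensitive to its exact value).
* **Mutation classes.** Calls fall into one transition class
  (G:C↔A:T) and three transversion classes (G:C↔T:A, A:T↔T:A,
  G:C↔C:G) with target marginal proportions 60.6/31.9/7.5/0%. Oxidative
  G:C→T:A "spikes" (4 or more extra oxidative calls, probability 3% per
  sample-year) concentrate the oxidative class in few individuals; because
  spikes are purely oxidative, the generator rescales its baseline class
  draw by the analytically expected spike fraction so the *marginal*
  spectrum stays on target.
* **MAF spectrum.** Minor-allele frequencies follow a shifted exponential
  on (0.01, 0.49] with rate 37.43, placing 77.6% of the mass below 5% —
  the strong low-frequency skew typical of somatic heteroplasmy.
* **Recaptures.** 21 individuals are sampled in consecutive years (3 four
  times, 8 three times, 10 twice). Each site present in one year persists
  to the next with probability 0.15 at unchanged MAF; new sites enter only
  through spikes. This makes the trivial boundary exact (persistence 1 and
  spike probability 0 reproduce call sets identically across years) at the
  cost of a mild downward drift in counts over follow-up years — an
  accepted simplification, since the longitudinal summaries are tested
  against the design parameters, not against a stationarity assumption.

# Calling

## Circularity

The mitogenome is circular; linear callers miss origin-spanning signal. The
standard remedy is implemented exactly: the last `pad` bases (default 500)
are copied in front of the sequence and the first `pad` bases behind it.
Calls made on the extended reference are mapped back by a total, surjective
coordinate map, and duplicate detections of one original site (pad copy and
body) collapse to the higher-depth record.

## The native caller

At every covered site the minor allele — the non-majority base with the
highest count (ties broken in fixed A<C<G<T order) — is tested against the
null that minor observations arise from sequencing error alone: an exact
binomial upper tail for the minor count at per-base null rate
$\tfrac{2}{3}e$, deliberately conservative relative to the simulator's
per-base rate of $e/3$. P-values are Bonferroni-corrected across assayed
sites. Zero-depth sites are skipped; a site with minor count zero is never
called ($P(X \ge 0) = 1$); with $e = 0$ the null is degenerate and any
minor read is significant. MAF is reported as minor count over depth and by
construction never exceeds 0.5 (the minor-allele convention: a planted
variant at frequency 0.9 is called as a reference-allele heteroplasmy at
0.1).

The caller is intentionally a clean, transparent baseline: the benchmarking
framework needs a caller to score, and any alternative — including wrappers
around external binaries — plugs in as a one-function interface
(`function(pileup) -> calls`).

## Filters

Empirical-sample retention uses strict inequalities, following the usual
phrasing of such thresholds ("greater than 1%", "greater than 1000X"): MAF
> 0.01, depth > 1000, and position outside primer-binding and repeat masks.
Each dropped call is tagged with the first failing filter in the fixed
order MAF, coverage, mask, which makes filter composition
order-independent.

# Benchmarking metrics

For a truth set of $T$ sites among $A$ assayable sites:

* power $=$ called true sites $/\ T$;
* accuracy $=$ called true sites whose reported frequency is within
  $\pm 0.01$ (absolute, inclusive) of truth $/$ called true sites, defined
  as 0 when nothing true is called;
* FPR $=$ called non-true sites $/\ (A - T)$;
* score $= (\mathrm{power} \times \mathrm{accuracy}) \times
  (1 - \mathrm{FPR})$.

Two denominators are genuinely ambiguous in the usual verbal definitions,
so both readings are implemented behind switches with the defaults above:
accuracy may instead divide by all true sites
(`accuracyDenominator = "all"`), and FPR may instead be the fraction of
calls that are false, i.e. $1 - \mathrm{precision}$
(`fprDenominator = "calls"`). The defaults were chosen so that power,
accuracy and FPR measure three distinct failure modes. The score is
monotone in each argument, 1 for a perfect caller on noiseless data and 0
for the empty caller; power and FPR are exact counts divided by known
denominators, so the underlying integers are always recoverable.

# Quality control

Two sample-level filters run before analysis. The duplicate-concordance
test runs detection with PCR duplicates retained and removed and examines
the per-sample absolute count difference: differences beyond 2 interquartile
ranges outside the quartiles are screened out (quartiles by linear
interpolation, the common convention — configurable, since conventions
differ); the cutoff is $\lfloor \bar{x} + 2s \rfloor$ of the retained
differences (sample standard deviation); samples whose difference exceeds
the cutoff are unreliable. The absolute difference is used because the rule
thresholds disagreement in either direction; only the upper fence matters
in practice since differences are non-negative, and the symmetric lower
cutoff is not applied. The coverage filter removes samples with mean depth
below 1000X (exactly 1000X is retained), the level below which callers
lose substantial power in the package's own benchmarks.

# Characterisation

Substitutions are classed strand-symmetrically into G:C↔A:T transitions
and the G:C↔T:A (oxidative, the 8-oxo-guanine signature), A:T↔T:A and
G:C↔C:G transversions; the four classes partition all 12 ordered
substitutions. Ts/Tv is transitions over all transversions, reported as
`NA` when no transversion exists.

Coding effects are annotated under the **vertebrate mitochondrial genetic
code** (translation table 2, where TGA is tryptophan and AGA/AGG are
stops); the organism class forces this choice. Codon and codon position
come from each protein feature's strand and frame offset; minus-strand
genes are handled on the reverse complement. A position inside two
overlapping protein genes yields one record per gene.

Deleteriousness of missense changes is a pluggable scorer. The default
stand-in scores the Grantham (physicochemical) distance, computed from the
original composition/polarity/volume formula, with changes above 100 — the
conventional boundary for "radical" substitutions — labelled Deleterious.
This is explicitly *not* equivalent to alignment-based scorers such as
PROVEAN, which require homolog databases; treat the labels as a screening
annotation, not as reproducing any published Deleterious/Neutral counts.

Spectrum comparisons use two-sided Kolmogorov–Smirnov or Mann–Whitney U
tests (exact where the implementation provides it). Regional enrichment
uses Pearson's chi-square on the 2×2 {heteroplasmic, homoplasmic} × {in
bin, out of bin} table over the assayable genome, without continuity
correction by default (configurable), flagged at caller-supplied critical
values (3.841 for p<0.05, 10.828 for p<0.001 at df 1) together with a
direction check that the bin's density actually exceeds the genome-wide
density. No multiple-testing correction is applied across the test battery;
the tests are descriptive screens, not a confirmatory family.

# Inference

## The age model

Heteroplasmy count on age is fitted as a negative binomial GLM with log
link (NB2 variance $\mu + \mu^2/\theta$), the standard treatment for
overdispersed counts where Poisson regression understates uncertainty. The
open-ended oldest cohort label ("6+") is coded as its lower bound 6, and
samples of unusable age are dropped. On equidispersed data the $\theta$
iteration cannot converge; the fit then falls back to Poisson regression
($\theta = \infty$, the NB's limit) with a flag instead of an exception.
AICc is AIC $+\,2k(k+1)/(n-k-1)$ with $k = 3$ (two coefficients plus
dispersion).

A batch-random-effect mixed model is deliberately not included: with batch
variance estimated at zero such a model is degenerate and collapses to the
plain GLM, so the package provides the Kruskal–Wallis batch check (with the
maximum pairwise batch-mean difference as an effect-size guard) alongside
the GLM instead.

## Influence, bootstrap, permutation

Cook's distance (leverage/Pearson-residual form) is reported per
observation. GLMs have no universally agreed threshold, so observations
above $8/(n - 2k)$ are flagged *and* the top-m list is returned; removal is
an explicit user action, mirroring how influence removal should be an
inspectable analysis step rather than an automatic one.

The bootstrap defaults to case resampling (rows of (count, age) resampled
with replacement, B = 1000), which makes no distributional assumption
beyond the sampling design; a parametric variant (counts simulated from the
fitted NB) is available behind a flag since both styles are current in this
literature and neither is privileged here. Non-converging replicates are
dropped and counted.

The recapture permutation quantifies the arbitrariness of "take the most
recent sample" for recaptured individuals: per replicate one sample per
recaptured individual is drawn uniformly, the model refit, and the slope
and its Wald p < 0.05 indicator recorded (no influence removal inside
replicates). Reported: fraction significant, mean and range of slopes.

## Longitudinal summaries

Per consecutive-year interval the signed count change is classed
increase/decrease/no change; non-consecutive intervals are excluded from
these statistics (individuals sampled in non-adjacent years contribute no
interval, but still contribute to sharing). The signed changes telescope:
their sum per individual equals last count minus first. Site sharing counts
distinct (individual, position, minor allele) heteroplasmies observed at
≥2 of the individual's time-points, and at all of them; the
site-by-individual denominator was chosen over counting raw call records
because it asks the biological question (does *this* heteroplasmy persist
in *this* bat?) rather than a bookkeeping one — the record-based
alternative is a one-line change and is documented here for transparency.

# Numerical choices and degenerate inputs

* Seeds: every stochastic entry point takes a `seed` and restores the
  caller's RNG stream; identical seeds give byte-identical outputs.
* Minor-allele ties at exactly 0.5 are reported at MAF 0.5; base-identity
  ties break in fixed A<C<G<T order.
* Strict vs non-strict boundaries: call filters are strict (>); the
  coverage QC filter removes only samples strictly below threshold; the
  accuracy tolerance ±0.01 is inclusive; the concordance cutoff flags only
  differences strictly above it.
* Zero-depth sites are never assayed; empty call sets evaluate to power 0,
  FPR 0, accuracy 0 without division by zero; an empty truth set is an
  error, not a zero.
* Chi-square requires a non-degenerate 2×2 (positive bin length, bin
  smaller than the assayable genome).

# Problem sizes

The shipped tests and the reproduction script run entirely on synthetic
data sized for a single CPU: the benchmark grid uses the full 9-coverage
design on the 17,211-site extended reference; generator calibration uses
~10,000 calls (cohort design scaled 45×); collision-model checks use
10,000 seeds at 500 sites; bootstrap and permutation use their default
B = 1000 at the 167-individual study scale.

# Known limitations

* Count-level simulation cannot expose mapping, recalibration or
  strand-bias artefacts; results on real data additionally depend on those
  upstream steps.
* The native caller assumes a single scalar error rate per sample; real
  error rates vary by position, cycle and context.
* The Grantham stand-in scorer is not PROVEAN and should not be compared
  against published deleteriousness counts.
* The generator's recapture dynamics add new sites only via oxidative
  spikes; it is a tool for validating the longitudinal summaries, not a
  mechanistic model of heteroplasmy turnover.
* Ts/Tv from class proportions equals $p_{ts}/(1-p_{ts})$; with the default
  60.6% transition target this is ≈1.54. Published Ts/Tv figures sometimes
  use other denominators, so cross-study comparison of this ratio needs
  care.
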
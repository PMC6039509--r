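---
title: "Models and methods behind ednariver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ednariver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednariver)
```

`ednariver` analyses river-scale fish eDNA metabarcoding surveys: it
standardizes read counts, models PCR detection probability, compares the
eDNA description of local assemblages against capture surveys, quantifies
longitudinal spatial structure, and predicts how far downstream an eDNA
signal remains detectable. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## Read standardization

Total read counts differ between sites for technical reasons (library
size), so raw counts are not comparable. `rarefy_reads()` subsamples each
site's reads **without replacement** to a common depth — an exact
multivariate hypergeometric draw, implemented by sequential conditional
hypergeometric sampling, not the multinomial approximation. Sampling
without replacement is the correct model for drawing reads out of a
finite sequenced pool; it conserves site totals exactly and cannot
inflate any count. The default depth is the smallest site total (the
deepest depth every site can support); an explicit depth overrides it. A
seed is mandatory: the reproducibility contract is *same seed, same
build, identical output*.

`filter_taxa()` applies the upstream filtering policy: an exclusion list
for implausible detections (taxa whose DNA plausibly enters the river
with effluents rather than from resident fish), and a copy-number floor —
a MOTU must reach `min_reads` reads at one site at least. The floor
defaults to 10 copies; it is a config parameter with no single canonical
value, and sensitivity to it should be checked on any real dataset.

## Detection-probability model

The probability that one PCR replicate amplifies a MOTU is modelled as
logistic in the natural log of its standardized read count,

$$\operatorname{logit}(p) = a + b\,\ln(\text{reads}),$$

fitted by `fit_detection_glm()` as a grouped binomial GLM — the response
is (k positives, R − k negatives) per site-and-MOTU record, so deviances
follow grouped-binomial conventions. Natural log is used throughout.
Records with zero standardized reads have no defined covariate and are
excluded, with the count of excluded positive-PCR records reported (such
cells can occur because reads derive from sequencing pooled PCR
products). Convergence follows the IRLS contract: relative deviance
change below 1e-8 or 100 iterations; perfect separation produces a
message, not a failure, and coefficients are still returned.

Four nested forms are available: one pooled curve; per-MOTU intercepts
(`identity`); per-MOTU intercepts and slopes in one model
(`identity_interaction`); and fully separate per-MOTU fits.
`deviance_partition()` reports how much total deviance each added term
explains, with likelihood-ratio chi-square tests. MOTUs enter the model
only if observed widely enough to anchor a curve
(`select_modelable_motus()`: present in more than 10 sites, positive-PCR
counts spanning 3 to 23 of 24 by default).

`invert_abundance_at_rate()` solves the fitted curve for the read count
at a target detection rate and divides by the rarefaction depth; this is
the package's route from a detection rate to a relative abundance. The
inversion requires a positive slope and is exact:
`predict(invert(r)) = r` to numerical precision.

## Assemblage comparison

Diversity indices go through vegan: richness S, Shannon
$H = -\sum p_i \ln p_i$, and Pielou evenness $J = H/\ln S$ (natural log
consistently; J is undefined at S = 1 and reported missing).

Paired eDNA/capture locations are chosen by `pair_sites()`: within each
river section, the least distant pair sharing a reach type (main channel,
bypass, deltaic arm), ties broken by site id. Distances are measured
along the river axis.

For richness, two tests with different nulls: per location, a one-sample
Wilcoxon signed-rank of the annual capture richness values against the
single eDNA richness (the test is unnamed in the field's reports; a
signed-rank against the paired constant is the natural nonparametric
choice, run one-sided by default because the documented hypothesis is
directional — captures find fewer species per pass); across locations, a
paired Wilcoxon of cumulative (all-years) capture richness against eDNA
richness, which is the fair comparison of total species lists.

Per-species abundance bias uses an exact binomial sign test on the
per-location sign of (eDNA proportion − catch proportion), Bonferroni
corrected over the species actually tested (those present in at least 6
paired locations), not the full species pool. CPUE is catch/effort per
year, averaged across years before correlation; capture sites are first
screened by `richness_trend_glm()` (Poisson GLM of annual richness on
year) so that only trend-free sites are pooled across years.

## Multivariate coupling

`centered_pca()` is a plain column-centered PCA with uniform row weights
1/n; eigenvalue k is (singular value k)²/n so the eigenvalues sum to the
total inertia. Count tables are log(x+1)-transformed first
(`log1p_abundance()`); the offset of 1 is the conventional choice that
admits zeros and is recorded here as configuration.

`coinertia()` couples the two 2-axis PCA score matrices: the co-inertia
axes are the singular vectors of their uniform-weight cross-covariance,
maximizing the covariance of the projected section coordinates, and the
RV coefficient
$\mathrm{RV} = \operatorname{tr}(C_{xy}C_{yx}) / \sqrt{\operatorname{tr}(C_{xx}^2)\operatorname{tr}(C_{yy}^2)}$
summarizes the global coupling. The analysis is run on the PC score
matrices, following the pipeline's definition of the coupled objects; a
rank-2 reconstruction variant was considered and not retained — with
uniform weights the two differ only by rotation of the discarded
complement, and scores are what downstream identity-line diagnostics
need. `rv_permutation_test()` permutes the section rows of one score
matrix; sampled p-values follow the (1 + exceedances)/(1 + n) convention
and an exhaustive mode enumerates all row orders for small n.
`identity_regression()` regresses one table's co-inertia scores on the
other's and tests the slope against 1 and the intercept against 0 (both
raw values are reported, so either pairing of the "slope and intercept
did not differ from…" phrasing can be inspected); exact zero-residual
fits are reported as exact identity rather than through degenerate
t statistics.

## Spatial structure

Community dissimilarity is Bray–Curtis (via `vegan::vegdist`) on
relative abundances by default (a log(x+1) alternative is a matter of
passing a transformed matrix). Site separation is |Δ kilometre point|
along the channel, not Euclidean distance — sampling follows the river.

`mantel_test()` correlates upper triangles and permutes rows/columns of
one matrix, one-tailed for r at least as large as observed. It is
implemented in-package (vegan's implementation is used as a
cross-check in the test suite) because the package contract includes
exact exhaustive enumeration at small n and a fixed seeded p-value
convention. `mantel_correlogram()` computes a per-class Mantel statistic
against the class-membership indicator, sign-flipped so positive values
mean within-class similarity; p-values are corrected progressively (Holm
over classes tested so far), and the autocorrelation extent is the upper
edge of the last class in the initial run of significant positive
classes. Class width and count are fully configurable (10-km classes by
default); empty classes report missing statistics and are skipped by the
correction.

## Transport model

eDNA in the water column is assumed to behave like fine particulate
organic matter: it settles with a deposition velocity $V_{dep}$ related
to the e-folding transport length $S_p$ by $V_{dep} = u\,h/S_p$. Under a
rectangular channel cross-section $u\,h = Q/w$, so
$S_p = (Q/w)/V_{dep}$ — discharge and wetted width are enough. Over one
$S_p$, 63.2% of suspended particles deposit ($1 - e^{-1}$). An upstream
release of $N_0$ copies (default 2000 copies/L × 2.5 L sampled) stays at
or above a one-copy detection threshold to
$x^* = S_p \ln(N_0/\text{threshold})$.

`vdep_summary()` summarizes literature deposition velocities by median
and interquartile range (linear-interpolation quantiles);
`predict_detection_table()` evaluates $x^*$ per reach at the median and
both quartiles — note the inversion: the *upper* quartile of $V_{dep}$
(fast settling) gives the *lower* distance bound. Printed hydraulic
inputs are used as printed, never "corrected", even where back-computed
values suggest rounding. Degradation of eDNA during transport is
deliberately omitted (a `decay_rate` hook exists and defaults to zero),
which makes the predicted distances conservative in the upstream
direction.

The empirical counterpart is `fit_distance_decay()` — a binomial-logit
GLM of detection rate on downstream distance from a known source — and
`distance_at_rate()`, which inverts the mean curve at a threshold rate
(default 4%, i.e. less than one positive in 24 replicates). The
uncertainty band inverts the mean ± 1 SE prediction curves; a delta
method band on the crossing distance would also be defensible, but
inverting the prediction envelope is reported because it is the band a
reader of the fitted curve sees.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, as pure
functions of a scenario and seed:

* `true_assemblage()` — Gaussian species-response curves along the river
  (the simplest mechanism producing gradual species turnover and an
  upstream–downstream first PCA axis);
* `apply_transport()` — first-order decayed upstream contributions with
  mixing length `sp_km`, renormalized (the mechanism by which downstream
  samples integrate upstream communities);
* `simulate_reads()` — multinomial reads at site depths drawn uniformly
  from a range whose default minimum, 163,121 reads, matches the
  standardized-depth regime of a real river campaign;
* `simulate_pcr()` — binomial PCR detections conditioned on *realized*
  reads (matching the covariate the detection GLM fits), default curve
  a = −6.0, b = 1.2 per ln(read), R = 24 replicates;
* `simulate_catches()` — negative-binomial catches (size 5 by default:
  electrofishing counts are strongly overdispersed) with per-species
  catchability multipliers emulating bank-biased sampling.

Defaults describe a 500-km river, 40 sites, 40 species, 10 annual capture
surveys at effort 400. What the generators do **not** emulate: sequencing
error, tag jumping or contamination, seasonal movement, species
interactions, tributary inputs, or eDNA degradation. Passing tests
therefore demonstrate the statistical machinery is correct under the
stated data-generating assumptions — not that real rivers satisfy those
assumptions.

## Numerical choices and degenerate inputs

* GLM convergence: deviance tolerance 1e-8, 100 iterations; separation
  returns coefficients with a message.
* Rarefaction depth above a site total is an error naming the site; a
  zero-total site is an error for relative abundances.
* Constant matrices: PCA returns zero eigenvalues and scores; Mantel and
  Spearman statistics on constant inputs are reported missing, not
  invented.
* Permutation p-values never reach zero: sampled tests use
  (1 + exceedances)/(1 + n), exhaustive tests include the identity order.
* Exhaustive enumeration is limited to 8 sites/sections (8! orders).
* Seeds are explicit arguments everywhere randomness exists; pipeline
  stages derive their seeds from the master seed by fixed offsets.

## Problem sizes

The test suite and examples run at deliberately small scale — tens of
sites and species, sequencing depths of 10^4, 99–999 permutations, 100
replicate fits in the recovery checks — chosen so the full suite
completes in minutes while keeping every statistical check comfortably
powered. All sizes scale up through the scenario and function arguments.

## Known limitations

* The transport model is a single-reach, rectangular-channel, constant
  `V_dep` approximation; it does not route flow through confluences or
  model resuspension.
* The detection model is a plain binomial GLM, not a hierarchical
  site-occupancy model; replicate-level heterogeneity beyond the read
  covariate is not modelled.
* Co-inertia is the two-table PCA-based form only.
* The sign and signed-rank tests assume exchangeable locations; spatial
  autocorrelation between paired locations is not accounted for in those
  tests (it is the object of the correlogram module instead).
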
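# ednariver

Quantitative analysis of river-scale eDNA metabarcoding fish surveys.

Environmental DNA (eDNA) metabarcoding identifies the fish assemblage of a
river reach from the DNA suspended in a few litres of filtered water. Two
questions decide whether such surveys can replace or complement capture
surveys (electrofishing) for monitoring: **can sequencing read counts be
read as relative species abundance**, and **over what distance does the
water sample integrate the upstream community**, given that eDNA is
advected downstream like fine particulate organic matter (FPOM)?

`ednariver` implements the full analysis pipeline for this class of study,
for ecologists and biomonitoring practitioners working from site-by-MOTU
read tables and long-term capture records:

* **Read standardization** — exact multivariate hypergeometric rarefaction
  of every site to a common depth, so counts compare as proportions.
* **Detection-probability model** — grouped binomial GLM
  `logit(p) = a + b·ln(reads)` of the PCR detection rate (k positives of R
  replicates) on log standardized reads, with deviance partitioning over
  MOTU identity and its interaction, and inversion
  `reads* = exp((logit(r) − a)/b)` giving the relative abundance at any
  target detection rate r.
* **Assemblage comparison** — richness, Shannon H, Pielou evenness;
  Wilcoxon signed-rank comparisons of paired eDNA and capture richness;
  exact sign tests (Bonferroni-corrected) for systematic per-species
  abundance bias; Spearman read–catch correlations per site.
* **Multivariate coupling** — centered PCA, co-inertia analysis of the
  eDNA and capture ordinations, RV coefficient with seeded (or exhaustive)
  permutation test, identity-line regression of paired section scores.
* **Spatial structure** — Bray–Curtis dissimilarity, Mantel tests, and
  distance-class Mantel correlograms with progressive Holm correction,
  yielding the longitudinal extent of assemblage autocorrelation.
* **Transport model** — the FPOM deposition-velocity model
  `V_dep = u·h / Sp`: with a rectangular channel (`u·h = Q/w`), the
  e-folding transport length is `Sp = (Q/w)/V_dep`, and an upstream
  release of `N0` DNA copies stays detectable (≥ 1 copy in the sample) to
  `x* = Sp · ln(N0)` downstream.
* **Synthetic data** — seeded generators (Gaussian niche gradient,
  multinomial reads, logit-linear PCR detections, negative-binomial
  catches with catchability bias, first-order downstream mixing) producing
  every input the pipeline consumes, so all stages are testable offline.

All user-facing functions take a data frame first and return tibbles;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a 30-site survey along 500 km, standardize it, fit and invert the
detection model, and predict detection distances for two channels:

```r
library(ednariver)

sc  <- synthetic_scenario(n_sites = 30, n_species = 30, seed = 42)
tbl <- simulate_survey(sc) |> rarefy_reads(seed = 1)

recs <- detection_records(tbl, select_modelable_motus(tbl))
fit  <- fit_detection_glm(recs, "pooled")
fit
#> Binomial-logit detection model (pooled)
#>   records: 611   MOTUs: 24
#>   null deviance: 11198.58   residual: 645.71   explained: 94.2%

invert_abundance_at_rate(fit, c(0.05, 0.5, 0.95), depth = 163121)
#> # A tibble: 3 × 4
#>   motu    target_rate  reads rel_abundance
#> 1 .pooled        0.05   7.57     0.0000464
#> 2 .pooled        0.5   83.9      0.000514
#> 3 .pooled        0.95 930.       0.00570
```

A MOTU reaches a 50% detection rate (12 of 24 PCR replicates) at about 84
standardized reads, i.e. a relative abundance of 0.05% at this generator's
settings; the 5% and 95% rates bracket the abundance range over which a
species moves from barely detectable to near-certain detection.

```r
v <- vdep_summary(c(0.08, 0.08, 0.18, 0.43, 0.43))  # mm/s, literature FPOM
predict_detection_table(
  tibble::tibble(label = c("large river", "small stream"),
                 discharge_q = c(436, 0.170),       # m3/s
                 wetted_width_w = c(132, 1.80)), v) # m
#> # A tibble: 2 × 8
#>   label        discharge_q wetted_width_w   sp_m predicted_km lower_km upper_km
#> 1 large river       436             132   18350.       156.      65.4     352.
#> 2 small stream        0.17            1.8   525.         4.47     1.87     10.1
```

At the median deposition velocity (0.18 mm/s) a large lowland river
transports detectable eDNA on the order of 150 km downstream, a small
stream only a few km: the spatial integration of an eDNA sample is set by
channel hydraulics. `run_pipeline()` chains all stages from a single
(YAML) configuration and writes per-stage tables plus a JSON summary that
is byte-identical across reruns with the same seed.

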
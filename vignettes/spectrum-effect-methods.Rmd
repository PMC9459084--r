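---
title: "Methods: spectrum-effect modelling of hepatotoxic components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectrum-effect modelling of hepatotoxic components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmtox)
```

## The problem

*Polygonum multiflorum* (PM) is an herbal medicine whose hepatotoxicity is
reduced by processing (steaming). Which of its hundreds of constituents
drive the toxicity is unknown; single-compound assays miss synergistic
effects and most constituents lack reference standards. The spectrum-effect
strategy implemented here sidesteps isolation: quantify a panel of
candidate compounds semiquantitatively (scheduled-MRM peak areas) across
many batches, measure each batch's cytotoxicity (IC50 on L02 and HepG2
hepatocytes), and let several independent statistical engines decide which
compounds' abundance profiles track potency across batches. A compound
flagged by *every* engine in *both* cell lines is called a toxicity marker.

The pipeline has four stages, each usable on its own:

1. **Differential screening** (`screen_feature_matrix()`): untargeted
   intensities for raw vs processed batches; features reduced by processing
   are candidate toxins (toxicity falls with processing).
2. **Dose-response** (`fit_four_pl()`, `plates_to_toxicity()`): plate
   optical densities to inhibition ratios to per-batch IC50.
3. **Three engines** (`relational_degree()`, `fit_opls()`,
   `train_bpann()`): each relates the batch x compound peak-area table to
   the IC50 (or 1/IC50) series and selects compounds.
4. **Consensus** (`across_model_intersection()`): intersection within each
   engine across cell lines, then across engines.

## Differential screening

Intensities are total-intensity normalized (each sample scaled to the
cohort-median total) and unit-variance scaled before multivariate
modelling. The screen combines three criteria, all strict inequalities:

* **VIP > 1.5** from an OPLS-DA model (binary raw/processed response,
  one predictive plus automatically chosen orthogonal components). VIP is
  computed on the predictive component only and normalized so
  mean(VIP^2) = 1.
* **p < 0.05** from a two-sided Welch t-test per feature, QC samples
  excluded. The test runs on normalized (not log) intensities by default; a
  log option exists because neither choice is canonical for peak areas.
* **FC < 0.5**, where FC is the processed/raw ratio of group means —
  the screen looks specifically for components *reduced* by processing.

No multiplicity correction is applied: the cascade's conjunction with the
fold-change condition already controls false discoveries tightly in the
regimes the generator emulates (a null feature must jointly reach VIP,
p and a halved group mean).

## Dose-response model

Inhibition is anchored by plate controls:
`inhibition % = 100 (OD_S - OD_NC) / (OD_STSP - OD_NC)`, with the vehicle
control defining 0% and the staurosporine kill control 100%. Each
replicate's 7-point curve (0.064–1000 ug/ml) is fitted with a
variable-slope four-parameter logistic on log concentration,

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + (\mathrm{IC}_{50}/c)^{h}},$$

by Levenberg–Marquardt least squares over a grid of starts (hill in
{0.5, 1, 2}; IC50 seeded from the concentration bracketing the
half-maximal response and at the grid median; asymptotes seeded from the
data range and at the nominal 0/100). The multi-start grid exists because
single starting points occasionally produce a numerically singular
Jacobian even on clean curves. The reported IC50 is the *relative* one
(midpoint between fitted asymptotes). Fits whose IC50 exceeds the top
tested concentration are *flagged censored but kept* — batch means beyond
1000 ug/ml are meaningful for weakly toxic processed batches, and the flag
keeps the extrapolation visible. Plates with no measurable response
anywhere (range < 10 points and maximum < 50%) are reported as censored at
ten times the censor limit rather than fitted, because the midpoint of a
flat curve is unidentifiable. Replicates are summarized by the arithmetic
mean; any censored replicate censors the mean.

## The three engines

**Gray relational analysis.** Series are made dimensionless (default:
divide by the series mean, which preserves profile shape for strictly
positive data) and compared with the 1/IC50 reference series through
Deng's coefficient with resolution coefficient rho = 0.5, the universal
convention. The extrema entering the coefficient are *global* (over all
compounds and batches). If every deviation is zero the coefficients are
defined as 1. The relational degree is the mean coefficient; compounds
with degree > 0.6 are retained. GRA degrees compress toward the top of
(0, 1], so on the reference cohort this threshold retains all 16
compounds — GRA acts as a guard in the consensus rather than a pruner,
which is exactly its role in the reference analysis.

**OPLS.** A single-response orthogonal-projections model: orthogonal
components (X variation uncorrelated with y) are peeled off by the
standard OSC step, then one predictive component is fitted. For a single
response the predictive weight is closed-form (proportional to X'y), so
no iteration is needed. With IC50 as the response, toxic compounds show
*negative* standardized coefficients; a compound is selected when
VIP > 0.7 and coefficient < -0.1. Q2 uses 7-fold venetian-blind
(interleaved, deterministic) cross-validation. The orthogonal-component
count defaults to `"auto"`: the count in 0..5 maximizing Q2. Permutation
validation refits on randomly permuted responses; the verdict is "no
overfitting" when every permuted Q2 falls below the original *and* the
intercept of the permuted-Q2 vs |correlation| regression is at most 0.05
(the usual permutation-plot criterion). The permuted models reuse the
component count resolved on the unpermuted data, mirroring the fitted
model's complexity — resolving it per permutation would let permuted
models cherry-pick, and forcing zero components penalizes genuine signal
that needs the extra components.

**BP-ANN.** A 16-10-1 feedforward network (sigmoid hidden layer, linear
output) maps min-max scaled peak areas to the min-max scaled IC50. We fit
it with `nnet` (BFGS with weight decay 1e-3) rather than hand-rolled
gradient descent: the selection contract depends on fit quality and
reproducibility, not on the optimizer, and decay plays the stabilizing
role early stopping otherwise would. Training uses a random 80/20
train/validation split and 5 random restarts under one master seed,
keeping the restart with the best validation MSE; restarts matter because
the loss is non-convex and sensitivity *signs* are the downstream product.
Two sensitivity measures follow:

* **Garson percentages**: per hidden unit, absolute input weights are
  normalized to shares, weighted by the absolute output weight, summed and
  normalized to 100% across inputs. Hidden units with all-zero incoming
  weights are skipped.
* **Mean impact value (MIV)**: each (scaled) input column is perturbed by
  +/-10% and the MIV is the mean prediction difference, in response units.
  Compounds with MIV < 0 against IC50 (more abundance, less viability) are
  selected. The 10% delta is the convention of the MIV literature.

## Consensus

Selections are intersected within each engine across the two cell lines
first, then across engines — deliberately in that order, matching how the
reference analysis reports its common sets. Empty sets warn but do not
abort. Markers are ranked by mean rank over the available evidence columns
(GRA degree, |coefficient| x VIP, |MIV|), ties broken by panel order.

## What the synthetic cohort emulates

`cohort_spec()` defaults encode the study conditions: 30 raw + 20
processed batches, 16 compounds, markers planted at X6/X7/X14. Abundances
are log-normal with 40% geometric CV (peak areas are positive and
right-skewed); processed batches are scaled by compound-specific reduction
factors drawn from the published fold-change range [0.137, 0.441] for the
planted compounds and 1 for the rest. Potency follows
`1/IC50 = baseline + sum(beta_j area_j)`, with the baseline at 1/3500
(ug/ml)^-1 and the betas calibrated so the raw-group *mean potency*
corresponds to 250 ug/ml, split equally across markers; HepG2 potency is
scaled by 0.89 (the published raw-group means, 250 vs 281 ug/ml). Note
the calibration is on the potency scale, so the cohort's mean *IC50*
exceeds 250 by Jensen's inequality — matching how potencies, not IC50s,
add. Assay noise is multiplicative on potency with a 10% CV: a
coefficient of variation is the natural error model for a dilution-series
readout, and additive constant-variance noise would occasionally drive a
weak batch's potency to zero and its IC50 to absurd values no plate assay
would report. Truncation keeps potency above 1e-6.

Under these defaults the planted compounds explain well over half the
potency variance (asserted in the test suite), which is the regime where
the recovery guarantees below are claimed.

The generator deliberately omits: retention-time drift and peak-shape
effects, batch-to-origin structure, censoring at the assay level (plates
are simulated separately), correlated compound families, and any
matrix-effect nonlinearity between abundance and peak area. Passing
recovery tests therefore show the *engines and plumbing* work under the
assumed statistical structure, not that the biology of any real cohort
satisfies that structure.

By default only planted markers receive a reduction factor. If all 16
compounds are reduced by processing (as in the real cohort), the group
contrast confounds every compound with toxicity and within-group
variation must do the discriminating — users can emulate that with an
explicit `reduction_factors` vector, at the cost of recovery rate.

## Problem sizes and tolerances in the test suite

The acceptance-style tests run: OPLS vs a NIPALS PLS oracle on 20 random
30 x 10 datasets (1e-8); GRA vs a direct-formula oracle on random 8 x 5
systems (1e-12); 100 random Garson networks (sum to 100 +/- 1e-6); 100
noisy plates at 2% OD noise (median IC50 error < 10%); 50 seeded
end-to-end cohorts (consensus = planted set in >= 90%); 50 seeded
screening matrices with 200 features / 20 planted (mean sensitivity >=
0.9, mean FDP <= 0.1); and 2 x 50 permutation runs with 200 permutations
each (signal verdict pass >= 95%, noise verdict fail >= 80%). These sizes
keep the full suite under a couple of minutes on one core while leaving
the Monte-Carlo rates far from their thresholds in routine runs.

## Known limitations

* The published cohort's per-batch IC50s and feature matrices are not
  public, so the package reproduces the *selection arithmetic* on the
  published per-compound score tables and validates the engines on
  synthetic cohorts; it cannot re-derive the published model statistics
  (e.g. R2X/R2Y/Q2 of the cohort OPLS models) from raw data.
* The OPLS "R value" in the published tables is treated as a standardized
  regression coefficient; the text is ambiguous between coefficient and
  Pearson correlation, and both readings reproduce the published
  selections, but numeric reproduction of that column is not attempted.
* The BP-ANN's selection (sign of MIV) is stable under the default effect
  sizes but remains the noisiest engine; with plate-level noise on top of
  potency noise it misses weak markers more often than OPLS (the analysis
  workflow shows both conditions side by side).
* Group comparison offers Welch and Mann-Whitney tests; with censored
  processed-group IC50s both are approximations, as censoring is carried
  as a flag rather than modelled.
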
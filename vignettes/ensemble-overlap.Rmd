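---
title: "Quantifying neuronal ensemble overlap from Arc catFISH compartment counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal ensemble overlap from Arc catFISH compartment counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catfishr)
```

## The measurement

catFISH (cellular compartment analysis of temporal activity by fluorescence
in situ hybridization) exploits the kinetics of the immediate-early gene
*Arc*: transcription foci appear in the nucleus within minutes of neuronal
activity, and the mRNA moves to the cytoplasm within about 20 minutes. After
two behavioral epochs separated by 20 minutes, the compartment holding the
*Arc* signal therefore timestamps each neuron's activity. Scoring a field of
CA1 pyramidal neurons yields a four-category tally per animal:

* `alpha` — no signal (silent in both epochs),
* `beta` — nuclear foci only (active in epoch 2 only),
* `gamma` — cytoplasmic signal only (active in epoch 1 only),
* `delta` — both compartments (active in both epochs, i.e. reactivated).

This package starts at those tallies. Image acquisition and the manual
nucleus/cytoplasm classification are upstream and out of scope, as is any
glial/neuronal discrimination: inputs are presumed-neuron counts. Tallies may
be raw counts or per-100 percentages — every derived quantity below is
invariant under uniform rescaling, and nothing is ever rounded internally.

## The similarity score

With $n = \alpha+\beta+\gamma+\delta$, the two epoch activation fractions are

$$E_1 = \frac{\gamma+\delta}{n}, \qquad E_2 = \frac{\beta+\delta}{n}.$$

If the two active ensembles were statistically independent the expected
double-positive fraction would be $p(E_1E_2) = E_1 E_2$; the observed excess
is $pO(E_1E_2) = \delta/n - E_1E_2$. The most overlap geometrically possible
is the smaller ("least") of the two active fractions, so the normalized score

$$S \;=\; \frac{\delta/n - E_1E_2}{\min(E_1,E_2) - E_1E_2}$$

equals 1 when one ensemble is nested in the other (perfect A/A reactivation)
and 0 under exact independence (a perfect A/B design). `similarity_components()`
returns all six quantities; `per_animal_scores()` maps them over a cohort.

Numerical choices:

* The score is **undefined** when the denominator
  $\min(E_1,E_2) - E_1E_2 \le 10^{-12}$ — e.g. caged controls with no epoch-1
  signal. Such tallies return a flagged `NA` with a reason string rather than
  an error, and group summaries exclude them with a logged count; they are
  never imputed.
* Negative scores (anti-correlated ensembles) are returned unclipped: the
  formula admits them and clipping would hide anti-correlation.
* Whenever defined, $S \le 1$, with equality exactly when
  $\delta/n = \min(E_1, E_2)$.

Per-animal scores are the default reporting unit; `pooled_counts()` offers the
neuron-weighted alternative explicitly. The two differ whenever animals vary:
the package's built-in table of published group-mean percentages gives a
pooled-mean score of about 0.80 for wild-type mice in the two-exploration
paradigm, while the published group score (0.88) is evidently a mean of
per-animal scores, whose inputs were never published. `pooled_reference_scores()`
reports both side by side and asserts nothing about their equality. Likewise
it is unstated whether published group percentages are animal-weighted or
neuron-weighted; the package treats them as animal-weighted means, matching
mean-plus-SEM reporting.

```{r}
wt <- reference_counts("WT", "A20A")
similarity_components(wt)
```

## The generative model

The simulator gives the analysis a ground truth. Each neuron is activated
independently in epoch 1 with probability $a_1$ (the ensemble **sparsity**),
and in epoch 2 with probability $r$ (**reactivation fidelity**) if it was
active in epoch 1, else $b$ (**recruitment**). Caged controls transcribe at a
baseline rate $f_0$. The category probabilities follow in closed form
(`expected_category_probs()`); e.g. $p_\delta = a_1 r$. Single-epoch designs
place all activity in the nuclear category.

Animal-to-animal variability enters as one level of hierarchy: each animal's
rates are drawn from Beta distributions with the stated means and a single
shared concentration $\kappa$ (variance $m(1-m)/(\kappa+1)$), then `n_neurons`
neurons are tallied by a multinomial draw. One $\kappa$ for all rates is a
deliberate single-knob choice; `calibrate_concentration()` inverts the Beta
variance formula so that a reported group SEM fixes it. The default
$\kappa = 126$ comes from the wild-type single-exploration SEM (2.16
percentage points at mean 0.3905 with 4 animals). The default
`n_neurons = 200` sits in the published range of roughly 85–225 scored
neurons per animal (340–900 per 4–5-animal group), and cohorts default to 4
animals — the published design.

The eight presets (`ensemble_presets()`) are closed-form inversions of the
published group-mean percentages — the MLE below applied to the group means —
so the published regime is the simulator's default. Cytoplasm-only
percentages available only via a published total are derived by subtraction
and tagged as such in the preset provenance and in `reference_values()`. The
repeated-exposure paradigm reuses the two-epoch forward model with its own
rates; no mechanism of training-dependent destabilization is modelled, and
the caged-control baseline is not added to behavioral epochs (presets fold
everything into marginal rates, mirroring the source, which subtracts no
baseline).

What the simulator does *not* emulate: spatial structure and place fields,
transcription kinetics, correlated activation between neurons, imaging or
classification error, and glial contamination. Passing tests therefore
certify the arithmetic and the statistical machinery under the stated
hierarchy, not robustness of real imaging pipelines.

## Estimation

Under the forward model the multinomial likelihood factorizes, giving the
closed-form MLE implemented by `ensemble_fit()`:

$$\hat a_1 = \frac{\gamma+\delta}{n}, \qquad
  \hat r = \frac{\delta}{\gamma+\delta}, \qquad
  \hat b = \frac{\beta}{\alpha+\beta},$$

with binomial standard errors on each estimate's own denominator. A zero
denominator flags that estimate undefined rather than erroring. The fit is
saturated (3 free rates, 3 free category fractions), so raw residuals vanish
on the fitted tally — the residual method exists for simulated or held-out
tallies. `asymptotic_similarity()` plugs the closed-form category
probabilities back into the score: the value an infinitely large animal would
attain, increasing in $r$, equal to 1 at $r=1, b=0$ and 0 at $r=b$.

```{r}
fit <- ensemble_fit(reference_counts("WT", "A20A"))
summary(fit)
```

`parameter_recovery()` closes the loop: simulate cohorts, refit, report bias
and RMSE. At the published design (4 animals × 200 neurons) the recovery RMSE
of $\hat a_1$ matches the beta-binomial variance decomposition
$\mathrm{Var} = \frac{1}{m}\left[\frac{\mu(1-\mu)}{\kappa+1} +
\frac{\mu(1-\mu)\,\kappa}{(\kappa+1)N}\right]$, and the wild-type and
trisomic sparsity presets separate cleanly — the package's qualitative mirror
of the published sparsity finding.

## Group contrasts

The source compared groups with two-way ANOVA and Tukey/Sidak post hoc tests
whose error terms depend on unpublished per-animal data; those are therefore
not reimplemented, and published 95% CIs, F statistics and p-values are not
reproduction targets. Instead `group_contrast()` provides generic resampling
on per-animal values: a percentile bootstrap CI for the mean difference
(resampling animals, never neurons; default 10,000 resamples) and a
two-sided permutation test of label exchangeability — exhaustive enumeration
whenever $\binom{n_A+n_B}{n_A} \le 20{,}000$ (for 4-vs-4, all 70 relabelings,
so the smallest attainable p is 2/70), otherwise Monte Carlo with the
add-one correction, keeping p strictly positive. Raw similarity scores are
compared without any variance-stabilizing transform (the source states none).
Single planned contrasts only; no multiplicity correction.

Known limitation: with 4 animals per group a nominal 95% percentile interval
undercovers — empirical null coverage is around 87%, the classic small-sample
behaviour of percentile bootstrap means. The permutation p-value is the more
trustworthy inferential summary at this design size, and its null
distribution is calibrated (super-uniform) by construction.

## Reproducing the published numbers

`reference_values()` ships every published group value with a provenance tag
(`reported` vs `derived-by-subtraction`, each with a descriptive location and,
for derived entries, the arithmetic). `repro_report()` recomputes all
desk-computable published contrasts — activation mean differences, the
trisomic two-exploration total, and the repeated-exposure similarity-score
difference — and compares each at a tolerance reflecting printing precision:
±0.02 where both inputs are two-decimal prints, ±0.05 where the published
target is a one-decimal print (its own half-ulp; the category sum 39.23
against the printed 39.2 cannot land closer). These bands absorb rounding of
the published inputs, nothing more.

```{r}
repro_report()
```

## Problem sizes used by the test suite

The suite exercises: exhaustive oracle comparison on all 455 weak
compositions of 12 cells; a $5\times5\times5$ rate grid for the MLE identity;
one $10^6$-neuron animal against the closed-form category probabilities (4
binomial SEs); 500-replicate recovery runs at 4 × 200 per genotype; and 500
null 4-vs-4 cohorts for permutation calibration and bootstrap coverage.
These sizes make the Monte-Carlo standard errors small relative to every
asserted band while keeping a full run in well under a minute.
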
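---
title: "Multimodal feature integration by layered PC regression with equivalent weight back-propagation"
author: "mmipcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal feature integration by layered PC regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmipcr)
```

## The problem

Multimodal neuroimaging studies routinely collect many more candidate
features than subjects. The motivating setting is a cohort of people with
HIV (PWH) starting antiretroviral therapy and demographically comparable
controls: eight imaging metrics (Vol, CT, FD, FW, FA, MD, CBF, CVR)
extracted as ROI means over cortical, subcortical and white-matter regions
give 147 features for 86 subjects, and the clinically interesting outcome —
the 12-week change ΔZ in the total cognitive z-score — is observed for only
27 treated subjects. Fitting anything directly in that regime invites
overfitting; cross-validation is unreliable at n = 27; and regularized
fits in component space are hard to interpret biologically.

`mmipcr` implements a deliberately conservative pipeline for this regime,
and an exact algebraic device that restores feature-level interpretability
afterwards.

## The pipeline

**Screening.** Each feature is tested for a PWH-vs-control mean difference
with a Welch (unequal-variance) two-sample *t*-test on the baseline cohort.
The threshold is liberal (two-sided *p* < 0.2, no multiplicity correction)
because this step is a *soft* filter meant to discard clearly uninformative
features, not an inference procedure. Screening always uses both groups at
baseline, even when the downstream model targets ΔZ on the treated subset,
so the retained features are those marked by the disease process.

**Layered correlation PCA.** The screened features are split into groups —
by brain region by default (cortical / subcortical / white matter), by
metric as an alternative — and each group is reduced by PCA on its sample
*Pearson correlation* matrix. Standardizing before rotation is essential
here: MD lives at 10⁻³ mm²/s and CT at millimetres, and covariance-matrix
PCA would let a single modality's scale dominate every leading component.
Components are retained by cumulative proportion of variance explained
(PVE), the smallest k with (Σ_{l≤k} λ_l)/p ≥ PVE. Two variants are
supported: *Model 1* applies a second, global correlation PCA to the
concatenated first-layer scores; *Model 2* uses the first-layer scores
directly. The second layer, when present, also standardizes its inputs
(first-layer scores have unequal variances λ, so this choice is material).

**Stepwise AIC regression.** The retained scores enter a linear model for
Z or ΔZ, pruned by bidirectional stepwise selection under
AIC = n·log(SSE/n) + 2(k+1) (the same criterion `stats::extractAIC` reports
for Gaussian linear models; additive constants are irrelevant to
selection). The returned model is locally optimal: no single addition or
deletion lowers AIC. Models are evaluated in-sample by adjusted R² and RSE
— with a shared outcome the two rankings are exact mirror images — rather
than by cross-validation, which the sample sizes cannot support.

**Equivalent weight back-propagation.** Both PCA layers are affine maps, so
the whole transform collapses to scores = X·A + c with A and c available in
closed form (`stack_affine_map()`). Padding stepwise-dropped components
with zero coefficients, the PC-space fit β̂ maps to an *exactly equivalent*
feature-space model

  β̃ = A·β̂,  β̃₀ = β̂₀ + c·β̂,

with identical predictions for every subject. The raw β̃_j inherit the
features' arbitrary units, so features are ranked by the **adjusted
weight** w_j = σ̂_j·β̃_j, where σ̂_j is the feature's sample SD (n−1
denominator) on the modelling cohort: the predicted-outcome change per
one-SD change in feature j. Multiplying a feature column by any a > 0
scales β̃_j by 1/a and σ̂_j by a, so w_j is exactly scale-invariant — the
property that makes weights comparable across modalities. `mmipcr` verifies
the prediction equivalence numerically on every fitted model
(`verify_equivalence()`, tolerance 10⁻¹⁰ of the prediction range) and
reports features with |w_j| ≥ 0.5 by default, in the standard five-column
layout (feature, adjusted weight, unadjusted weight, mean, SD).

This exactness depends on the linearity of both stages; it does not extend
to nonlinear reductions or models.

## Comparison suites

Two companion suites contextualize the multimodality model for ΔZ:

- **Unimodality models** (8): features of one metric across all regions,
  screened as above, then stepwise AIC directly on the raw features (the
  candidate sets are small enough that no PCA is needed). A model whose
  stepwise selection empties is reported as "no informative features".
- **Modality-region models** (17 = 7 cortical + 7 subcortical + 3 white
  matter): one metric in one region, with screening deliberately skipped,
  so these models can exploit features that predict the outcome without
  differing by group status.

`compare_models()` ranks any suite by adjusted R² and asserts the RSE
reversal as an internal consistency check.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.2 | two-sided screening p-value cutoff (dimensionless) |
| `pve` | 0.9 | cumulative PVE for component retention; 0.8 as the tighter conventional choice |
| `grouping` | `by_region` | first-layer PCA grouping; `by_metric` supported |
| `variant` | `model2` | one-layer (model2) vs two-layer (model1) reduction |
| `w_min` | 0.5 | reporting cutoff on the adjusted weight, in outcome SD units per feature SD |
| `start` | `full` | stepwise starting model; `null` needed when retained scores exceed n − 2 |
| `pca_cohort` | `modeling` | fit PCA/SDs on the modelling cohort (ΔZ: treated subjects with follow-up) or on all subjects |

The defaults for `grouping` and `pca_cohort` were genuinely open design
choices: per-region grouping keeps each PCA's inputs anatomically
homogeneous while letting metrics mix (which is what gives the correlation
matrix its levelling role), and fitting the PCA on the modelling cohort
keeps the predictor self-contained — the alternatives remain one switch
away. The stepwise start is `full`, mirroring the conventional default of
stepwise implementations for this pipeline; with 27 subjects and PVE 0.9
the retained component count can exceed n − 2, in which case the full start
is refused with instructions rather than silently changed, and
`start = "null"` is the documented escape.

## Power and design arithmetic

For study planning the package exposes the standard effect-size chain:
f² = R²/(1−R²) (computed from the *adjusted* R² of a fitted model), the
power of the overall multiple-regression F-test using the noncentral F
distribution with λ = f²·n and denominator df n−u−1, and the required
sample size. The alternative convention λ = f²·(n−u−1) is rejected because
it is inconsistent with the printed design points this arithmetic targets.
`required_sample_size()` solves the power equation in continuous n and by
default rounds to the *nearest* integer, which is the behaviour that
reproduces the reference values (f² = 0.906 → n = 33, f² = 1.731 → n = 23);
note the integer-n power at n = 33 is 0.8988, marginally under the 0.90
target. A `rounding = "ceiling"` mode returns the smallest integer whose
power truly reaches the target (here 34 and 23) and satisfies the
round-trip guarantee power(n) ≥ target > power(n−1). `cumulative_attrition()`
compounds a per-modality dropout rate r over k required modalities as
1−(1−r)ᵏ — at r = 5% and k = 9 domains, 37% of enrolled subjects lack
complete data, the practical cost of requiring complete multimodal
observations.

## The synthetic cohort generator

`simulate_cohort()` emulates the study's *structure*, not its data: 56
controls and 30 PWH (27 with follow-up), the 147-feature grid, and three
independent standard-normal latent factors, one per brain region. A planted
subset of 39 features (11 cortical, 23 subcortical, 5 white matter — spread
evenly across each region's metric blocks so that signal genuinely spans
modalities) both shifts by −0.8 SD in the PWH group and loads 0.6 on its
region's factor; all other features are pure noise. Features are expressed
on metric-realistic scales (MD ~ 10⁻³, CT ~ 2.6, FD ~ 2.1, CBF ~ 1.2) with
unit standardized variance in controls. Baseline Z is the sum of six domain
z-scores, each loading 0.2 on every factor and clipped at ±3 SD before
summation; ΔZ loads (0.8, 0.6, 0.4) on the three factors with unit noise
SD. All draws flow from a single seeded stream in documented order, so
cohorts are bit-reproducible.

Routing the outcome signal through latent factors shared across regions —
rather than through direct feature→outcome coefficients — is what makes
multimodal integration *provably* useful on these cohorts: each metric's
features see the factors only noisily, so pooling metrics improves the
factor estimate and no unimodality model can match the integrated one. The
generator also supplies closed-form oracle R² values (for ΔZ exactly; for Z
exactly when clipping is disabled, by Monte Carlo otherwise), the target
that the fitted adjusted R² should approach as n grows.

What the generator does **not** emulate — and what passing recovery tests
therefore do not establish about real data: spatial correlation among ROIs
beyond the three-factor structure, heavier-tailed or skewed feature
distributions, site/scanner effects, age and demographic confounding,
nonlinear feature–outcome links, and informative (non-random) follow-up
missingness.

## Numerical conventions and degenerate inputs

- Eigenvector signs are fixed by orienting each loading column so its
  largest-magnitude entry is positive (ties: lowest input index);
  predictions and adjusted weights are invariant to this choice, which
  exists purely for cross-platform determinism.
- Eigenvalues below 10⁻¹² are treated as numerically zero: never retained,
  but the PVE denominator is the exact trace p, so under rank deficiency
  (n−1 < p) retention is capped at the positive spectrum.
- Constant feature columns are an error naming the feature at the PCA
  stage; at the screening stage a feature constant *and equal* in both
  groups degenerates to t = 0, p = 1 (never selected), keeping screening
  total over real tables.
- Stepwise ties within 10⁻¹⁰ AIC prefer deletion over addition, then the
  lowest candidate index; a defensive iteration guard (2·m² accepted moves)
  backstops the strict-improvement loop. SSE = 0 maps to AIC = −∞
  ("perfect fit dominates").
- Sample SDs use the n−1 denominator throughout; the screening variance,
  PCA standardization and adjusted weights are all consistent on this
  point.
- Feature tables are complete-case by contract; `drop_incomplete = TRUE`
  performs listwise deletion with a reported count. CSV output uses 17
  significant digits so finite doubles round-trip bit-identically.

The adjusted-R² bootstrap (`bootstrap_adj_r2_ci()`) is a percentile
interval over subject resamples with screening held fixed and the PCA and
stepwise stages refitted per replicate; degenerate replicates (e.g. a
resampled design whose distinct-subject count falls below the candidate
dimension) are skipped and counted. It is provided as a *decided*
uncertainty summary for this pipeline — no claim is made that it matches
any particular published interval, whose construction is not specified.

## Test problem sizes

The automated suite exercises the pipeline at sizes chosen to make the
statistical properties visible while keeping runs quick: exactness and
optimality properties on 20–40-subject fixtures; screening sensitivity at
the study's own 86-subject configuration (5 seeds); consistency of the
fitted adjusted R² toward the oracle at n = 100 vs n = 1000; and
feature-recovery and multimodality-dominance checks as medians over 20
seeded cohorts (n = 300 strong-signal and the 86-subject default,
respectively). These sizes are the package's own testing choices.

## Known limitations

- The equivalence of PC-space and feature-space models is exact only for
  linear PCA plus linear regression.
- In-sample adjusted R² at n in the tens remains optimistic despite the
  complexity correction; the suites mitigate but do not remove this.
- Stepwise AIC returns a local optimum; the tests compare it against
  exhaustive search only for small candidate sets (≤ 6), where the two
  coincide on typical landscapes.
- The screening, PCA and regression stages are refitted jointly only by
  the bootstrap; the reported point estimates condition on the selected
  features and components.
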
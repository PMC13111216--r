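# mmipcr

Integrative modelling of multimodal brain-imaging feature panels against
cognitive outcomes in "large p, small n" cohorts.

A typical study of this kind measures eight imaging metrics — subcortical
volume (Vol), cortical thickness (CT), fractal dimensionality (FD),
extracellular free water (FW), fractional anisotropy (FA), mean diffusivity
(MD), cerebral blood flow (CBF) and cerebrovascular reactivity (CVR) —
across cortical, subcortical and white-matter regions of interest, yielding
on the order of 150 candidate features for fewer than 100 subjects. `mmipcr`
implements a conservative three-step pipeline for relating such a panel to a
cognitive score *Z* (or its longitudinal change ΔZ), plus the surrounding
model-comparison and study-design arithmetic:

1. **Marginal screening.** A per-feature Welch two-sample *t*-test between
   patient and control groups with a deliberately liberal threshold
   (*p* < 0.2, uncorrected), retaining weakly associated features for the
   multivariate stage.
2. **Layered correlation-matrix PCA.** One PCA per feature group (by brain
   region, or by metric), each on the sample *Pearson correlation* matrix so
   that no modality's natural scale dominates, truncated at a configurable
   proportion of variance explained (PVE 0.8 or 0.9). An optional second,
   global PCA layer further compresses the concatenated scores ("Model 1");
   omitting it uses the first-layer scores directly ("Model 2").
3. **Stepwise AIC regression.** Bidirectional stepwise selection under
   AIC = n·log(SSE/n) + 2(k+1) on the retained component scores, with
   deterministic tie-breaking. Models are compared by adjusted
   R² = 1 − (SSE/(n−p−1))/(SST/(n−1)) and residual standard error.

The package's core algorithm is the **equivalent weight back-propagation**:
because both PCA layers are affine and the output model is linear, the
fitted predictor

&nbsp;&nbsp;ŷᵢ = β̂₀ + Σₗ PCᵢₗ β̂ₗ

is rewritten *exactly* as a feature-space model
ŷᵢ = β̃₀ + Σⱼ Xᵢⱼ β̃ⱼ via the composite affine map, and each coefficient is
standardized into the **adjusted weight** wⱼ = σ̂ⱼ·β̃ⱼ — the change in
predicted outcome per one-SD change in feature *j*, invariant under any
rescaling of that feature and therefore comparable across metrics with
wildly different units (MD ~ 10⁻³ vs CT ~ 2.6). Prediction equivalence is
verified numerically on every run (gap below 10⁻¹⁰ of the prediction
range).

Also included: the eight unimodality and seventeen modality-region
comparison suites, Cohen's *f*² = R²/(1−R²) power analysis for the overall
multiple-regression F-test through the noncentral F distribution
(λ = f²·n), attrition compounding 1−(1−r)ᵏ, and a seeded latent-factor
synthetic cohort generator with closed-form oracle R² for parameter-recovery
studies.

## Worked example

```r
library(mmipcr)

cfg <- sim_config()                       # 56 controls + 30 PWH, 147 features
sim <- simulate_cohort(cfg, seed = 42)

scr <- screen_features(sim$table, sim$outcomes)      # Welch screen, p < 0.2
sum(scr$selected)
#> [1] 65

rep <- run_multimodal(sim$table, sim$outcomes,
                      variant = "model2", outcome = "Z", pve = 0.9)
rep
#> <model_report> model2 (pve 0.9, Z) [ok]
#>   n = 86, p = 19, adj R^2 = 0.5078, RSE = 2.0992
#>   terms: cor.PC1, cor.PC2, cor.PC3, cor.PC6, ... wm.PC1

head(rep$ranked, 3)                       # adjusted-weight report, |w| >= 0.5
#>    feature_id adjusted_weight unadjusted_weight         mean           sd
#> 1 PUC.CVR.cor      -0.9115773         -2.716420 0.9570732828 0.3355804074
#> 2  TH.CBF.sub      -0.7390017         -3.397038 1.1200235717 0.2175429549
#> 3 AccN.MD.sub       0.7210753       3835.231319 0.0009928998 0.0001880135

rep$equivalence$max_gap                   # exact two-path equivalence
#> [1] 4.662937e-14
```

The screen keeps 65 of 147 features (the generator plants group shifts on
39); the single-layer Model 2 pipeline compresses them to 34 component
scores, of which stepwise AIC retains 19, explaining about half the variance
of the baseline score. The top adjusted weights are of order 1 and directly
comparable, while the unadjusted coefficients range over four orders of
magnitude — the point of the SD adjustment.

Design arithmetic:

```r
f2 <- cohens_f2_from_adj_r2(0.6339)       # 1.731
required_sample_size(10, f2)              # 23 subjects for 90% power
cumulative_attrition(0.05, 9)             # 0.370 of subjects lost
```

A command-line interface with `simulate`, `screen`, `fit`, `weights`,
`power`, `attrition` and `compare` subcommands is installed as
`exec/mmipcr`.

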
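# hippomicro

Tools for studying age-related change in hippocampal gray-matter
microstructure with multi-shell diffusion MRI — as a fully testable pipeline
that runs end-to-end on synthetic phantom cohorts with known ground truth.

The package is aimed at diffusion-MRI methodologists and neuroimaging
statisticians who want each stage of a hippocampal microstructure study —
forward signal simulation, super-resolution reconstruction, biophysical
model inversion, surface morphometry, and cohort statistics — as an
inspectable, seed-reproducible R function rather than a chain of external
toolboxes.

## What it implements

**SANDI forward model.** The direction-averaged (spherical-mean, "powder
average") signal of gray matter is modelled as a three-compartment mixture

S(b) / S(0) = f_soma · S_sphere(b; R_soma, D_is) + f_neurite · S_stick(b; D_in) + f_extra · exp(−b · D_e)

with f_soma + f_neurite + f_extra = 1 and D_is fixed at 3 µm²/ms. The stick
compartment has the closed form √(π/(4 b D_in)) · erf(√(b D_in)); the soma
compartment is the finite-pulse Murday–Cotts Gaussian-phase-distribution
attenuation for diffusion restricted in a reflecting sphere under a PGSE
pulse pair (δ = 8 ms, Δ = 19 ms by default), evaluated from the eigenvalue
roots of x J′₃/₂(x) = ½ J₃/₂(x). A Monte-Carlo random-walk simulator of the
same pulse sequence (`mc_sphere_signal()`) ships as an independent
validation oracle.

**Inversion.** `build_training_set()` draws parameter combinations uniformly
from the model ranges (100,000 at full scale), simulates their shell
signals with optional Rician noise, and `train_sandi_inverter()` fits one
random-forest regressor per parameter (200 trees at full scale).
`fit_sandi()` maps voxelwise shell means to parameter maps under the
fraction-sum constraint. A constrained weighted-least-squares DKI fit
(`fit_dki()`) covers the b ≤ 3450 s/mm² shells, enforcing non-negative
apparent diffusivity/kurtosis and monotone signal decay.

**Super-resolution.** `super_resolve()` implements anatomically guided
self-similarity super-resolution: weights from 3×3×3 patch differences in
the diffusion volume plus voxel intensity differences in a co-registered
high-resolution reference, computed in a 5×5×5 kernel with an
h-series (1, 2, 4, 6, 8, 16) over six iterations, each followed by an exact
data-consistency correction so the downsampled result always equals the
acquired low-resolution data.

**Surface morphometry.** Cotangent Laplace–Beltrami mean curvature with
mixed Voronoi areas, gyrification as the native/unfolded vertex-area
ratio, inner–outer thickness (undefined for the dentate gyrus), and
trilinear mid-thickness sampling of volumetric maps.

**Aging statistics.** ROI and vertexwise OLS of each metric on age with a
sex covariate (model ladder M1–M4), the identity t = r√(n−2)/√(1−r²) for
age-only fits, Benjamini–Hochberg FDR within each metric family,
nested-model likelihood-ratio tests, Welch two-sample tests from group
summaries, and spatial Pearson correlation matrices between metric maps.

**Synthetic ground truth.** Labelled pseudo-subfield phantoms (subiculum,
CA1–CA4, DG), multi-shell DWI simulation with interleaved b0 volumes and
Rician noise, matched low/high-resolution pairs, piecewise-constant
anatomical references, age-structured cohorts calibrated to target
age–metric correlations at n = 72 (32 male / 40 female, ages 19–85), and
analytic toy meshes (sphere, plane, cylinder, sinusoid, concentric pair).

## Worked example

```r
library(hippomicro)
# cohort age balance from group summaries
welch_t_from_summary(32, 42.25, 17.99, 40, 40.75, 17.98)
#> # A tibble: 1 × 3
#>       t   dof     p
#>   <dbl> <dbl> <dbl>
#> 1 0.352  66.6 0.726

# simulate an aging cohort and regress every SANDI metric on age
cohort <- simulate_cohort(seed = 42)
fit <- age_regression(cohort, model = "M3")
print(dplyr::arrange(dplyr::filter(fit, metric == "f_soma"), roi), n = 6)
#> # A tibble: 6 × 11
#>   metric roi   beta0     beta1    beta2     t       p      r     n   dof   p_fdr
#>   <chr>  <chr> <dbl>     <dbl>    <dbl> <dbl>   <dbl>  <dbl> <int> <int>   <dbl>
#> 1 f_soma CA1   0.455 -0.00102  -0.0101  -4.15 9.38e-5 -0.437    72    69 1.87e-4
#> 2 f_soma CA2   0.491 -0.000948  0.00958 -3.94 1.95e-4 -0.437    72    69 2.34e-4
#> 3 f_soma CA3   0.534 -0.00121   0.00522 -4.56 2.13e-5 -0.487    72    69 9.28e-5
#> 4 f_soma CA4   0.453 -0.000806  0.0115  -3.55 7.01e-4 -0.404    72    69 7.01e-4
#> 5 f_soma DG    0.560 -0.00119  -0.00886 -4.46 3.09e-5 -0.466    72    69 9.28e-5
#> 6 f_soma Sub   0.392 -0.00103   0.0142  -4.07 1.25e-4 -0.450    72    69 1.87e-4
```

The Welch t of 0.352 (p = 0.726) confirms the simulated cohort convention
of an age-balanced sex split. In the regression table, `beta1` is the
change per year of the soma signal fraction in each subfield, `t` and `p`
test that slope with sex partialled out, `r` is the age-only Pearson
correlation (here ≈ −0.45, the target the generator was asked to induce),
and `p_fdr` is Benjamini–Hochberg-adjusted within the metric across its
six ROIs. All six subfields remain significant after FDR, as expected at
this effect size and n = 72.

`run_pipeline(demo_config())` chains the whole thing — phantom, degraded
acquisition, super-resolution, SANDI + DKI fitting, surface metrics, and
cohort regression — and writes parameter maps (NIfTI), tables (TSV) and a
JSON report of every statistic and seed.

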
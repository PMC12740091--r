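---
title: "Models and methods behind the hippocampal microstructure aging pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the hippocampal microstructure aging pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomicro)
```

# Overview

`hippomicro` rebuilds a hippocampal microstructure aging analysis as a
chain of seed-reproducible R functions: forward simulation of multi-shell
spherical-mean diffusion signals under the SANDI three-compartment model,
anatomically guided self-similarity super-resolution of low-resolution
diffusion volumes, inversion to voxelwise parameter maps by a
simulation-trained tree ensemble, a constrained DKI representation on the
low-b shells, per-vertex surface morphometrics, and ROI/vertexwise age
regression with Benjamini–Hochberg FDR control. Because clinical cohorts
of this kind are not publicly shareable, every stage is exercised on
synthetic phantoms and cohorts whose ground truth is known, and the test
suite quantifies what each stage does and does not recover.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices made where the design was genuinely open,
and the known limitations — in particular two identifiability limits that
shape how the pipeline's accuracy should be read.

# Units

All internal quantities are kept at magnitude O(1): b-values in ms/µm²
(1 ms/µm² = 1000 s/mm²), diffusivities in µm²/ms, radii in µm, times in
ms, coordinates in mm. External FSL-style `bvals` files (s/mm²) are
divided by 1000 on read. No gyromagnetic constant appears anywhere:
wherever the squared gradient amplitude (γg)² is needed it is recovered
from b = (γg)²δ²(Δ − δ/3), which sidesteps unit pitfalls entirely.

# The SANDI forward model

A voxel's direction-averaged signal at b-value b is

$$\frac{S(b)}{S(0)} = f_\mathrm{soma}\,S_\mathrm{sphere}(b) +
  f_\mathrm{neurite}\,S_\mathrm{stick}(b) + f_\mathrm{extra}\,e^{-b D_e},
  \qquad f_\mathrm{soma}+f_\mathrm{neurite}+f_\mathrm{extra}=1 .$$

*Stick (neurite).* The powder average of $e^{-bD_\mathrm{in}\cos^2\theta}$
over the sphere, $\sqrt{\pi/(4bD_\mathrm{in})}\,\mathrm{erf}(\sqrt{bD_\mathrm{in}})$,
with a series expansion below $bD_\mathrm{in} = 10^{-8}$ to avoid 0/0.
The unit tests pin this against adaptive quadrature to 10⁻⁶ over the full
(b, D) training grid.

*Ball (extracellular).* Isotropic Gaussian decay; the spherical mean
equals the per-direction signal.

*Sphere (soma).* The finite-pulse Murday–Cotts Gaussian-phase-distribution
(GPD) attenuation for spins restricted in a reflecting sphere of radius R
under rectangular PGSE pulses (δ, Δ):

$$-\ln S = \frac{2(\gamma g)^2}{D}\sum_m
  \frac{\alpha_m^{-4}}{\alpha_m^2R^2-2}\left[2\delta -
  \frac{2 + e^{-\alpha_m^2 D(\Delta-\delta)} - 2e^{-\alpha_m^2 D\delta}
  - 2e^{-\alpha_m^2 D\Delta} + e^{-\alpha_m^2 D(\Delta+\delta)}}
  {\alpha_m^2 D}\right]$$

with $\alpha_m = x_m/R$ and $x_m$ the roots of
$x J'_{3/2}(x) = \tfrac12 J_{3/2}(x)$ (first root 2.08158), found by dense
sign-change scanning plus bisection to residual < 10⁻¹⁰ and cached. The
series is truncated at 20 roots by default; 20 vs 50 roots differ by less
than 10⁻⁸ everywhere in the training ranges. The constant terms of the
exponential sum cancel exactly, so it is evaluated with `expm1` — without
this the frozen-spin limit (D → 0) loses four digits to cancellation.

The finite-pulse GPD form was chosen over the Neuman long-pulse limit
because it is the kernel used by the reference SANDI implementations; the
package documents this as its choice since δ = 8 ms is not in the
long-pulse regime for small somas.

## Validity of the GPD kernel — and the Monte-Carlo oracle

`mc_sphere_signal()` is a deliberately independent check: walkers start
uniformly in the sphere, take Gaussian steps (time step snapped so the
pulse edges land on the step grid), reflect specularly at the boundary,
and accumulate phase by the trapezoidal rule; the signal is the mean
cosine of the phase. Its own `mt19937_64` stream keeps it decoupled from
R's RNG. Against the exact free-diffusion limit (huge radius) it is
unbiased within Monte-Carlo error.

Two regimes emerge, and both are asserted by tests rather than assumed:

* At small-to-moderate attenuation (R ≤ ~5 µm at b = 3.45 ms/µm², or any
  radius at small b, where the GPD — being the exact second phase
  cumulant — must be exact) the closed form and the walker agree to well
  under 1%.
* At strong attenuation (R = 8–11 µm at b = 3.45 ms/µm²,
  γgδR ≈ 3–4 rad) the GPD underestimates the attenuation by tens of
  percent. This is the documented breakdown of the Gaussian-phase
  approximation, not an implementation artifact: the same code passes the
  small-b exactness check at those radii. The acceptance suite reports
  the per-radius discrepancies as measured; users fitting large somas at
  high b should treat the soma kernel — in any GPD-based SANDI
  implementation — as an effective model.

# Inversion

`build_training_set()` samples the five free parameters uniformly:
the fraction pair uniform on the triangle
$f_\mathrm{soma}+f_\mathrm{neurite}\le 1$ (rejection sampling, so the
pair is jointly uniform with $f_\mathrm{extra}$ the remainder),
R_soma ∈ [1, 12] µm, D_in and D_e ∈ [0.25, 3] µm²/ms, D_is = 3 fixed.
Full scale is 100,000 combinations; the tests and acceptance script use
10,000, which the closed-loop experiments show is within a few percent of
the large-sample accuracy plateau. Optional Rician noise is applied at a
scalar SNR (σ = 1/SNR on the normalised scale, referenced to the b = 0
level); training at the voxelwise-SNR level was considered and rejected
for single-model-per-dataset simplicity.

`train_sandi_inverter()` fits one `ranger` forest per parameter (200
trees at full scale, library defaults otherwise, single-threaded,
seeded — identical refits are bit-identical). One-model-per-parameter
rather than multi-output keeps per-parameter validation and metadata
simple. Predictions are clipped to the training ranges, and the fraction
triple is projected back to the simplex: negative remainders are clipped
to zero and the (f_soma, f_neurite) pair rescaled.

## The identifiability ceiling

A point that shapes every downstream accuracy statement: over the *full
uniform prior*, spherical-mean signals at the 8-shell protocol do not
determine the signal fractions to better than roughly ±0.15 RMSE even
with noiseless data. This is a property of the model space, not of the
regressor — a nearest-neighbour search over tens of thousands of
noiseless training signals finds parameter sets whose signals coincide to
a fraction of a percent while their f_soma differs substantially
(small-radius somas imitate a slow extracellular ball; large-radius somas
trade against stick and ball mixtures). The soma radius, by contrast, is
well determined in its sensitive range: median absolute error well under
1 µm for true R ∈ [3, 10] µm at SNR 50.

Consequently the unit tests assert the properties the inverter does
guarantee — determinism, range clipping, simplex validity, informative
recovery far below the prior's spread, accurate R_soma, and
*monotone-on-average* behaviour (averaging predictions over random base
settings at a common f_extra grid yields strictly increasing means) —
while the acceptance suite reports the raw closed-loop RMSEs as measured.
A single f_extra sweep at one base setting has a noisy rank correlation
(~0.4–0.6) for the same degeneracy reason; only the averaged sweep is a
fair monotonicity probe.

# The constrained DKI representation

The low-b shells (b ≤ 3.45 ms/µm², i.e. 0–3450 s/mm²) are fitted with

$$\ln S = \ln S_0 - b\,D(\mathbf n) + \tfrac{b^2}{6}\,\bar D^2 K(\mathbf n)$$

linear in 22 coefficients (6 tensor elements, 15 elements of
$V = \bar D^2 W$), by weighted least squares with weights equal to the
squared predicted signal (two passes). Summaries: MD/AD/RD/FA from the
tensor eigen-decomposition; apparent kurtosis $K(\mathbf n) = V(\mathbf
n)/\mathrm{MD}^2$; MK as the mean over a 256-direction Fibonacci sphere,
AK along the principal eigenvector, RK averaged around the orthogonal
great circle.

Constraints — $D(\mathbf n)\ge 0$, $K(\mathbf n)\ge 0$, and monotone decay
$D(\mathbf n) \ge (b_{max}/3)V(\mathbf n)$ — are imposed on the acquired
directions plus a 60-direction test sphere. No quadratic-programming
solver is used: when the unconstrained solution violates a constraint,
the fit is refined by minimising the weighted residual plus an increasing
quadratic penalty on the violations (analytic gradient, BFGS, penalty
weights rising to 10⁸ × a data-anchored scale). The penalty scale is
anchored to the weighted signal variance rather than the residual sum so
that exactly representable signals — where the residual is zero — still
see a strong penalty; residual constraint violations after refinement are
at the 10⁻¹⁰ level in the test fixtures. Signals lying in the model space
are reproduced to numerical tolerance, and the isotropic and prolate
fixtures recover MD, FA, MK analytically to 10⁻⁶.

# Self-similarity super-resolution

Each 3D volume of the series is processed independently:

1. initialise by nearest-neighbour upsampling (factor 2 per axis by
   default);
2. for each h in (1, 2, 4, 6, 8, 16): one weighting pass, then one
   data-consistency pass.

The weight between a centre voxel and a kernel neighbour is

$$-\ln w = h^2\left[\frac{\mathrm{SSD}_{3\times3\times3}}
  {N_\mathrm{patch}\,k_\mathrm{DWI}} +
  \frac{(T_x - T_c)^2}{k_\mathrm{T1w}}\right]$$

computed over a 5×5×5 kernel; voxel-to-voxel distance is deliberately
absent from the weight. Design choices where the formulation was open:

* **Normalisation constants.** $k_\mathrm{DWI}$ is the mean squared
  in-mask intensity *per 3D volume* (intensity scale varies strongly
  across shells); $k_\mathrm{T1w}$ is computed once. The reference term
  uses the single-voxel intensity difference, not a patch, matching the
  weight formula's asymmetric structure.
* **Boundary handling.** Patches are truncated at the volume edge and the
  SSD normalised by the number of voxel pairs actually compared,
  replacing the nominal 27; this removes edge bias.
* **Down/up operators.** Downsampling is the block mean (the natural
  partial-volume model) and the residual is upsampled by nearest
  replication. Because these form an exact mean/replicate adjoint pair,
  the consistency step — add back the upsampled residual between the
  acquired low-resolution volume and the downsampled estimate — is exact
  to machine precision and idempotent, and in-mask mass is conserved.
* **Ordering.** Weighting first, then consistency, every iteration, so
  data fidelity holds at every step, not just at convergence.
* **h² placement.** The h² factor multiplies both dissimilarity terms and
  the h-series is (1, 2, 4, 6, 8, 16) — i.e. smoothing is weakest first
  and grows as the estimate sharpens.

On seeded two-tissue phantoms the super-resolved series roughly halves
the masked RMSE against the 1-mm truth relative to nearest-neighbour
upsampling, and halves the boundary-voxel RMSE. One metric deserves a
caveat: the *fraction of boundary voxels within 10%* of truth cannot
separate super-resolution from nearest-neighbour on a piecewise-constant
phantom, because nearest-neighbour is exactly correct for every boundary
voxel whose 2³ block does not straddle the boundary (about half the
boundary set); the tests therefore use that fraction only against the
trilinear baseline and use RMSE against nearest-neighbour.

The noise map used for SNR estimation is squared before upsampling and
square-rooted after (variance, not σ, is the additive quantity under
i.i.d. noise); the upsampling there is trilinear, since nearest
replication would make the variance-domain detour a no-op.

# Surface morphometrics

* **Mean curvature**: cotangent Laplace–Beltrami with mixed Voronoi
  vertex areas (Voronoi area for non-obtuse triangles, area/2 at an
  obtuse corner, area/4 otherwise); H is half the norm of the
  mean-curvature normal, signed by its projection on the outward vertex
  normal. Boundary vertices (incomplete one-ring) are returned as NA
  rather than silently computed. Accuracy on analytic fixtures: sphere
  essentially exact on an icosphere, cylinder within 3% on a regular
  tube, plane interior flat to 10⁻⁶.
* **Gyrification**: per-vertex barycentric area (one third of incident
  triangle areas — a partition of unity) on the native surface divided by
  the same vertex's area on the unfolded surface. Per-vertex rather than
  per-face areas were chosen so the quantity lives on the vertex table
  like every other metric; vertex-index correspondence across
  representations is required, matching a template-projection workflow,
  and no resampling is performed.
* **Thickness**: Euclidean distance between corresponding inner/outer
  vertices; undefined (NA) for dentate-gyrus-labelled vertices, which
  lack the two-layer structure.
* **Sampling**: trilinear interpolation at mid-thickness vertices via the
  stored voxel-to-world affine (0-based voxel convention); exact for
  affine intensity fields, NA outside the grid.

# Aging statistics

The model ladder is M1: Age, M2: Age + Age², M3: Age + Sex (the default),
M4: Age + Age² + Sex, fitted by OLS; the reported t tests the linear age
coefficient at dof = n − p, and the Pearson r comes from the age-only
relationship, for which t = r√(n−2)/√(1−r²) holds to 10⁻¹⁰ by identity.
Sex is coded 0/1; the age t-statistic is invariant to the coding, which a
test asserts. Conventions chosen where practice varies:

* **Two-sample age-balance test**: the Welch (unequal-variance) form with
  Welch–Satterthwaite dof. From printed group summaries (32 males
  42.25 ± 17.99; 40 females 40.75 ± 17.98 years) it gives t = 0.35165,
  p = 0.726.
* **FDR families**: within each metric across its six ROIs for the ROI
  analysis, and across vertices within each metric map for the vertexwise
  analysis — mirroring how per-metric result tables and surface maps are
  read. `bh_fdr()` delegates to the standard step-up implementation; the
  test suite checks it against an independently written "minimum over the
  larger-p tail" brute force on a thousand random vectors.
* **Likelihood-ratio tests** between nested OLS models use the Gaussian
  form n·ln(RSS₀/RSS₁) against χ² with the coefficient difference as
  dof; under the null its p-values are uniform (KS-checked).
* **ROI summaries** are unweighted vertex means (area weighting was
  considered; the tests document the difference on a skewed-area fixture
  so the choice is explicit), with DG excluded for thickness via NA
  propagation.
* **Spatial correlation matrices** are pairwise-complete Pearson across
  vertices with FDR flags on the upper triangle.

# The synthetic-data generators

The generators define the study conditions; they are ordinary tested code,
not throwaway fixtures.

* **Phantom**: a 32³ grid of 1-mm voxels (ground truth), an ellipsoidal
  foreground partitioned into six pseudo-subfield slabs, each with
  gray-matter-plausible SANDI values inside the training ranges
  (f_soma 0.35–0.50, R_soma 6.5–9 µm, D_e 0.8–1.0 µm²/ms), optional
  smooth within-region perturbation clamped to the valid ranges. The
  default super-resolution experiment degrades by factor 2 to a 16³
  low-resolution grid — small enough that the full chain runs at desk
  scale, large enough to contain genuine region boundaries.
* **Subject DWI**: per-voxel forward signals expanded to per-direction
  volumes. Each direction of a shell carries the shell's spherical-mean
  value: every SANDI consumer downstream uses only spherical means, so no
  orientation-dispersion model is simulated (DKI direction-dependence
  tests use separately generated tensor signals instead). Shell direction
  sets are deterministically rotated against each other so the joint
  direction set spans the kurtosis basis. b = 0 volumes are interleaved
  every 16 DWIs; Rician noise uses σ = b0-level / SNR.
* **Cohort**: ages uniform on 19–85, 32/40 male/female split, n = 72 by
  default. Per-subject, per-region parameters are baseline + slope·age +
  subject noise, clamped to valid ranges; the slope for a target
  cross-sectional correlation r is r/√(1−r²) · σ_subject/sd(age). The
  default targets (e.g. −0.5 for f_soma, +0.4 for R_soma, ±0.3 for
  others, subject noise 0.04 on fractions) are synthetic stand-ins at
  effect sizes a cross-sectional aging study of this size could plausibly
  detect — they are not estimates of any real cohort. Calibration is
  verified: across 200 replicates the estimated r lies inside the
  Fisher-z ± 2/√(n−3) band in well over 90% of runs, and sex (which
  carries no injected effect) is rejected at no more than the nominal
  rate. If clamping saturates more than 20% of subjects a warning is
  recorded in the provenance attribute.
* **Toy meshes**: icospheres, triangulated sheets, open cylinders,
  sinusoidal sheets paired with their flat projection, and concentric
  sphere pairs — each with analytic curvature/area/thickness.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: realistic hippocampal geometry and folding,
orientation-dispersed fibres, susceptibility/eddy/motion artifacts
(their corrections are out of scope), voxelwise noise maps, T2-dependent
compartment weighting, and partial-volume mixtures beyond the block-mean
model.

# Pipeline, configuration and reproducibility

`run_pipeline()` executes simulate → degrade → super-resolve → spherical
means → SANDI fit → DKI fit → surface metrics → cohort regression from a
single configuration list (or YAML file) with one top-level seed; every
stage's randomness is derived from it, and rerunning a configuration
reproduces the JSON report exactly. The report carries every FDR decision
with its raw p-value, all seeds, and the package version. Outputs use the
standard formats of their consumers: NIfTI volumes with FSL-style
bvals/bvecs, ASCII PLY meshes with per-vertex properties, TSV tables.
The exported stage functions are the intended programmatic surface; the
demo configuration keeps the whole chain to about a minute.

Problem sizes used by the shipped tests and the acceptance script —
chosen as the smallest scales at which each property is cleanly
measurable: 10⁴ training samples / 50 trees for closed-loop experiments,
10⁵ Monte-Carlo walkers for the sphere-signal validation, 32³ phantoms
for super-resolution, 200 replicates for the FDR and cohort calibration
checks, 10,242-vertex icospheres for curvature.

# Known limitations

* The soma kernel inherits the GPD approximation's bias at strong
  attenuation (large R × high b), quantified above by the Monte-Carlo
  oracle.
* Signal fractions are identifiable only up to the model-space degeneracy
  of spherical-mean SANDI at this protocol; reported fraction maps should
  be read as regularised estimates whose voxelwise error can reach the
  degeneracy scale even at high SNR.
* Compartment exchange and T2 weighting of the fractions are not
  modelled (short-diffusion-time and single-TE assumptions).
* The DKI constraint surface is enforced on sampled directions, not
  algebraically; pathological tensors violating constraints strictly
  between sampled directions are possible in principle.
* Registration between the anatomical reference and the diffusion data is
  assumed done; the super-resolution tolerates misregistration only on
  the order of its kernel radius.
* Statistics are cross-sectional linear/quadratic models; no splines or
  longitudinal structure.
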
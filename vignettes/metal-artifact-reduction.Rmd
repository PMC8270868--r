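---
title: "Simulating and reducing metal artefacts in CT for PET attenuation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reducing metal artefacts in CT for PET attenuation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(marct)
```

This vignette is the package's account of its science: the forward models,
the correction algorithms, the choices that were genuinely open and how we
made them, and what the synthetic experiments do and do not demonstrate.

## The problem

Dense implants (dental fillings, fixation screws, joint prostheses)
attenuate a polychromatic X-ray beam so strongly and so non-linearly that
filtered backprojection (FBP) reconstructions develop bright and dark
streaks and shading around the metal. When such a CT image is converted to
a 511 keV attenuation map (μ-map) for PET attenuation correction, the
artefacts bias the reconstructed activity near the implant — precisely the
region a clinician is often asked to quantify. The package builds the whole
chain in simulation so that artefact generation, correction and PET
propagation can be studied against a known ground truth.

## Forward model

**Geometry.** An equi-angular fan beam: by default 1000 views over 360° and
920 detector bins, source–isocenter distance 600 mm, source–detector
1100 mm, field of view 500 mm. The detector is centered so the isocenter
ray falls midway between the two middle bins; the per-bin fan increment is
chosen to cover the FOV with a two-bin margin. The source/detector
distances and FOV are conventional clinical values and are configuration
keys; results in this package are insensitive to them at the few-percent
level.

**Projection.** The projector is an interpolating ray-driven (Joseph-type)
scheme: one bilinear sample per row or column crossing along the dominant
ray axis. A deliberately independent reference implementation
(`forward_project_ref`) marches every ray at a fixed 0.25 mm step; the two
agree within about 0.1% on smooth 64×64 images, and the test suite enforces
0.5%.

**Spectrum.** The tube potential fixes only the maximum energy. We ship a
closed-form bremsstrahlung-like 120 kVp spectrum: Kramers fluence
`(kVp − E)` multiplied by an inherent-filtration factor `exp(−(30/E)³)`,
discretized into 20 bins from 20 keV; its mean energy is ≈63 keV, typical
of a moderately filtered clinical beam. Any spectrum can be substituted as
an `(energy, weight)` table. For beam-hardening simulation only the broad
shape matters: the cupping and streak magnitudes change with filtration,
their existence does not.

**Attenuation data.** `inst/extdata/materials_xcom_approx.csv` is an
approximate re-tabulation of standard photon mass attenuation
coefficients for air, soft tissue, cortical bone, iron, titanium, copper
and gold on a common 20-point 20–150 keV grid, with gold's K-edge at
80.7 keV declared so that log–log interpolation never crosses the
discontinuity. The table is data, not code: users with access to a
cross-section database can drop in an exact file with the same columns.

**Polychromatic projection and water calibration.** Material density maps
from the weighted-threshold segmentation (hard classes air/soft/bone/metal
with ±50 HU linear transition ramps) are projected per material; the
transmitted fraction is `Σ_E w(E) exp(−Σ_m (μ/ρ)_m(E) t_m)`; rays below a
10⁻¹² transmission floor are clamped (photon starvation). Reconstructing
these line integrals directly reproduces the classic cupping artefact, and
the acceptance suite checks it on a water disc. The artefact *pipeline*,
however, applies a water calibration first — the ray-wise inversion of the
polychromatic water curve that every clinical scanner performs — so that a
metal-free acquisition reconstructs nearly cleanly (≈10 HU residual from
bone at the fixture resolution) and the artefacts attributed to metal
really are caused by metal. The toggle `water_calibration = FALSE` exposes
the uncalibrated behaviour.

**Noise.** Optional Poisson counting noise at a configurable incident
photon count `N0` per bin: expected counts `N0·exp(−p)`, Poisson draw,
log-convert with a 1-count floor. The desk study conditions use
`N0 = 2×10⁴` (a low-dose setting): through several centimetres of metal
the expected count falls below one and the measured values are
noise-dominated, which is the dominant clinical artefact mechanism and the
one projection-completion methods target.

**HU conventions.** Inserted implants get `HU = 1000(μ/μ_water − 1)` at the
70 keV reference energy on an extended scale clipped at 30000 HU (so gold
is representable). Reconstructed images are clipped to the 12-bit clinical
range [−1024, 3071]: without this, error metrics for gold are dominated by
a ±25000 HU overshoot halo that no correction method touches and that
clinical data cannot contain. `hu_to_mu` uses water scaling below 100 HU
and a linear blend toward tabulated bone attenuation at 1500 HU above it;
`mu_to_hu` is its exact inverse.

## Phantoms and study conditions

Three parametric body templates (thorax, head, pelvis) are built from
ellipses — body outline, low-density lung surrogates, bone ovals, organ-like
soft structures — plus a seeded smooth texture field (six broad Gaussian
blobs, ±20 HU) so projections are not piecewise constant. Sizes scale with
the grid extent (templates are authored for 384 mm), and implants scale
with the *same* factor: keeping the implant-to-anatomy ratio fixed turned
out to be essential, because oversized implants produce sinogram traces so
wide that interpolation-based correction is destroyed (a 42% trace
fraction was measured for a hip implant on a 64-pixel grid with
unscaled implants).

The eight implant shapes are stylized (two dental fillings, two spine
screws, two hip and two shoulder prostheses) with anatomically plausible
dimensions (e.g. 7 mm screw shafts). Their geometry is declared, not
inferred from any clinical dataset.

The default corpus design crosses 25 realizations × 8 shapes × 4 materials
= 800 cases with a stratified 660/140 train/evaluation split (each
(shape, material) stratum contributes within ±1 case of its share).
Realization randomness is anchor jitter (±15 px at 256-px scale), rotation
(±20°) and scale (0.8–1.2); anatomical variety comes from cycling the three
body templates.

**Desk conditions.** Tests and the acceptance script run a scaled-down
study: 128×128 pixels at 2 mm, a 192×160 fan beam, Poisson noise at
`N0 = 2×10⁴`, and the *clinical implant-material pairing* — dental
fillings in gold (amalgam surrogate), screws and shoulder prostheses in
iron (steel), hips in copper (cobalt-chrome surrogate) — rather than the
full factorial crossing. Two reasons. First, 25 realizations × 8 shapes
under this pairing is exactly a ~200-pair training corpus that a CPU can
simulate and train on in minutes. Second, the correction experiments are
only meaningful in the severe-artefact regime that clinical MAR cohorts
("substantial" implants) comprise: a titanium dental filling produces a
~14 HU artefact, below the intrinsic error floor of prior-based
correction, and no method — here or clinically — improves such cases. The
full crossing remains the default of `build_manifest()` and is used for
the bookkeeping checks. The 16-case acceptance fixture mirrors a clinical
cohort's composition: dental-dominant, then hips, then shoulders, no spine
screws.

## NMAR

The pipeline: segment metal (> 2500 HU, components under 3 px discarded);
forward-project the metal mask to get the trace (plus one bin of
dilation); pre-correct with plain linear interpolation (LI) across the
trace; classify the LI image into air (−1000), soft tissue (0) and bone
(original values above 150 HU) to form the prior; normalize the measured
sinogram by the prior sinogram; linearly interpolate the *normalized* data
across the trace; denormalize; reconstruct; reinsert the original metal
pixels.

Three implementation points deserve emphasis:

* **Offset-stabilized normalization.** The textbook ratio `s/s_prior`
  (with a bare floor on the prior) explodes whenever a trace segment ends
  near the body boundary: the interpolation endpoint becomes an air-ray
  ratio — numerically arbitrary, since both sinograms vanish there — and
  the error is re-amplified by the large prior values mid-trace. We use
  `(s + δ)/(s_prior + δ)` with δ = 1 (about 5 cm of water), which sends
  air ratios to 1, is exact for a perfect prior, and reduces to the bare
  formula as δ→0 (`delta = 0` selects the floored division). The
  perfect-prior oracle — corrected trace equal to ground truth when the
  prior is the true sinogram — holds in both modes and is enforced to
  10⁻⁶ by the tests.
* **Measured sinograms when available.** A scanner's NMAR operates on raw
  projections. When the acquisition is available (every
  `simulation_case`), `nmar_correct` uses it; re-projecting an
  already-reconstructed image instead adds a ~60 HU double-resampling
  floor that buries the correction. Image-only input still works by
  reprojection, matching the standalone use case.
* **Two prior-refinement passes.** The prior built from the LI image is
  poor wherever the implant sits inside bone (the LI reconstruction is
  worst exactly there). A second pass rebuilds the prior from the
  first-pass corrected image and re-corrects the *original* sinogram;
  this iterative refinement is the default (`passes = 2`) and makes the
  correction robust across anatomies. A perfect prior leaves a 16–27 HU
  floor on the fixtures; the two-pass prior reaches 58–170 HU depending
  on severity, always below the affected baseline on the clinical-cohort
  fixture.

NMAR's intrinsic floor also delimits its applicability: on mild artefacts
(≲60 HU) the classification error of the prior (organs and texture mapped
to water, lung surrogates mapped to soft tissue) exceeds the artefact
itself, and NMAR worsens the image. This is a true property of the
algorithm, visible clinically as well, and it is why the acceptance
fixtures represent the severe regime.

## Deep-learning MAR

The network is a compact residual dilated CNN in the spirit of
high-resolution segmentation/restoration architectures: an entry 3×3
convolution, `L` pre-activation residual convolutional layers (3×3,
dilation 1 over the first third, 2 over the second, 4 over the last, so
the receptive field grows without pooling), and a 3×3 output convolution.
Two presets: `"paper"` (20 residual layers, two 400×400 input channels)
and `"desk"` (8 layers, 16 filters, 64×64 patches) used by all tests.
Kernels are 2D (the training data are 2D slices; the cited architecture's
3×3×3 kernels are its 3D origin).

Design choices we made where the published description is silent:

* **Residual restoration with a zero-initialized output.** The output
  convolution starts at zero and its result is added to a designated
  input channel — the NMAR image (image domain, strategy iii) or the
  affected sinogram (projection domain). The untrained network is
  therefore exactly an identity on its best available input, training
  can only improve on it, and optimization never has to re-learn the
  image from scratch. This also changes the meaning of the classic
  "overfit a single pair" sanity check: the initial loss is already
  NMAR-quality, so driving it below 1% of *that* (the test does, in 1000
  Adam steps at `lr = 10⁻³`) is a stricter bar than the usual
  random-initialization variant.
* **Learning rates.** The published schedule (0.06 linearly decayed to
  0.01 with Adam) is preserved as the `"paper"` preset for fidelity. At
  desk scale it diverges — as do all rates above ~3×10⁻³ we measured —
  so the `"practical"` preset (constant 10⁻³) is the test default.
* **Patch training.** Training samples random 64×64 crops (the network is
  fully convolutional; inference runs on full grids). Normalization
  (HU/1000 for images; line integrals scaled by their training maximum)
  is recorded on the model and reapplied at inference; a model without a
  recorded normalization, or applied to the wrong unit, is an error.
* **Input strategies.** Strategy iii (affected + NMAR channels) is the
  default, per the published finding of its superiority; strategies i/ii
  are selectable in `model_config`.

On the 200-pair desk corpus, DLI-MAR reproduces the qualitative method
ordering of the published Table-1-style comparison on its evaluation
split: mean RMSE ≈117 HU (affected) → ≈91 HU (NMAR) → ≈87 HU (DLI), for
both tested training seeds. The absolute numbers are not comparable to
any clinical figure — they depend on our phantoms, geometry and noise —
but the ordering and the sign of every comparison are the reproduced
findings.

**Projection-domain MAR at desk scale.** DLP-MAR is implemented with the
same machinery (input: affected sinogram; target: artefact-free
projections; FBP of the network output). At desk scale it does *not*
reach parity: halving the sinogram-domain MSE still leaves small
inconsistencies that the ramp filter amplifies into image-domain streaks,
and the evaluation RMSE lands above the affected baseline (≈154 vs
117 HU after 600 steps). This mirrors the published experience that the
projection domain is the more fragile route (it was ranked below the
image domain there, and chosen only for robustness among its own
variants); closing the gap would need substantially longer training and
consistency-aware losses, which is outside the desk budget. The module
surface, its contracts and its determinism are fully tested; the
improvement property is asserted for the image domain only.

## Metrics

Eq.-style definitions are implemented exactly as printed: RMSE over the
evaluation mask; PSNR with `Pk` the maximum over *both* images in the mask
(hence symmetric under swap; identical images report `Inf` and are
flagged); SSIM as a *global* (single-window) statistic from whole-mask
means, population variances and covariance with `k1 = 0.01`, `k2 = 0.02`.
Because those constants are not scaled by the dynamic range, the
comparison machinery affinely rescales both images to [0, 1] over the mask
(joint min/max) before applying the formula — the constants then act at
their intended magnitude; `ssim()` itself applies the raw formula, and a
sliding-window variant is deliberately not the default since the printed
equation has no window. The evaluation mask excludes the metal footprint
(metal pixels are reinserted, not corrected). Paired two-sided t tests
compare methods per metric; degenerate pairs (zero variance of
differences) report p = 1 with a flag.

## PET attenuation-correction module

CT images are converted to 511 keV μ-maps with the standard bilinear rule
(water scaling below 0 HU from 0.096 cm⁻¹; a shallower 5×10⁻⁵ cm⁻¹/HU
bone-like slope above; clip at 0.4 cm⁻¹). Emission data are parallel-beam
line integrals of an activity phantom multiplied by `exp(−∫μ)` along the
line of response (in PET the attenuation factor is independent of the
emission point), optionally Poisson-noised. Reconstruction is MLEM with
the attenuation factors in the system model — nonnegative, deterministic,
20 iterations by default. This deliberately replaces the clinical
OP-OSEM/TOF/PSF chain: the mechanism under study (μ-map errors → local
uptake bias) is dimension- and algorithm-agnostic, and the desk version
runs in seconds per case. Scatter is not simulated; published
scatter-fraction effects hinge on vendor single-scatter-simulation and
tail-fitting implementations and are out of scope.

The propagation experiment (`pet_case_bias`) assigns uniform body uptake
plus a 10 mm lesion of 4× contrast adjacent to the implant (16 mm toward
the body center), simulates emission through the *true* μ-map (from the
unreconstructed metal-inserted image), and reconstructs with μ-maps from
the reference CT, the affected CT and each corrected CT. Bias is the
lesion-VOI mean against the reference-map reconstruction. Two design
points, both measured before being fixed:

* The lesion is the VOI — the uptake-quantification target "in the
  affected region". A blind implant-centered disc VOI mixes in the metal
  core, whose pixels no method corrects (they are reinserted), and lets
  streaks luck-cancel over large areas; with it the affected-vs-corrected
  comparison becomes a coin flip on mild cases.
* The "matched μ-map" check is *self-consistency*, constructed so MLEM
  convergence cancels: a lesion-free uniform-body emission is
  reconstructed once from attenuated data with the matched map and once
  from unattenuated data with a zero map, and the regional means
  (implant-neighborhood VOI, body contour eroded by 3 px) are compared at
  50 iterations. Measured ≤0.1% on the fixtures. The naive alternatives
  both fail for reasons unrelated to map quality: comparing against the
  true activity is limited by hot-lesion contrast recovery and body-edge
  convergence (−1 to −3% even at 100 iterations), and comparing the true
  map against the reference-CT map can never reach 1% at desk resolution
  because the reference CT carries a clipped reconstruction halo around
  the metal (a 3–14% offset under either clipping convention).

On the 16-case clinical-cohort fixture the mean |lesion bias| falls from
≈12% (affected μ-map) to ≈4% (NMAR) with the corrected map better in
15/16 cases, the desk-scale analogue of the published
affected → NMAR → learned-MAR bias reduction pattern; those clinical
percentages themselves depend on private data and are not reproduction
targets.

## Numerical choices and degenerate inputs

FBP uses the equi-angular discrete ramp kernel with Hann apodization at
the Nyquist cutoff by default (pure ramp selectable); cosine
pre-weighting and inverse-square-distance backprojection follow the
standard full-scan formula. Filtering is done by FFT with power-of-two
zero padding. Fully-traced sinogram rows are replaced by the nearest
untraced row with a warning; traces touching a row edge extend the
nearest untraced value. Division floors: 10⁻¹² transmission clamp
(photon starvation), δ = 1 normalization offset, 10⁻¹² MLEM ratio guard.
All randomness (phantom texture, realization jitter, Poisson draws,
weight initialization, batch and patch sampling) flows from explicit
integer seeds, and every stochastic function restores the caller's RNG
state.

## Problem sizes

The test suite and acceptance script use: 20 images of 64×64 for the
projector-oracle comparison (40×72 geometry); a 256×256 disc on the full
1000×920 geometry for the round trip; 128×128 at 2 mm with a 192×160 fan
beam for all artefact fixtures; a 200-case corpus (165 train / 35 eval)
for learning experiments with 300 Adam steps per model; 16 fixture cases
with 20 MLEM iterations for the PET study. These sizes were chosen so a
complete from-scratch run of everything finishes in well under half an
hour on a single CPU while every comparison retains a comfortable margin
over its decision threshold.

## Known limitations

* 2D slices only; no cone-beam, helical, scatter or detector cross-talk
  modelling in CT, and no TOF/PSF/randoms in PET.
* The implant geometries and body templates are stylized; absolute HU
  artefact magnitudes depend on them and should not be read as clinical
  predictions. Passing tests demonstrate the *mechanisms* and the
  *ordering* of methods, not clinical performance.
* The attenuation table is an approximate re-tabulation; users needing
  exact cross sections should substitute their own CSV.
* The NMAR prior class map (air/water/bone) cannot represent
  intermediate-density tissue: mild-artefact cases sit below the method's
  error floor, and lung-like tissue in the prior is mapped to water.
* Projection-domain learning underperforms at desk scale (see above).
* The paper-scale network preset (20 layers, 400×400, lr 0.06→0.01) is
  provided for fidelity but is not exercised by the tests; at desk scale
  the published learning rate diverges.
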
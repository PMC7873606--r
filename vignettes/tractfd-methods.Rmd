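---
title: "Along-tract analysis of paired hemispheres: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract analysis of paired hemispheres: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tractfd` implements a bihemispheric along-tract analysis of a
corticospinal-tract-like bundle: diffusion-tensor FA/ADC maps,
constrained spherical deconvolution (CSD), probabilistic fiber-orientation
distribution (FOD) tractography, a four-step tract-specific apparent
fiber density (FD), and segment-wise hemispheric statistics. Because
clinical diffusion data cannot be redistributed, the package ships a
synthetic two-hemisphere diffusion phantom that emulates the acquisition
(b = 1000 s/mm^2, 40 gradient directions plus 3 b = 0 volumes, 2 mm
isotropic voxels) and injects a lateralized focal lesion with known
effect sizes over a known segment range, so that every stage of the
pipeline can be tested against ground truth.

## The phantom

Each subject carries two mirror-image curved tubular bundles (cubic
spline centerlines, 8 mm tube radius, ~72 mm arc length) running from a
caudal "medulla" end to a cortical end, embedded in an isotropic
background. Each bundle voxel mixes a cylindrically symmetric fiber
compartment (axial diffusivity 1.7e-3, radial 0.25e-3 mm^2/s — standard
healthy white-matter values) with a free-water-like isotropic
compartment (3.0e-3 mm^2/s). The diffusion-weighted signal is the
multi-tensor forward model
`S(g, b) = S0 [ f_iso exp(-b d_iso) + sum_k f_k exp(-b g' D_k g) ]`,
optionally degraded with Rician noise (default SNR(b0) = 30; channel
SD = S0/30).

The tract fiber fraction rises linearly along the tract,
`f_t(s) = 0.35 + 0.25 s` with `s` the arc fraction (caudal = 0), and
tapers over the outer 2 mm of the tube. The monotone ramp is deliberate:
along-tract FD estimates are judged by their rank correlation with this
profile, which requires a wide, strictly ordered dynamic range. An
optional transverse crossing bundle (radius 7 mm, centered mid-tract)
carries a fiber fraction equal to the local tract fraction (capped so at
least 5% isotropic signal remains). An equal-fraction orthogonal
crossing is the configuration in which the diffusion tensor is closest
to planar and FA is least interpretable, which is exactly the situation
the fixel-based metric is meant to survive; a weaker crossing barely
moves FA and cannot exercise the claim.

Free water (3.0e-3 mm^2/s) was chosen for the isotropic compartment so
that its signal is nearly extinguished at b = 1000 (about 5% of S0).
This keeps the estimated single-fiber response essentially fiber-only:
with a slower isotropic diffusivity, the response absorbs an isotropic
signal share per unit fiber, and any voxel whose isotropic fraction
deviates from the response's implicit ratio has its FOD lobes inflated
or deflated — a single-tissue-CSD artifact that would otherwise
contaminate the crossing-region FD. (Clinical implementations of this analysis use
multi-tissue CSD for the same reason; single-tissue CSD on the
free-water phantom is the documented simplification, with the response
estimation behind a configurable mask.)

### Lesion model

Ground truth per subject: one lesioned hemisphere (left/right with
equal probability) and one contiguous lesional segment range sampled
within [25, 95] (tumors do not occur in the most caudal fifth of the
tract). The injected effect sizes are defined **in metric space**: FA
decreases by `effect_fa` (default 0.10, absolute), ADC increases by the
fraction `effect_adc` (default 0.25), and the tract fiber fraction —
hence FD — decreases by the fraction `effect_fd` (default 0.20). The
defaults are repository choices of plausible peritumoral magnitudes
(clinical protocols do not quantify per-subject effect sizes) and are
flagged as such here. Inside the DWI simulation the compartment
parameters of each lesional voxel are calibrated numerically (a
coordinate search over an anisotropy-shrink factor and a diffusivity
scale) so that the zero-noise tensor-fit FA/ADC change by exactly the
injected amounts; the fiber-fraction change is exact by construction.
This makes parameter-recovery tests meaningful: the linear mixed model
is asked to recover a known, exactly injected difference.

### Two fixture tiers

* `scalar_mode_maps()` produces analytic FA/ADC/FD maps: FA and ADC are
  the zero-noise IRLS tensor fit of the exact forward signal (the value
  the imaging chain converges to as noise vanishes), FD is the
  ground-truth tract fraction. The full chain on the upsampled grid
  agrees with these maps to better than 1% (relative) at interior
  bundle voxels; near tube edges, tract ends, and the lesion boundary,
  signal interpolation mixes configurations and the comparison is not
  meaningful.
* `make_profile_cohort()` is the statistics fast path: it generates the
  long-format per-segment median table directly, using the zero-noise
  metric baselines along the centerline plus a per-subject random
  intercept (SD 0.02 FA, 4e-5 mm^2/s ADC, 0.03 FD) and residual
  per-segment noise (0.012, 3e-5, 0.018) that stands in for
  streamline-sampling and fit noise. These SDs are repository choices
  of realistic between-subject and within-tract variability. Passing
  statistical tests on this tier demonstrates calibration and recovery
  under a correctly specified noise model — not robustness to
  real-data pathologies (motion, distortion, segmentation error).

### Mirror symmetry

With zero effects and zero noise the two hemispheres are exact mirror
images *as tissue*. The raw gradient-wise signals are not voxel-wise
equal under mirroring (the gradient set itself is not mirror
symmetric), so the mirror invariant is asserted on reflection-invariant
scalar maps: FD mirrors exactly, FA/ADC mirror to ~1e-3 relative (the
log-linear tensor fit of a multi-exponential mixture retains a faint
direction dependence).

## Tensor stage

The tensor is fit by iteratively reweighted linear least squares:
iteration 0 is the ordinary log-linear fit, then each measurement is
reweighted by its squared model-predicted signal (2 iterations by
default; published protocols rarely state an iteration count, so the
default is exposed in the function signature). Signals at or below zero
are clamped to `1e-6 * max(signal)` before the log. Negative
eigenvalues from noise are retained in the FA formula but flagged
per-voxel rather than clipped, matching common tool behavior and
avoiding bias. ADC is reported in mm^2/s throughout.

## CSD stage

The single-fiber response is estimated from ground-truth core bundle
voxels (within 2 mm of a centerline, away from tract ends and crossing):
per voxel, the gradient directions are rotated so the principal tensor
axis maps to +z, the b0-normalized signal is projected onto the zonal
harmonics, and voxel-wise coefficient vectors are averaged. The FOD is
fit at `lmax = 8` (45 coefficients, a standard choice for 40-direction
data; super-resolved, so the non-negativity constraint supplies the
missing rank — a tiny ridge, 1e-8 of the design scale, keeps the
degenerate near-isotropic case solvable). The constraint set is the 321
hemisphere vertices of a three-times subdivided icosphere (642
vertices, antipodally exact); amplitudes below
`tau * mean(initial amplitude)` (tau = 0.1) are penalized with weight
`lambda^2` (lambda = 1) and the fit iterates to a stable constraint set
(at most 50 iterations; non-convergence is flagged, never silent).
The spherical-harmonic convention (real, symmetric, even orders,
`m = -l..l` with sin/cos pairs, orthonormal, no Condon-Shortley phase)
is fixed package-wide and named `tractfd-rsh-even-1` in FOD sidecars,
because silent basis mismatch is the dominant interoperability failure
in this domain.

## Tracking stage

Probabilistic tracking runs on the 1.3 mm upsampled grid. Streamlines
grow bidirectionally from uniform random points inside the seed ROI (a
3 x 3 x 3 acquisition-voxel patch near the cortical end, the phantom's
stand-in for a TMS-derived motor seed). At each 0.65 mm step (half a
voxel), 12 candidate directions are drawn uniformly inside the
curvature cone (angle `2 asin(step / 2 r_c)` with a 1 mm
curvature-radius floor, ~38 degrees) and one is chosen with probability
proportional to the product of FOD amplitudes at the midpoint and
endpoint of the candidate step. This two-point arc scheme is a
documented approximation of second-order integration-over-arcs
tracking; the exact arc-wise candidate scoring of the published
second-order algorithm is proprietary detail this package does not
claim to reproduce. Termination: no candidate clears the
0.1 amplitude cutoff, the track leaves the volume, or it reaches the
100x-voxel length cap (capped tracks are discarded). A candidate
streamline is accepted iff its length is at least 5x the voxel size and
it intersects the caudal inclusion slab; generation repeats to the
5,000-streamline target with a 50x attempt ceiling (reaching the
ceiling returns the partial set with a warning). On the default
phantom the acceptance rate is ~99%, so the target is met four orders
of magnitude below the ceiling. All randomness comes from R's RNG:
identical seeds give bit-identical tractograms.

Streamlines overshoot the tube end caps by a few millimetres before the
partial-volume FOD falls below the cutoff — the same behavior real
tractography shows at gray-matter terminations. End segments (1-2 and
99-100) are therefore noisy, and along-tract positions are compressed
by a few segments relative to the anatomical arc; tests that relate
segment indices to ground-truth arc positions use interior segments.

## Tractometry and fixel FD

Each accepted streamline is co-oriented caudal-first (nearest end to the
inclusion-slab centroid), resampled to 100 equal-arc-length points
(segment 1 = caudal, 100 = cortical), and FA/ADC maps are sampled by
trilinear interpolation (nearest-voxel lookup is the main alternative;
trilinear is the documented choice). Per segment and
hemisphere the median over the 5,000 streamlines is kept; segments with
no streamline support are flagged missing and excluded listwise —
imputation would fabricate signal.

The along-tract FD follows the four-step procedure: (i) fixel
tract-density imaging — each streamline step is assigned to the
angularly nearest fixel of its voxel within 45 degrees; (ii) fixels are
thresholded by traversal count (default `max(1, 5%` of the per-voxel
maximum`)`; no standard value exists for this threshold, so the default
is exposed); (iii) the mean FD of retained fixels becomes a scalar map
(voxels with no retained fixel are missing, not zero); (iv) that map is
interpolated at the 100 resampled points. Fixels come from watershed
segmentation of the FOD on the 642-vertex mesh: local maxima seed
lobes, every positive vertex ascends to its maximum, the lobe FD is the
quadrature integral `sum(A(v) w_v)` (vertex weights = one third of
adjacent spherical-triangle areas), sub-threshold maxima (below 10% of
the global peak) merge into their strongest neighbor, and antipodal
lobe pairs are reported once as an axis whose direction is the
amplitude-weighted mean over the lobe pair (sub-mesh accuracy, ~0.1
degree on single-fiber voxels) and whose FD is the mean of the paired
lobe integrals.

## Statistics

The long-format table has one row per subject, hemisphere (0 = healthy,
1 = pathological), segment (1-100) and metric; a complete 65-subject
cohort gives 13,000 rows per metric. Three analyses are provided:

* **Hemisphere LMM** — `value ~ hemisphere + (1 | subject)`, REML via
  lmerTest, Satterthwaite p-values, Wald 95% CI, on all segments and on
  the peritumoral subset (each subject contributes its own flagged
  segments). Residual diagnostics (fitted/residual pairs, QQ data) are
  returned as data.
* **Segment-wise paired t-tests** — pathological vs healthy per-subject
  values at each segment, two-sided, compared against the
  Bonferroni-adjusted alpha 0.05/100 = 0.0005. Segments with fewer than
  3 complete pairs or zero difference variance are untestable (NA),
  never "significant at p = 0". The pairing unit (subjects' per-segment
  medians) is the documented pairing unit.
* **Detection** — a segment is predicted tumorous iff it is
  Bonferroni-significant *and* |Cliff's delta| >= 0.474 (the
  conventional large-effect threshold; delta computed by exhaustive
  pair comparison). Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
  with zero-denominator rates flagged undefined. The interface
  summaries convert the "three voxels" interface width into segments
  via the mean inter-point arc spacing, since voxel and segment units
  differ.

On null phantoms the familywise false-positive probability of the
Bonferroni procedure is ~0.049 per metric (measured 0.043 over 600
cohort-metric families at n = 10), and an injected hemispheric FA
deficit of -0.05 is recovered inside the LMM's 95% CI in 20/20 seeded
cohorts. Cohort-level coefficients and detection rates measured on
clinical patient data are properties of that data and are not
reproduction targets for a phantom; what the phantom establishes is
calibration, parameter recovery, the direction of the peritumoral
effects (FA and FD down, ADC up), and the crossing-fiber specificity
of FD.

## Problem sizes and determinism

Test and acceptance runs use: one-subject chains at the full default
grid (40 x 48 x 40 at 2 mm, upsampled to 62 x 74 x 62 at 1.3 mm) with
5,000 streamlines per hemisphere for the tracking checks and 800-1,500
streamlines for chain-level property checks; 200 null cohorts of 10
subjects and 20 recovery cohorts of 20 subjects on the statistics fast
path. A master seed derives all per-subject and per-hemisphere seeds
(noise seeds are drawn once per cohort from the master seed; tracking
seeds are `seed + 7919 * subject + 13 * hemisphere`), so every figure
in the outputs is reproducible bit-for-bit given the seed, up to BLAS
rounding in the mixed-model fits.

## Known limitations

* Single-tissue CSD with a ground-truth response mask; no multi-tissue
  decomposition, no GM/CSF responses, no FOD group template.
* The phantom has no scanner artifacts; the preprocessing slots
  (denoising, Gibbs, motion/eddy/susceptibility, bias field,
  registration) are pass-throughs by design, so the pipeline's
  robustness to those artifacts is untested here.
* Fixel FD in crossing regions carries a ~10-12% negative bias from
  lobe overlap at lmax 8; the specificity claim is about rank
  correlation along the tract, not absolute accuracy.
* Tracking is a two-point approximation of arc-wise probabilistic
  tracking; the step-size and angle defaults use the documented
  derivations above and are not claimed to equal any other tool's
  unpublished defaults.
* Fiber cross-section (FC), FDC, anatomically constrained tracking,
  SIFT filtering and whole-brain fixel statistics are out of scope.
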
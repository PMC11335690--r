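---
title: "Glymphatic MRI markers: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glymphatic MRI markers: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`glymkit` quantifies two indirect markers of glymphatic function from
clinically standard MRI — the enlarged perivascular space (ePVS) burden and
the DTI-ALPS index — and implements the longitudinal statistics of a
two-visit injury study around them. This vignette is the package's account
of the underlying models, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate,
and the numerical decisions a maintainer should know about.

## 1. ePVS burden

### Model

Perivascular spaces are CSF-filled sheaths around penetrating vessels:
tubular, dark on T1w, bright on T2w. The pipeline is

1. **Normalisation** — each channel is divided by its white-matter median
   (`normalize_intensity()`). The median, not the mean, because the WM mask
   itself contains the PVS voxels being sought.
2. **EPC** — the enhanced perivascular contrast image is the guarded ratio
   `T1w / max(T2w, eps)` (`compute_epc()`). The ratio compounds the
   opposite-signed contrasts of the two channels, so PVS voxels are
   strongly hypointense against WM (a PVS voxel at T1w 0.2 / T2w 2.0 has
   EPC 0.1 against WM at 1.0).
3. **Vesselness** — multiscale Frangi filtering in dark-tube polarity
   (`frangi_vesselness()`): with Hessian eigenvalues ordered
   `|l1| <= |l2| <= |l3|`, the tube score combines plate suppression
   (`Ra = |l2|/|l3|`), blob suppression (`Rb = |l1|/sqrt(|l2 l3|)`), and
   structureness (`S`, the Frobenius norm), maximised over scales; the
   score is zeroed where `l2 > 0` or `l3 > 0` (a bright tube's
   cross-section must curve downward in both transverse directions).
4. **Segmentation** — voxels with vesselness `>= h`, grouped at
   26-connectivity, keeping components of at least 9 voxels
   (`segment_epvs()`).
5. **Burden** — `100 * ePVS voxels / region voxels` per region
   (`compute_burden()`); the voxel volume cancels.

### Parameters

| parameter | default | rationale |
|---|---|---|
| working spacing | 0.7 mm | sub-voxel tubes at 1 mm acquisition become resolvable; 9 voxels is then ~3 mm³ |
| Frangi scales | 0.35, 0.7, 1.05 mm | spans sub-voxel to ~1.5-voxel tube radii on the working grid |
| alpha, beta | 0.5, 0.5 | the filter's standard discrimination constants |
| c | auto = half the maximal Hessian norm, per scale | adapts to the image's contrast scale; see numerical notes |
| h (WM / BG) | 2e-7 / 3e-7 | conventional absolute defaults; meaningful only on the vesselness scale of the implementation that produced them |
| min cluster | 9 voxels (~3 mm³) | suppresses speckle while keeping short tubes |
| connectivity | 26 | tubes at arbitrary angles touch diagonally |

Absolute vesselness values are **not comparable across implementations**:
the shipped `h` defaults are tied to whatever scaling produced them, which
is why the package treats `calibrate_threshold()` — bisection of `h`
against a known burden on a noise-free phantom — as the supported route to
quantitatively meaningful thresholds. Calibration returns an absolute `h`
that transfers to sibling data *provided the vesselness scaling is frozen*:
`frangi_vesselness()` records the per-scale `c` it used (`c_used`
attribute), and pipelines re-use it (`frangi_params(c = ...)`). Without
freezing, the auto-`c` adapts to each image's own maximal Hessian response
and silently rescales the map.

### Boundary handling

A Frangi response exists wherever intensity curves, including at every
tissue interface. The segmentation support is therefore eroded by the
truncated-kernel support radius of the largest scale (6 voxels at the
defaults; `boundary_erosion = "auto"`), which makes the response in flat
tissue *exactly* zero — kernels are renormalised to zero-sum, and a
sub-floor guard removes the ~1e-16 floating-point residue — so a tube-free
noiseless phantom segments to exactly 0% burden at any positive threshold.
The burden denominator always uses the uneroded region. No further
periventricular exclusion is applied.

## 2. DTI-ALPS

### Model

The diffusion signal follows the kurtosis extension of the tensor model:

```
log S(b, g) = log S0 - b * g'Dg + (1/6) * b^2 * MD^2 * W(g)
```

with `D` the diffusion tensor, `MD = tr(D)/3`, and `W(g)` the fourth-order
kurtosis tensor contracted with the direction. `fit_dki_lls()` fits all 22
parameters jointly and linearly in the log-signal (the `b^2` coefficient
tensor `V = MD^2 W` is linear; `W` is recovered by dividing by the fitted
`MD^2`); `fit_dti_wls()` is the single-shell tensor-only estimator. Both
use signal-squared weighted least squares: a first pass weighted by the
squared *observed* signal (so clipped or floored measurements carry no
leverage), then one reweighting by the squared fitted signal.

The ALPS index samples the diagonal maps (tensor components in the volume
frame, **not** eigenvalues) in four 16 mm² axial square ROIs — bilateral
projection-fiber (principal axis inferior–superior) and association-fiber
(anterior–posterior) — and forms
`mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`, each term first
averaged over left and right. Averaging sides *before* the ratio is a
choice; forming per-side indices first and averaging after is available
(`side_average = "per_side"`) and identical for mirror-symmetric fields.
ROI "drawing" is replaced by configurable world-coordinate centres with
mirror symmetry enforced on the lattice; slab thickness defaults to one
axial slice.

### Rician noise and the noise floor

At the outer shell (b = 2500) along high-diffusivity axes the true signal
sits *below* the magnitude-noise floor at realistic SNR (at SNR 30 and
D = 1.5e-3, per-measurement SNR ~0.7). A log-domain fit then reads the
floor as kurtosis and inflates D by ~10%. The package's correction
(`rician_floor_correct()`) uses the exact second-moment identity
`E[M^2] = nu^2 + 2 sigma^2`: sigma is estimated from the two b = 0 volumes
(half the variance of their voxelwise difference), the second moment is
pooled over a cubic neighbourhood (radius 2 by default in `run_alps()`),
and the corrected amplitude `sqrt(max(<M^2> - 2 sigma^2, floor))` feeds the
weighted fit. Pooling is what makes the correction effective: it shrinks
the variance of the corrected amplitude by the neighbourhood size, which is
what drives the residual bias of the downstream log-fit. The cost is
partial-volume blurring near region boundaries, so the phantom geometry
keeps a homogeneous margin of at least the pooling radius around each ROI;
on real data the radius should not exceed the homogeneous extent of the
ROI's surroundings. On noiseless data the sigma estimate is 0 and the
correction is the identity, so exactness results are unaffected.

With this correction the full pipeline recovers analytic ALPS truths of
1.2 and 1.5 with about 1% mean error over 50 Rician replicates at SNR 30,
and to 1e-9 noiselessly.

### Negative eigenvalues and failed fits

Fitted tensors with a negative eigenvalue are counted and reported
(`n_negative_eigen`) rather than silently clamped; non-positive signals are
clipped to a small epsilon with a warning count (`n_clipped`). Single-shell
input to the kurtosis fit is an error that points to `fit_dti_wls()`.

## 3. Synthetic data

### Structural phantoms

Block-compartment "head": a WM slab containing a central CSF ventricle and
two basal-ganglia blocks, wrapped in a GM shell; straight cylindrical PVS
inclusions with CSF-like contrast are placed in WM and BG. Straight
cylinders keep the ground-truth volume analytic; rendering uses 3x
supersampling with antialiased (linear-ramp) subvoxel coverage, which
integrates the cross-section to second order — a radius-1 mm, length-10 mm
tube's rendered volume is within 2% of pi r^2 L. The whole tube must lie
inside a margin-eroded region interior (WM margin 6 voxels = the
segmentation support erosion; BG margin 2, because the region is thin —
BG burden is deliberately the less reliable measurement, as it is in
practice). True burden is computed from the supersampled analytic volume
and is exact by construction.

What the phantom does **not** emulate: curved or tapering PVS, anatomy
(no template brain), bias fields, motion, partial-volume at tissue
interfaces beyond block boundaries. Passing tests therefore show the
pipeline is correct *given* tubular PVS and aligned inputs, not that
segmentation accuracy transfers to arbitrary patient data.

### DWI phantoms

Region-labelled grids with one (D, W, S0) triple per region, evaluated
through the forward model above; the generator rejects kurtosis values for
which the signal is no longer decaying at the maximal b (the model's
validity bound). Noise is Rician by default (magnitude of a complex
Gaussian with per-channel sd `S0/snr`), Gaussian and noiseless modes exist
for analytic checks. `make_alps_tensor_field()` builds the ALPS geometry —
projection blocks with principal axis along z at x = +-8 mm, association
blocks along y at x = +-20 mm, on a 40 x 32 x 12 grid at 2 mm — with blocks
defined by world-coordinate extents so the left/right pair is exactly
mirror-symmetric on the lattice, and each ROI keeps >= 4 mm of homogeneous
margin (the pooling requirement above). The attached ground truth is the
closed form `((Dxx_proj + Dxx_assoc)/2) / ((Dyy_proj + Dzz_assoc)/2)`.

The default acquisition scheme is 2 b = 0 volumes plus 45 directions at
b = 1000 and 90 at b = 2500 s/mm², with directions from a deterministic
golden-angle spiral (no RNG in the scheme itself).

### Synthetic cohort

`make_synthetic_cohort()` draws a control group (one visit) and an mTBI
group (two visits) with the dependency structure the statistics are built
to detect: log WM-ePVS increasing in age, ALPS decreasing in age, a
Poisson symptom count linked to WM-ePVS, a logistic memory-problem outcome
on education, CT/MRI findings and the two markers, a BG burden with
subject random intercept and a visit effect, and a bivariate-normal
(ALPS ratio, PSQI ratio) pair with correlation -0.42. Defaults are
calibrated so the control marginals sit near plausible population values
(WM-ePVS 0.40 +/- 0.18%, ALPS 1.51 +/- 0.12, age uniform 18-60); they are
generator settings, not estimates of any dataset. RPQ items (22 ratings
0-4) are reconstructed from the drawn counts under the constraints the
score derivations assume: a symptom is "present" at rating >= 2, the
memory flag *is* the memory item's presence flag, and the total is the
plain sum (0-88); the alternative convention of zeroing ratings of 1 is
available but off. Follow-up values are baseline times the drawn ratio, so
the ratio-correlation analysis recovers its target by construction.

Every generator is a pure function of its spec, seed included; the
caller's RNG stream is left untouched.

## 4. Statistical battery

Welch (unequal-variance) t-tests with Satterthwaite df; Pearson chi-squared
without continuity correction; Pearson correlations with the t-transform
p; covariate-adjusted associations by OLS, reporting the marker slope and
the partial correlation (the signed root of the marker's partial R²);
the visit effect by a REML random-intercept model (`lme4`) with Wald z
tests, boundary fits reported rather than errored; stepwise logistic
selection bidirectional by AIC from the intercept-only model (the
criterion is a fixed design choice); ROC/AUC as the tie-corrected pairwise
concordance probability (Mann-Whitney identity); AUC model comparison by
paired percentile bootstrap over subjects (normal p on the bootstrap SE;
seed mandatory; single-class resamples redrawn and counted);
Benjamini-Hochberg FDR with one family per analysis block. Under null
generators the bootstrap comparison and the adjusted association hold
their nominal 5% size within +/-2 points (tested at 500 and 2000
replicates).

## 5. Numerical notes

* **Gaussian-derivative kernels** are sampled, truncated at 4 sigma, and
  renormalised so the response to the matching monomial is exact and the
  response to constants is exactly zero; a relative structureness floor
  (1e-10 of the image range) removes the floating-point residue so flat
  regions are vesselness-0, not vesselness-1e-17.
* **Eigenvalues** of the many symmetric 3x3 Hessians/tensors use the
  closed-form trigonometric solver, vectorised over voxels, with an
  isotropic-matrix guard.
* **Connected components** use iterative minimum-label propagation on the
  mask's bounding box; equality with a breadth-first-search oracle is part
  of the test suite for all three connectivities.
* **Resampling** keeps the input's world origin and direction, covers the
  voxel-centre span, and clamps gather coordinates, so linear ramps
  round-trip and linear interpolation cannot overshoot.
* **Ties and determinism**: component labels are ordered by first linear
  index; threshold comparison is `>= h`; all bootstrap and simulation
  paths take explicit seeds, and two demo runs with one seed produce
  byte-identical metric files.

## 6. Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at deliberately modest
sizes chosen as the package's own validation design: 72³ structural
phantoms at 0.7 mm (five burden levels, 8-40 tubes), 40 x 32 x 12 DWI
phantoms at 2 mm with the full 137-volume scheme (50 Rician replicates),
100 random 32³ maps against the flood-fill oracle, cohorts of 2,000 for
coefficient recovery and 10,000 for the ratio-correlation target, and
500-2,000 replicates for the size checks. These are large enough to pin
each property well inside its tolerance while keeping a full run in the
minutes range.

## 7. Known limitations

* Registration, segmentation of real anatomy, denoising, and eddy/motion
  correction are upstream: the package assumes co-registered inputs and
  supplied label maps.
* The BG-ePVS measurement is structurally less reliable than WM-ePVS
  (thin region, boundary erosion), mirroring its status in practice.
* Absolute ePVS thresholds do not transfer across vesselness
  implementations; use the calibration route.
* The second-moment Rician correction assumes local homogeneity within
  the pooling radius and at least two b = 0 volumes.
* The DKI fit's validity ends where the quadratic model stops decaying in
  b; the generator enforces this bound, real data do not.
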
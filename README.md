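# glymkit

Glymphatic function cannot be imaged directly in humans without intrathecal
contrast, so two indirect MRI markers have become standard: the **enlarged
perivascular space (ePVS) burden**, a structural measure of fluid-filled
sheaths around penetrating vessels segmented from T1w/T2w images, and the
**DTI-ALPS index**, a diffusion measure of water mobility along the
perivascular channels that flank the medullary veins at the level of the
lateral-ventricle body. `glymkit` implements both markers and the
longitudinal statistical analysis built on them — the design used in
two-visit mild-TBI studies (an acute visit around 14 days post-injury and a
chronic visit at 6–12 months, against a single-visit control group) — and
ships synthetic phantom and cohort generators with analytic ground truth so
that every stage is testable without patient data.

## The two markers

**ePVS burden.** After white-matter-referenced intensity normalisation of
the co-registered T1w and T2w volumes, an enhanced perivascular contrast
(EPC) image is formed as the guarded ratio T1w/T2w, on which PVS voxels
(CSF-like: dark T1w, bright T2w) are strongly hypointense. A multiscale
Frangi vesselness filter — the Hessian-eigenvalue tubularity measure

&nbsp;&nbsp;&nbsp;&nbsp;V<sub>σ</sub> = (1 − e<sup>−R<sub>A</sub>²/2α²</sup>) · e<sup>−R<sub>B</sub>²/2β²</sup> · (1 − e<sup>−S²/2c²</sup>),&nbsp;&nbsp; V = max<sub>σ</sub> V<sub>σ</sub>

with R<sub>A</sub> = |λ₂|/|λ₃| (plate suppression), R<sub>B</sub> =
|λ₁|/√|λ₂λ₃| (blob suppression) and S the Hessian norm — is run in
dark-tube polarity at scales {0.35, 0.7, 1.05} mm on a 0.7 mm working grid.
The binary ePVS mask applies a vesselness threshold *h* with a minimum
connected-component size of 9 voxels (~3 mm³, 26-connectivity), and the
burden is

&nbsp;&nbsp;&nbsp;&nbsp;ePVS burden = 100% × ePVS volume / region volume

for whole-brain white matter (WM-ePVS) and basal ganglia (BG-ePVS).
Absolute vesselness values are implementation-specific, so the package also
provides `calibrate_threshold()`, which fixes *h* on a noise-free phantom
with known burden.

**DTI-ALPS.** From a two-shell diffusion acquisition (2 b=0, 45 directions
at b=1000, 90 at b=2500 s/mm²), a joint log-linear diffusion-kurtosis fit
(22 parameters per voxel; signal-weighted least squares with a moment-based
Rician noise-floor correction) yields the diffusion tensor, whose diagonal
maps Dxx/Dyy/Dzz are sampled in four 16 mm² square ROIs: bilateral
projection-fiber ROIs (principal axis inferior–superior) and bilateral
association-fiber ROIs (anterior–posterior). With each term first averaged
over the left and right ROIs,

&nbsp;&nbsp;&nbsp;&nbsp;ALPS = mean(Dxx<sub>proj</sub>, Dxx<sub>assoc</sub>) / mean(Dyy<sub>proj</sub>, Dzz<sub>assoc</sub>)

is the ratio of diffusivity along the perivascular (left–right) axis to the
fiber-perpendicular diffusivities; 1 means no preferential perivascular
diffusion.

**Statistics.** Group comparisons (Welch t, chi-squared), age correlations
(Pearson), age/sex-adjusted marker–symptom associations with partial
correlations, a random-intercept linear mixed model for the visit effect,
longitudinal ratio (6–12Mon/14Day) correlations, stepwise (AIC) logistic
prediction of chronic memory problems with paired-bootstrap ROC/AUC model
comparison, and Benjamini–Hochberg FDR correction.

## Worked example

```r
library(glymkit)

## a diffusion phantom whose analytic ALPS index is 1.5, with Rician noise
spec <- make_alps_tensor_field(1.5e-3, 1.0e-3, 1.5e-3,   # projection Dxx,Dyy,Dzz
                               1.5e-3, 1.5e-3, 1.0e-3,   # association Dxx,Dyy,Dzz
                               snr = 30, noise_model = "rician", seed = 1)
ph <- make_dwi_phantom(spec)
res <- run_alps(ph$dwi, ph$gtab, ph$mask, ph$spacing, attr(spec, "roi_centers"))
res
#> <alps_result> ALPS index = 1.4899
#>   Dxx proj 1.492e-03  Dxx assoc 1.494e-03  Dyy proj 9.964e-04  Dzz assoc 1.008e-03 (mm^2/s)

## a structural phantom with known PVS content, segmented end to end with a
## threshold calibrated against the analytic burden
phs <- make_structural_phantom(structural_phantom_spec(
  pvs_count = c(WM = 24, BG = 0), noise_sigma = c(t1w = 0, t2w = 0), seed = 103))
base <- run_epvs(phs$t1w, phs$t2w, phs$labels, regions = "WM")
h <- calibrate_threshold(base$vesselness, region_mask(phs$labels, "WM"),
                         phs$true_burden[["WM"]])
seg <- run_epvs(phs$t1w, phs$t2w, phs$labels, regions = "WM",
                frangi = frangi_params(c = attr(base$vesselness, "c_used")),
                seg_params = list(WM = segmentation_params(h = as.numeric(h))))
c(true = phs$true_burden[["WM"]], estimated = seg$regions$WM$burden_pct)
#>      true estimated
#> 0.2732634 0.2732371
```

The measured ALPS of 1.4899 sits within 0.7% of the analytic truth 1.5
despite SNR 30 magnitude noise; the calibrated threshold (h = 0.242 on this
map's vesselness scale) reproduces the analytic white-matter burden to four
decimals on a noise-free phantom.

A full synthetic study — cohort generation, per-subject phantom
measurement, and the whole statistical battery — runs with

```r
report <- run_demo(seed = 1, out_dir = "demo_out")
```

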
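---
title: "Motion-immune first-pass CT myocardial perfusion: model, phantom and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-immune first-pass CT myocardial perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifpa)
```

## The measurement problem

Dynamic CT perfusion estimates myocardial blood flow from the rise of the
myocardial CT number (in Hounsfield units, HU) as an iodinated contrast
bolus transits the heart. Classical dynamic techniques subtract scans
voxel-by-voxel across many heart beats, so beat-to-beat variation and
imperfect breath-holding force image registration — and registration itself
alters CT numbers, biasing the perfusion estimate (typically downward).

`mifpa` implements a two-volume first-pass estimator that sidesteps
registration entirely. Only two whole-heart scans are used: **V1** at the
base and **V2** at the peak of the aortic enhancement. The key observation
is that before contrast arrives the myocardium is nearly homogeneous, so
the *spatial arrangement* of V1 carries no information the estimator needs:
V1 enters only through two scalars — the mean aortic blood-pool value and
the mean lateral-wall (myocardial) value. Any rigid or non-rigid motion of
V1 that preserves those two scalar samples cannot change the result. That
is the motion-immune (MI) property, and it is exercised literally in the
test suite (a random permutation of all V1 myocardial voxels outside the
ROI leaves the MI map bit-identical).

## The model

Treating the whole left-ventricular myocardium as one compartment with no
contrast outflow during the first pass, the average perfusion is

$$P_{AVG} = M_T^{-1}\, C_{IN}^{-1}\, \frac{dM_C}{dt},$$

where $dM_C/dt$ is the rate of contrast-mass entry, $C_{IN}$ the average
incoming aortic blood-pool contrast concentration and
$M_T = n\, v_{vox}\, \rho$ the tissue mass ($n$ myocardial voxels of volume
$v_{vox}$, density $\rho$). Because iodine mass and enhancement are related
by one physical constant that cancels in the ratio, everything is carried in
HU: the integrated V2 enhancement is the sum of HU over the V2 myocardium
segmentation, the integrated V1 enhancement is approximated as the V1
lateral-wall mean times $n$, and their difference per unit time
($\Delta t = t_{V2} - t_{V1}$, converted to minutes) realizes $dM_C/dt$ up
to the cancelled constant. Algebraically,
$P_{AVG} = \Delta HU_{AVG} / ((\Delta t/60)\, C_{IN}\, \rho)$.

The voxel-wise map scales the average by a perfusion ratio map with
mask-mean exactly 1:

$$P_{MI} = P_{AVG} \cdot \frac{\Delta HU^*}{\Delta HU_{AVG}}, \qquad
\Delta HU^* = HU_{V2}(v) - \overline{HU}_{V1}.$$

The comparison estimator ("motion-susceptible", MS) replaces
$\Delta HU^*$ with the voxel-wise difference $HU_{V2}(v) - HU_{V1}(v)$,
which is correct only when V1 and V2 are aligned. The two estimators
coincide exactly whenever V1 is spatially homogeneous over the myocardium —
the model's second assumption; the first is that the V1 and V2 myocardial
volumes are equivalent.

Two caveats the estimator inherits from the model: $\Delta HU_{AVG} \le 0$
means the pair does not bracket a first-pass inflow (the code warns);
negative map voxels caused by noise are retained in all quantitative
outputs so that region means stay unbiased (clamping is a display concern,
not a measurement one).

## The input function C_IN

The phrase "average aortic enhancement between V1 and V2" admits two
readings, both implemented:

* **Endpoint convention** (`compute_c_in`, the two-scan default):
  $(ao_{V1} + ao_{V2})/2 - \text{baseline}$ with the baseline defaulting to
  the V1 aortic value, i.e. $(ao_{V2} - ao_{V1})/2$. Exact when the aortic
  upslope is linear between the two scans.
* **Series average** (`compute_c_in_series`, used by the study pipeline):
  the mean of the per-scan aortic blood-pool values from V1 to V2 inclusive,
  above the V1 value. When a dynamic series was acquired anyway — as in the
  validation design this package replicates — this tracks the true
  time-average of a curved upslope much more closely; on a linear upslope
  the two conventions agree exactly.

The choice is logged by the CLI, and both reduce to the same number in the
phantom's linear-ramp oracle configuration.

## Segmentation inputs

The myocardium mask is an *input* (in practice it comes from a clinical
workstation segmentation of V2); the package supplies ground-truth masks
from its phantom. Two small segmentation tools are provided:

* `region_grow`: volumetric region growing for the aortic blood pool. The
  inclusion test uses the fixed seed HU, not a running mean, so the result
  is order-independent and deterministic. Default tolerance 150 HU,
  6-connectivity, both configurable.
* `sample_roi_mean`: the V1 lateral-wall sample — a 5 mm sphere (no ROI
  size is prescribed by the validation study; the radius is configurable
  and should be sensitivity-checked on new data), clipped to the V2
  myocardium mask, with a robust trim that keeps voxels within ±15 HU of
  the ROI median. The trim is a symmetric truncation of the CT noise
  (hence unbiased) whose purpose is to reject voxels that a displaced V1
  would sample from enhanced cavity blood or extra-cardiac tissue.

On V1 the blood pool has almost no contrast against surrounding soft
tissue, so seeded region growing on V1 is ill-posed. The pipeline default
samples the V1 aorta through the V2-grown aortic mask eroded by 5 mm,
which is robust to inter-scan displacement smaller than the erosion
radius; per-volume seeded growing remains available
(`v1_aorta = "region_grow"`) for operator-placed seeds.

Voxel indices are 1-based `(i, j, k)` throughout (the R convention); world
units are mm, volumes in mL, acquisition times in seconds (converted to
minutes only inside the perfusion math).

## The synthetic study

No imaging data are deposited with the validation study this package
replicates, so `generate_study` builds a digital stand-in for its swine /
microsphere design — the generator is first-class, tested code, and its
defaults *are* the study conditions:

* **Geometry**: half-ellipsoidal LV shell (outer radii 28×28×44 mm, 10 mm
  wall) with a blood-filled cavity and a cylindrical aortic segment, on a
  96³ grid at 1 mm isotropic spacing. The voxelized shell masses 51.8 g
  against the 52.1 g target (the reported mean LV mass). The grid size is
  chosen so a whole study runs on a desk machine in well under a minute;
  the scanner's native 0.43×0.43×0.50 mm voxels appear in unit tests of
  the volume arithmetic.
* **Territories**: two 180° angular sectors about the long axis — anterior
  = LAD (the stressed, stenosed vessel), lateral = LCx (rest). Ground-truth
  perfusion is piecewise constant per territory: LCx rest 0.87 mL/min/g;
  LAD hyperemic perfusion mapped from the stenosis grade, FFR
  1.0/0.9/0.8/0.7/0.6 → 3.5/2.75/2.0/1.25/0.5 mL/min/g. The sweep brackets
  the reported territory means (LAD 2.62, LCx 0.87 mL/min/g) and makes the
  lowest grade functionally significant (stress perfusion < 1.0).
  Per-subject heterogeneity is lognormal (σ_log = 0.12), with a small
  per-acquisition jitter on the rest territory.
* **Enhancement**: a gamma-variate arterial input function
  $A\,u^{\alpha} e^{\alpha(1-u)}$, $u = (t-t_0)/t_p$ (A = 400 HU, α = 3,
  t₀ = 4.5 s, t_p = 5.5 s), peaking at exactly $A$; a linear-ramp mode
  serves as the analytic oracle. Myocardial voxels accumulate
  $\rho P \int AIF /60$ with no outflow — the forward model refuses times
  beyond the peak plus a margin, where a washout term would be needed.
  Cavity enhancement leads aortic enhancement by 1.5 s (contrast reaches
  the ventricle before the aortic root); this anatomical ordering is what
  makes the MS estimator underestimate under motion, because a mask
  transferred onto a displaced V1 samples already-enhanced cavity blood.
  Baselines: tissue 50 HU, blood 45 HU, surrounding soft tissue 30 HU.
* **Acquisition**: 20 scans at 0.822 s intervals (one per beat at 73 bpm).
  V1/V2 are selected systematically from the aortic curve — the last scan
  at or below 5% of the peak, and the scan at the peak — giving a V1–V2
  delay of 4.93 s, inside the reported 4.7 ± 1.2 s, and an average
  myocardial enhancement change of ~25–30 HU at the configured flows.
* **Noise and motion**: independent Gaussian CT noise (σ = 10 HU) per
  scan; a random rigid displacement per scan (translation ≤ 4 mm, rotation
  ≤ 3°, drawn isotropically), expressed relative to the V2 frame since the
  myocardium mask is segmented from V2 and only relative pose matters.
  An optional Gaussian blur for gantry effects is deliberately omitted;
  resampling uses trilinear interpolation (nearest-neighbour available).

What the phantom does **not** emulate: beam hardening, partial-volume
averaging at real tissue interfaces, non-rigid deformation, washout,
anatomy beyond an LV shell and aorta, and the biological variability of
microsphere reference measurements. Passing tests therefore demonstrate
the estimator's mathematical properties and its behaviour under rigid
inter-scan motion with realistic noise — not clinical performance.

## Virtual tissue plugs and statistics

Mirroring the microsphere protocol's 10 g tissue plugs, `extract_plug`
grows a sphere about a landmark (proximal LAD, distal LAD, LCx), clipped
to the myocardium, until the realized mass reaches 10 g (ties at the
boundary radius broken deterministically by voxel order; realized volume
within 2% of target). The plug's reference value is the ground-truth field
averaged over the *same* voxels, so a plug straddling a territory boundary
is compared against the matching mixture rather than a nominal value.

`evaluate_pairs` reproduces the validation study's statistical layout:
OLS regression of CT on reference with t-based CIs, Pearson r (Fisher-z
CI), Lin's concordance correlation (population moments; Fisher-z with
Lin's asymptotic SE), RMSE about the identity line (accuracy) and RMSD
about the regression line (precision; RMSE ≥ RMSD always), Bland–Altman
limits of agreement, a paired t-test, and — on the stress (LAD) rows —
sensitivity/specificity/PPV/NPV/accuracy for detecting functionally
significant stenosis (reference < 1.0 mL/min/g) with Wilson-score CIs,
plus ROC AUC via the rank-sum estimator (ties ½) with the Hanley–McNeil
variance. The CT-side positivity cutoff defaults to the same 1.0 mL/min/g
as the reference definition but is an explicit, separate parameter, since
the validation study does not state the cutoff it used. Percentages are
reported integer-rounded for table parity alongside unrounded values. The
one-way random-effects intra-cluster correlation by subject is computed
and reported; measurements are otherwise treated as independent.

Design notes on genuinely open points: Wilson-score CIs were chosen
because the study does not name its CI method (exact reproduction of
printed CI bounds is not attempted); Δt uses the scans' nominal
acquisition times; all estimators use population (1/n) moments where the
defining formula does, sample moments where regression theory does.

## Numerical choices and degenerate inputs

* Region growing: inclusion by |HU − HU(seed)| ≤ tolerance; BFS order has
  no effect on the result. A seed outside the grid errors; an empty region
  is impossible (the seed is always included). An optional HU plausibility
  window catches seeds placed outside the blood pool.
* `mi_map`/`ms_map` refuse a zero average enhancement change (the ratio
  map would be undefined) and warn when it is negative.
* Rigid resampling is implemented in compiled code with inverse mapping;
  an integer-voxel translation under nearest-neighbour interpolation is an
  exact shift, and a transform and its inverse compose to identity within
  interpolation error (< 5 HU on smooth volumes). Voxels pulled from
  outside the grid take a configurable fill value, with a warning when
  non-background signal is clipped.
* Ties in plug growth and in ROC ranks are handled deterministically
  (voxel order; midranks).
* All randomness flows from a single integer seed; per-acquisition and
  per-scan sub-seeds are derived arithmetically so a study is reproducible
  scan by scan regardless of which scans are materialized.

## Problem sizes used in the shipped checks

The test suite runs the full 96³ study once (6 subjects × 5 grades,
~30 s), a 96³ noise-free exact-recovery oracle, a four-step motion sweep
(0/2/4/8 mm along the long axis — the dominant beat-to-beat displacement —
chosen tangential to the lateral wall so the V1 ROI sample is preserved,
which is the stated precondition of the motion-immunity property), and
brute-force cross-checks of every statistic on 100 random small datasets.
Routine unit tests use the same physical geometry voxelized at 2 mm.

## Known limitations

* The MI estimator's accuracy depends on V1 myocardial homogeneity;
  infarcted or calcified myocardium violates it (as it does in vivo).
* The endpoint C_IN convention biases perfusion upward when the upslope
  between V1 and V2 is convex; the series-average convention (default in
  the study pipeline) reduces this to ~3% under the default gamma-variate
  AIF. Neither is exact for arbitrary input functions.
* Rigid motion only; the phantom cannot probe non-rigid deformation or
  registration algorithms (out of scope by design — the method's point is
  to need neither).
* Diagnostic metrics from 60 stress plugs have wide Wilson intervals;
  the phantom study is a scaled replication, not a power analysis.
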
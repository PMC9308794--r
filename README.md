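# mifpa — motion-immune first-pass CT myocardial perfusion

Quantitative myocardial perfusion (mL/min/g) from **two** volumetric CT
scans, without image registration.

Dynamic CT perfusion normally subtracts scans voxel-by-voxel across many
heart beats, which forces image registration between acquisitions — and
registration itself alters CT numbers, biasing perfusion (usually
downward). `mifpa` implements a first-pass-analysis estimator that is
*mathematically immune* to inter-scan motion: of the baseline scan V1
(base of aortic enhancement) it uses only two scalar summaries — the
aortic blood-pool mean and the lateral-wall myocardial mean — while all
voxel-wise information comes from the single enhanced scan V2 (aortic
peak), whose myocardium segmentation is by construction aligned with
itself. Any motion of V1 that preserves those two scalars cannot change
the result.

The package is aimed at researchers studying CT perfusion quantification:
it bundles the estimator, the classical motion-susceptible (MS)
voxel-subtraction comparator, volumetric region growing for the blood
pool, a dynamic contrast-enhancement cardiac phantom with ground-truth
perfusion (the stand-in for a swine/microsphere validation), virtual
10 g tissue plugs, and the full agreement + diagnostic statistics.

## The model

With the whole LV myocardium as one compartment and no contrast outflow
during the first pass:

    P_AVG = dM_C/dt / (C_IN * M_T),          M_T = n * v_vox * rho
    P_MI(v) = P_AVG * dHU*(v) / dHU_AVG,     dHU*(v) = HU_V2(v) - mean(HU_V1)

where `dM_C/dt` is the integrated myocardial enhancement change between V1
and V2 per unit time, `C_IN` the average incoming aortic blood-pool
enhancement (HU; the HU-to-iodine constant cancels in the ratio), and the
perfusion ratio map `dHU*/dHU_AVG` has mask-mean exactly 1. The MS
comparator replaces `dHU*` with the voxel-wise difference `HU_V2 - HU_V1`,
which is what motion corrupts.

## Worked example

Simulate one stressed acquisition (20-scan dynamic series, CT noise,
inter-scan motion), then measure perfusion from its V1/V2 pair:

```r
library(mifpa)

cfg <- phantom_config(study = list(n_subjects = 2L, ffr_grades = c(1, 0.6)))
st  <- generate_study(cfg, seed = 7)
acq <- st$acquisitions[[1]]          # subject 1, FFR 1.0 (no stenosis)
lmk <- st$landmarks

c_in <- compute_c_in_series(acq$aortic_hu, acq$v1_idx, acq$v2_idx)
res  <- fpa_perfusion(acq$v1, acq$v2, acq$myo,
                      aorta_seed = lmk$aorta_seed,
                      roi_center = lmk$roi_center,
                      method = "mi", c_in = c_in)
res
#> <perfusion_result MI> P_AVG = 2.969 mL/min/g over 49200 voxels (M_T = 51.8 g)

plug <- extract_plug(res, acq$myo, lmk$plug_centers[["proximal LAD"]])
sprintf("C_IN = %.1f HU; proximal LAD plug: %.2f mL/min/g (ground truth %.2f)",
        c_in, plug, mean(acq$field[attr(plug, "voxels")]))
#> "C_IN = 216.7 HU; proximal LAD plug: 4.75 mL/min/g (ground truth 4.61)"
```

`P_AVG` is the whole-myocardium average perfusion; this hyperemic subject
runs high (its ground-truth LAD flow is 4.61 mL/min/g after per-subject
variability). The plug value is the MI map averaged over a 10 g virtual
tissue sample, the same comparison unit a microsphere protocol uses; it
lands within ~3% of truth despite 10 HU CT noise and up-to-4 mm inter-scan
motion, because the MI estimator never subtracts the displaced V1
voxel-by-voxel.

The full study replication — 6 subjects × 5 stenosis grades, both
estimators, plug-level pairing and statistics — is one call:

```r
study <- run_phantom_study(phantom_config(), seed = 1)
evaluate_pairs(study$pairs)
#> <fpa_evaluation> 180 paired measurements; positive: reference < 1.00 mL/min/g
#> -- MI --
#>   LAD+LCx  (n=90) slope 1.03 [1.02, 1.04]  r 1.00  CCC 1.00  RMSE 0.08  RMSD 0.06
#>   SN 100%  SP 100%  PPV 100%  NPV 100%  accuracy 100%  AUC 1.00
#> -- MS --
#>   LAD+LCx  (n=90) slope 1.01 [0.93, 1.09]  r 0.94  CCC 0.93  RMSE 0.40  RMSD 0.38
#>   SN 92%  SP 79%  PPV 52%  NPV 97%  accuracy 82%  AUC 0.92
```

(abridged; per-territory rows and intra-cluster correlation omitted). The
pattern is the method's point: under identical motion and noise the MI
estimator stays on the identity line while the MS estimator scatters and
loses specificity.

## Command line

```sh
Rscript inst/cli/fpa.R simulate --config phantom.yaml --seed 7 --out-dir study/
Rscript inst/cli/fpa.R perfuse  --config perfuse.yaml --method mi
Rscript inst/cli/fpa.R evaluate --config eval.yaml
```

Volumes and masks are NIfTI (`.nii.gz`; acquisition times in a JSON
sidecar), configs YAML or JSON, tabular outputs CSV. See `?run_cli`.

## Package layout

- `R/volume.R`, `R/segmentation.R` — volume/mask containers, NIfTI I/O,
  region growing, ROI sampling, erosion
- `R/fpa.R` — C_IN conventions, enhancement summary, `mi_map`, `ms_map`,
  the `fpa_perfusion` pipeline
- `R/phantom.R` — phantom geometry, AIF, forward model, rigid motion
  (compiled resampler in `src/`), study generator
- `R/evaluation.R` — plugs, regression/correlation/concordance,
  Bland–Altman, RMSE/RMSD, diagnostics, ROC, ICC, `run_phantom_study`
- `vignettes/motion-immune-perfusion.Rmd` — model, assumptions, phantom
  design and its limits, numerical choices
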
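# ivimrobust

Multi-software robustness and diagnostic evaluation of IVIM radiomics in
breast diffusion MRI.

## What this package is for

Intravoxel incoherent motion (IVIM) imaging fits the diffusion-weighted MRI
signal to a biexponential decay,

    S(b)/S0 = f_p * exp(-b * D_p) + (1 - f_p) * exp(-b * D_t),

separating tissue diffusivity `D_t` (mm^2/s, sensitive to cellularity) from
capillary pseudo-diffusion `D_p` (mm^2/s) with perfusion fraction `f_p`.
Different analysis packages — segmented least-squares and Bayesian fitters —
return systematically different parameter maps from the same data, which
undermines multi-center use of IVIM biomarkers. `ivimrobust` is for imaging
scientists who want to quantify that software dependence: it implements

* a seeded **synthetic multi-site breast cohort generator** (three sites
  with their published b-value schemes, benign/malignant counts, ROI sizes
  and per-class IVIM parameter distributions; Rician magnitude noise), so
  the whole pipeline runs without patient data;
* three voxelwise **IVIM estimators** standing in for the software families
  in clinical use — two segmented least-squares variants (`seg_a`, `seg_b`,
  sharing the high-b log-linear step, differing in the perfusion step) and
  a deterministic grid-posterior **Bayesian** fitter (S0 and noise SD
  marginalized analytically) — plus a multi-start full-NLLS reference fit;
* fixed-range, 100-bin **histogram radiomics** (min/max/mean/variance/
  skewness/kurtosis per parameter, with per-parameter voxel-utilization
  accounting);
* **agreement statistics**: per-site, per-pair Pearson r with mean/CV
  ranking across the 16 reported metrics, three-rater ICC(2,1), and
  Bland–Altman summaries;
* **diagnostic statistics**: site-adjusted logistic regression (site-
  specific intercept and slope), apparent and leave-one-patient-out AUC
  with DeLong standard errors, paired DeLong tests, and cross-software
  AUC mean/CV ranking;
* NIfTI + `.bval` import/export for running the same fitters on real
  acquisitions.

## Worked example

```r
library(ivimrobust)

# one malignant Site C lesion with known ground truth
cfg <- cohort_config(counts = data.frame(site = "C", label = "malignant",
                                         n_patients = 1L))
coh <- generate_cohort(cfg, seed = 7)
les <- coh$lesions[[1]]
round(les$center, 4)
#>    f_p    D_p    D_t
#> 0.2164 0.0186 0.0008

# fit every voxel with a segmented and the Bayesian estimator
map_seg <- fit_roi(coh$signals[[1]], les$scheme, "seg_a")
map_bay <- fit_roi(coh$signals[[1]], les$scheme, "bayes",
                   priors = bayes_priors(32, 32, 32))
round(c(seg_a = mean(map_seg$D_t), bayes = mean(map_bay$D_t),
        truth = mean(les$truth$D_t)), 5)
#>   seg_a   bayes   truth
#> 0.00083 0.00082 0.00082

# first-order histogram features of the segmented map
features_for_map(map_seg)[, c("parameter", "mean", "utilization")]
#>   parameter         mean utilization
#> 1       f_p 0.2077272727           1
#> 2       D_p 0.0216948052           1
#> 3       D_t 0.0008257792           1
```

Both fitters agree with the true ROI-mean tissue diffusivity to within a
few percent for this lesion, while the `D_p` histogram mean (0.0217)
already deviates visibly from the generating center (0.0186) — the
parameter-wise robustness ordering the cohort-level analysis quantifies.
On noisier or smaller lesions `seg_a` additionally drops `D_p` voxels as
out of histogram range (utilization below 1) while `f_p` always uses every
voxel, the utilization pattern that distinguishes the software families.

The full study — 302 synthetic patients across three sites, three fitters,
16 radiomic metrics, agreement + diagnostics, all output CSVs — is one
call (about 3–4 minutes on one core):

```r
report <- run_study(study_config(seed = 1, out_dir = "ivim-study"))
head(report$agreement$summary, 3)
#>         metric    mean_r cv_r_pct n_cells rank
#> 1     D_t_mean 0.9898067 1.613342       9    1
#> 2      D_t_max 0.9772582 2.336729       9    2
#> 3 D_t_variance 0.9545601 5.005580       9    3
```

`D_t` radiomics lead the cross-software agreement ranking (mean r ~0.99
for `D_t_mean`) while `D_p` metrics trail — the robustness ordering that
motivates preferring tissue-diffusivity metrics in multi-software trials.
A shell wrapper with the same functionality ships in
`inst/cli/ivim_study.R` (`Rscript inst/cli/ivim_study.R run-all --out dir
--seed 1`).

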
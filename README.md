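# dtialps

Simulation and analysis pipeline for the **DTI-ALPS index** — the
"diffusion tensor image analysis along the perivascular space" proxy for
glymphatic function — together with the cohort statistics used to evaluate
it as a treatment-response biomarker in drug-resistant focal epilepsy.

At the body of the lateral ventricle, perivascular spaces run left–right
(x) while projection fibers run superior–inferior (z) and association
fibers anterior–posterior (y). The index is the ratio of apparent
diffusivities along the perivascular direction to those perpendicular to
it:

```
ALPS = mean(Dxx_projection, Dxx_association) / mean(Dyy_projection, Dzz_association)
```

where the D terms are diagonal elements of the voxel diffusion tensor in
scanner axes, taken from one voxel per fiber type — the voxel in a
periventricular search box whose principal eigenvector is best aligned with
that fiber's canonical axis.

The package provides, as plain R functions:

* **I/O** — NIfTI volumes (via RNifti), FSL-style bval/bvec gradient
  tables, cohort CSVs (`read_volume()`, `read_gradient_scheme()`,
  `read_cohort_table()`, and writers).
* **Phantom simulation** — a periventricular DWI phantom with known
  fiber-block tensors, Rician noise, and an analytic ground-truth ALPS
  (`phantom_layout()`, `simulate_dwi()`, `truth_alps()`).
* **Tensor reconstruction** — brain masking (threshold, majority-filter
  smoothing, largest-component defragmentation) and voxelwise log-linear
  least-squares tensor fits with eigensystems, FA and MD
  (`compute_brain_mask()`, `fit_tensor_volume()`).
* **ALPS computation** — fiber-voxel selection and the index, per
  hemisphere or bilateral (`select_fiber_voxel()`, `compute_alps()`,
  `alps_pipeline()`).
* **Cohort simulation** — responder/non-responder cohorts matching the
  published marginal summaries, and logistic-outcome scenarios for
  recovery testing (`simulate_cohort()`, `simulate_logistic_outcomes()`).
* **Statistics** — summary-statistic and raw two-sample t-tests,
  Mann–Whitney U with exact small-sample inference, 2×2 chi-square, ROC
  with DeLong variance and Youden cutoff, logistic regression with
  univariate screening and backward elimination, post-hoc power
  (`ttest_summary()`, `mann_whitney_u()`, `roc_analysis()`,
  `logistic_regression()`, `backward_eliminate()`,
  `posthoc_power_ttest()`, `analyze_cohort()`).

The workflow lives in `analysis/` as numbered drivers over these functions:

```
analysis/01_simulate_phantom.R   # DWI phantom -> results/phantom/
analysis/02_alps_recovery.R      # files -> mask -> tensors -> ALPS, vs truth
analysis/03_simulate_cohort.R    # 33 responders / 122 non-responders -> CSV
analysis/04_analyze_cohort.R     # t-test, ROC, logistic model, power
```

See `vignettes/dti-alps-methods.Rmd` for the model, parameter choices and
design decisions.

## Worked example

```r
library(dtialps)

# a phantom whose true ALPS is known analytically
layout <- phantom_layout(snr = 30)
truth_alps(layout)$bilateral_mean
#> [1] 1.386364

sim <- simulate_dwi(layout, default_gradient_scheme(), seed = 7)
res <- alps_pipeline(sim$dwi, sim$scheme, default_roi_spec(layout))
res
#> DTI-ALPS index (bilateral_mean): 1.36828
#>   left: 1.30423  right: 1.43234

# the published group summaries reproduce the printed p-value and power
ttest_summary(1.4022, 0.1936, 33, 1.3218, 0.1761, 122, "pooled")
#> pooled t-test (summary): statistic = 2.2777 (df = 153), p = 0.02413
posthoc_power_ttest(1.4022, 0.1936, 33, 1.3218, 0.1761, 122)
#> [1] 0.6192219

# a synthetic cohort through the full statistical plan
cohort <- simulate_cohort(cohort_params(), seed = 1)
analyze_cohort(cohort)
#> Cohort: 33 responders, 122 non-responders
#> ALPS pooled t-test: t = 3.423, p = 0.0007942
#> ROC: AUC = 0.703 (p vs 0.5 = 0.0001786), cutoff 1.3823
#> Logistic (backward elimination): retained age, asm_burden, na_blocker_prior, eeg_discharges, alps
#> Post-hoc power of the ALPS comparison: 0.925
```

The phantom recovery above is within 1.3% of truth at SNR 30 (exact to
1e-6 relative error when noiseless). The cohort numbers fluctuate with the
seed around the generating effect size at n = 155 — this seed happens to
draw a stronger-than-average ALPS separation.

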
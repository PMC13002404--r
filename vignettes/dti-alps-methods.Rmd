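---
title: "Simulating and recovering the DTI-ALPS index: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and recovering the DTI-ALPS index: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtialps)
```

## The scientific problem

Diffusion tensor image analysis along the perivascular space (DTI-ALPS) is a
non-invasive proxy for glymphatic function. At the level of the lateral
ventricle body, perivascular spaces around the medullary veins run
left–right (the scanner x axis), while the neighbouring white-matter tracts
run orthogonally to them: projection fibers superior–inferior (z) and
association fibers anterior–posterior (y). Water that moves easily *along*
the perivascular channels therefore shows up as x-axis diffusivity in
voxels whose tissue microstructure would not otherwise favor x. The ALPS
index condenses this into a ratio of apparent diffusivities:

$$\mathrm{ALPS} =
\frac{\mathrm{mean}(D_{xx}^{\mathrm{proj}},\, D_{xx}^{\mathrm{assoc}})}
     {\mathrm{mean}(D_{yy}^{\mathrm{proj}},\, D_{zz}^{\mathrm{assoc}})}$$

where the numerator collects diffusivity along the perivascular direction
and the denominator collects diffusivity perpendicular to both the fibers
and the perivascular direction. An index near 1 means no preferential
perivascular diffusion; larger values suggest freer glymphatic transport.
The $D$ terms are the *diagonal elements of the diffusion tensor in scanner
axes*, not eigenvalues — "diffusivity along the x-axis" is an apparent
diffusivity in a fixed laboratory direction. Subcortical-fiber
diffusivities are extracted and reported alongside but never enter the
ratio.

In the motivating clinical study, the index was computed for 155 patients
with drug-resistant focal epilepsy starting lacosamide add-on therapy (33
responders who stayed seizure-free, 122 non-responders), compared between
groups, evaluated as a response predictor by ROC analysis, and entered into
a multivariable logistic model together with clinical covariates. The
patient data are not public. This package therefore rebuilds the *method*
end to end and validates it against synthetic data whose ground truth is
known exactly: a geometric DWI phantom for the image-processing half, and a
parametric cohort simulator for the statistical half.

## The phantom and its signal model

`phantom_layout()` defines a rectangular "brain" of isotropic tissue
containing a CSF-filled ventricle box flanked in each hemisphere by three
fiber blocks. Each block carries a diagonal diffusion tensor whose largest
entry sits on the block's canonical fiber axis, so principal-eigenvector
voxel selection is well-posed by construction. The defaults are:

* grid 32 × 32 × 16 voxels at 2 × 2 × 2.25 mm (the slice thickness of the
  emulated protocol; the in-plane size keeps desk-scale runs under a few
  seconds);
* fiber blocks of 4 × 4 × 2 voxels lateral to the ventricle, mirrored
  across the midline;
* projection tensor diag(0.00058, 0.00049, 0.00102) mm²/s, association
  diag(0.00064, 0.00101, 0.00039), subcortical diag(0.00108, 0.00068,
  0.00060) — the responder-group mean diffusivities of the motivating
  cohort — plus isotropic CSF (0.003) and tissue (0.0008);
* baseline signal $S_0 = 1000$ and a configurable SNR $= S_0/\sigma$.

These tensors give an analytic ground-truth index of
`r sprintf("%.6f", truth_alps(phantom_layout())$bilateral_mean)`
(= 0.00061/0.00044). Because the truth is a closed-form function of the
layout, the entire mask → fit → selection → ratio pipeline can be tested
for exact recovery, not just plausibility.

Signals follow the single-tensor Stejskal–Tanner model
$S = S_0 \exp(-b\, g^\top D g)$ per volume, with the default acquisition
one $b=0$ volume plus 32 directions at $b = 1000$ s/mm² spread by a
golden-angle spiral (a well-conditioned design; the emulated protocol used
32 directions at the same b-value). Noise is Rician,
$|S + n_1 + i n_2|$ with $n_1, n_2 \sim N(0, \sigma^2)$ applied
independently per measurement — the standard magnitude-MRI model, verified
in the tests through the second-moment identity
$E[\tilde S^2] = S^2 + 2\sigma^2$.

What the phantom deliberately does **not** emulate: curved or crossing
fibers, partial-volume mixtures, susceptibility/eddy distortion, and real
anatomy. An optional `rotation_deg` perturbs the fiber tensors off-axis to
probe selection robustness, but passing tests on this phantom demonstrates
correctness of the *computation*, not robustness to everything a real
periventricular slab can contain. Real-data use assumes
distortion-corrected input and a user-supplied ROI.

## Tensor reconstruction and masking

The brain mask follows the classical threshold–smooth–defragment recipe:
voxels above `threshold_fraction` (default 0.1) of the 99th-percentile
$b_0$ intensity, a binary majority filter of radius 1, then the largest
26-connected component. The motivating workflow names these steps without
parameters, so the defaults here are conventions, surfaced as arguments.

Tensors are fit by ordinary log-linear least squares,
$\ln(S/S_0) = -b\,[g_x^2, g_y^2, g_z^2, 2g_xg_y, 2g_xg_z, 2g_yg_z]\cdot
(D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz})$,
with $S_0$ the mean of the $b=0$ volumes. OLS is exact on noiseless
single-tensor data (the tests demand recovery of random SPD tensors to
1e−12 mm²/s) and is the simplest defensible estimator when the upstream
tool is unspecified; weighted or nonlinear refinements matter mainly at low
SNR. Degenerate designs (fewer than six independent directions) are
errors; voxels with nonpositive signals are excluded and flagged; negative
eigenvalues are clamped to zero and flagged rather than aborting the fit —
the standard behavior at moderate SNR.

## Voxel selection and the index

Within each rectangular search box (0-based, half-open voxel intervals),
the selected voxel maximizes $|e_1 \cdot \hat a|$, the absolute principal
eigenvector component along the fiber's canonical axis — our reading of
"the voxel showing the maximum orientation", which the source workflow does
not define numerically. The alternative criterion (maximal axis-aligned
diffusivity) is available via `criterion = "diffusivity"`. Ties are broken
by lexicographic voxel order (x, then y, then z), making selection fully
deterministic. Hemisphere handling is likewise unspecified upstream;
the default reports both hemispheres and averages them
(`hemisphere_mode = "bilateral_mean"`), the common practice in the ALPS
literature.

Numerical properties verified by the test suite: exact truth recovery on
noiseless phantoms (to 1e−6 relative, across randomized layouts);
invariance of the index to global diffusivity scaling and to $S_0$
rescaling; strict monotonicity in the projection-fiber $D_{xx}$. At SNR 30
the single-voxel selection is inherently noisy — a single realization's
relative error fluctuates at the few-percent level — so the noisy-recovery
tests assert the *median* error over five fixed seeds against the 5% bound
rather than gambling on one realization.

## The cohort simulator

`simulate_cohort()` draws the two groups at their observed sizes (33 / 122
by default) with independent within-group covariates:

* ALPS: Normal per group (1.4022 ± 0.1936 vs 1.3218 ± 0.1761), truncated
  at 0 (negligible truncation at these parameters). The normal model
  mirrors the fact that the source compared ALPS by t-test and reported
  mean ± SD.
* Age at onset: lognormal with median 24 (responders) / 18 (non-responders)
  years; `sdlog` is matched to the reported interquartile ranges via
  $\log(q_{75}/q_{25}) / (2 \cdot 0.6745)$.
* Prior antiseizure-medication burden: $2 + \mathrm{Poisson}(\lambda)$
  with $\lambda = 0.5 / 1.2$, which reproduces the printed medians (2 / 3)
  and IQRs (2–3 / 2–4) exactly on the discrete quantiles, and respects the
  drug-resistance definition (at least two failed trials).
* Binary covariates (EEG epileptiform discharges 57.6% / 78.5%, MRI
  abnormality, prior sodium-channel-blocker use, sex) as Bernoulli draws
  at the reported rates. The reported 78.5% of 122 is not an integer
  count, so the simulator uses the printed rate, not a reconstructed count.
* Follow-up: lognormal matched to medians 64 / 65 months and their IQRs.

Covariates are independent within group — the source reports only marginal
summaries, so any dependence structure would be invented. Age is bumped up
to age-at-onset where a draw would violate onset ≤ age, preserving the
onset marginal (which is tested) at the cost of slightly inflating the age
marginal (reported only as mean ± SD). Simulated cohorts reproduce the
marginal structure, not patient-level reality: tests passing on them
validate the statistical machinery, and the expected large-sample behavior
of the published effect sizes, not the clinical findings themselves.

`simulate_logistic_outcomes()` generates outcomes from a known logistic
model over user-specified covariate distributions; the test suite uses it
to demand coefficient recovery within 3 standard errors at n = 5,000.

## The statistical plan

All pieces of the published analysis are implemented behind one surface:

* **`ttest_summary()`** works from group means/SDs/sizes, which is what
  allows printed p-values to be checked without raw data. The pooled
  (Student) variant is the default because it reproduces the published
  ALPS p-value (0.024) from the published summaries, whereas Welch gives
  0.036; Welch remains available by flag. `ttest_raw()` delegates to the
  summary form, so the two can never disagree.
* **`mann_whitney_u()`** uses midranks; exact inference (via the exact null
  distribution when tie-free, full enumeration when ties are present and
  the labeling count is feasible) for $n_1 n_2 \le 400$, otherwise a
  tie-corrected, continuity-corrected normal approximation. The
  approximation's worst-case deviation from exact p at $n_1, n_2 \le 8$ is
  0.011–0.017 (enumerated over all U values), which is what the property
  test asserts.
* **`chi_square_2x2()`** defaults to no continuity correction (the common
  package default); Yates is a flag.
* **`roc_analysis()`** builds the empirical ROC over all distinct
  thresholds; the trapezoidal AUC equals the tie-corrected
  $U/(n_1 n_2)$ identity on every input (property-tested), the standard
  error is DeLong's (computed in $O(n \log n)$ via midrank placements, and
  cross-checked against an independent ROC implementation), significance
  against AUC = 0.5 uses the normal z, and the optimal cutoff maximizes
  the Youden index with ties resolved toward higher sensitivity — the
  criterion is unstated upstream, and Youden is the standard reading of
  "optimal cutoff".
* **`logistic_regression()`** is binomial maximum likelihood by IRLS,
  reporting Wald statistics, odds ratios and 95% CIs; quasi-separation and
  non-convergence are flagged, never silent.
* **`univariate_screen()`** chooses the per-variable test by type; for
  continuous variables the automatic normality gate is the
  D'Agostino–Pearson $K^2$ test at α = 0.05 per group (the source names
  no criterion; $K^2$ is the omnibus standard and is verified against an
  independent reference implementation), falling back to Mann–Whitney for
  groups too small to test (n < 8).
* **`backward_eliminate()`** repeatedly removes the largest-Wald-p term
  while that p ≥ `removal_alpha` (default 0.05), refitting after each
  removal and recording a full trace. Because the published multivariable
  table retains terms with p = 0.168 — suggesting it is the
  pre-elimination model — the full model is always kept alongside the
  eliminated one.
* **`posthoc_power_ttest()`** evaluates two-sided power from the
  noncentral t distribution with
  $\mathrm{ncp} = d\sqrt{n_1 n_2/(n_1+n_2)}$, $d = (m_1-m_2)/s_p$; at the
  published ALPS summaries this gives 0.62, cross-checked in the tests by
  Monte-Carlo simulation of the t-test itself.

## Reproducibility machinery

Every stochastic function takes an explicit seed; `run_full_study()`
derives stage seeds by a stable hash of (master seed, stage label), so the
phantom and cohort stages are independently reproducible and the whole
artifact directory is byte-identical across reruns with one seed (asserted
in the tests). Problem sizes used by the checked examples: 1e5 draws per
group for the binormal AUC reproduction; 1e5 null replications for the
pooled-t type-I-error calibration; n = 5,000 for logistic coefficient
recovery; 100 random SPD tensors for the fit-inversion check; the default
32 × 32 × 16 phantom for recovery tests. These sizes make every
Monte-Carlo tolerance small relative to the asserted bounds while keeping
a full run on a laptop in the minutes range.

## Known limitations

* The phantom's fibers are axis-aligned blocks; selection robustness under
  oblique fibers is only probed via the rotation option, not
  characterized.
* ROI placement on real scans is user-supplied; nothing here localizes the
  lateral-ventricle body anatomically.
* The cohort simulator matches marginals only; joint structure (and hence
  any multivariable result's exact magnitude) is not identifiable from the
  published tables.
* Exact logistic regression and Firth correction are out of scope; heavily
  separated data are flagged rather than rescued.
* The 2×2 cells behind the published EEG comparison cannot be
  reconstructed unambiguously (78.5% of 122 is non-integer), so that
  printed p-value is approximated, not reproduced.
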
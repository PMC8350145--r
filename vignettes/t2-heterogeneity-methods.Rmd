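---
title: "Quantitative T2 heterogeneity of MTL subfields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T2 heterogeneity of MTL subfields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2het)
```

## The problem

Quantitative T2 relaxometry measures, per voxel, the transverse relaxation
constant of tissue water. In the medial temporal lobe (MTL), microstructural
degeneration — demyelination, gliosis, iron deposition, incipient atrophy —
pulls voxelwise T2 in both directions, so the *median* T2 of a hippocampal
subfield can remain normal while the *spread* of its voxel values widens.
`t2het` implements a pipeline built around that observation: the width
parameter of a log-logistic distribution fitted to the voxelwise T2 values of
a subfield (T2 heterogeneity, $\sigma$) is used as an early microstructural
marker, and is propagated into group comparisons (healthy older controls vs
mild cognitive impairment), age models, prediction of cognitive decline, and
a path model in which age drives heterogeneity, heterogeneity drives volume
loss, and volume loss drives memory performance.

Because the clinical scans behind this design are not redistributable, the
package ships a first-class synthetic-data module that emulates every input
the pipeline consumes; all tests and the acceptance report run against that
stated world.

## Subject-level model

**T2 mapping.** Multi-echo acquisitions sample $S(\mathrm{TE}) = S_0
e^{-\mathrm{TE}/T_2}$ at a train of echo times. `fit_t2_voxel()` estimates
$T_2$ by ordinary least squares of $\log S$ on TE (slope $b \Rightarrow T_2
= -1/b$, intercept $\Rightarrow S_0$). Log-space OLS is exact on noiseless
data and implicitly downweights late, low-SNR echoes relative to nonlinear
least squares; the two agree to $r > 0.99$ at the SNRs simulated here
(tested against an `nls()` oracle). The first echo of CPMG-style trains is
excluded from fitting (stimulated-echo contamination) but *is* included in
the sum-of-echoes structural image. Voxels with any nonpositive usable
signal, a nonnegative slope, or fitted T2 outside $(1, 2000)$ ms are flagged
invalid — never clipped — so they cannot enter distribution fits. The bounds
are deliberately loose; they exist to catch numerically absurd fits, not to
trim the histogram.

**Masks and erosion.** Subfield label masks (ASHS-style integer codes) are
consumed, not produced. CA1–CA3 are pooled into one CA label before
anything else (CA2/CA3 are too small to fit alone). Each label is then
eroded by one voxel under 6-connectivity, with *other* labels treated as
outside, so voxels at subfield–subfield interfaces are removed along with
tissue–CSF boundary voxels; this targets partial voluming in both
directions. A 2-D (in-plane) variant exists for strongly anisotropic
acquisitions. Volumes are measured on the un-eroded mask; T2 samples on the
eroded one. On compact subfield shapes a one-voxel erosion removes 20–50%
of voxels, and the synthetic mask generator is required to stay in that
band for its default blob/ribbon families.

**Distribution fit.** Within each eroded subfield, voxel T2 values are
modelled as log-logistic,
$$f(x \mid \mu, \sigma) = \frac{1}{\sigma x}\,
  \frac{e^{z}}{(1+e^{z})^{2}}, \qquad z = \frac{\log x - \mu}{\sigma},$$
i.e. $\log T_2$ is logistic with location $\mu$ (midpoint; $e^{\mu}$ is the
median T2 in ms) and scale $\sigma$ (heterogeneity, dimensionless). These
play the role median/MAD play for a normal distribution. Estimation is raw
maximum likelihood on voxel values (not on binned histograms — bin-free,
reproducible, and the limit of any reasonable binning), via BFGS on
$(\mu, \log\sigma)$ with analytic gradient, initialized from the log-median
and $\mathrm{IQR}(\log x)/(2\log 3)$. A $\sigma$ floor of $10^{-4}$ keeps
the likelihood finite on degenerate samples, which are flagged. Samples
with fewer than `n_min = 50` voxels are reported missing rather than
fitted.

## Cohort-level model

**Z-pooling.** Raw $\mu$, $\sigma$ and volumes from different studies are
not commensurable, so each study is converted to Z-scores before pooling.
The default reference stratum is the left DG of that study's healthy
controls — one anchor per study and metric, preserving group, subfield and
hemisphere contrasts. Two alternative references serve specific analyses:
per-subfield HC-referenced Z-scores (used by the path model, where
between-subfield level differences are deliberately removed) and
per-subfield MCI-referenced Z-scores (decline prediction, an MCI-only
analysis).

**Group contrasts.** Hemispheres are averaged per subject and subfield,
then the MCI−HC contrast is estimated *corrected for age*. The default is
an ANCOVA, `metric ~ age_z + group`, with Cohen's
$d = \hat\beta_{\text{group}} / \hat\sigma_{\text{resid}}$ — i.e. $d$ on
the age-conditional scale. A two-step variant (residualize on age alone,
then a pooled t-test) is available as `adjust = "residualize"`, but note
that because the MCI group is older, the pooled age slope in that variant
absorbs part of the group effect and attenuates $d$ by roughly 3% at the
default demographics; the ANCOVA does not, which is why it is the default.
Bonferroni correction is applied across the five analysis subfields.
Consistently, the synthetic generator applies group shifts on the
age-conditional scale, so a configured `d_sigma` *is* the age-adjusted $d$
an unbiased pipeline should recover.

**Age associations** are per-subfield simple regressions of the
hemisphere-averaged metric on age ($R^2$ = squared correlation), Bonferroni
corrected.

**Decline prediction.** Follow-up cognition in MCI is regressed on forced
covariates (age, baseline cognition) plus forward-selected subfield
predictors: at each step the candidate with the smallest partial-F p-value
enters if $p < .05$; ties break by larger F, then alphabetically, so
selection is deterministic. A whole-hippocampus composite (mean of the DG,
CA and SUB Z-scores) competes alongside the subfields.

**Path model.** A recursive system of standardized OLS equations under
theory-driven direction constraints — volume may not predict heterogeneity,
memory predicts nothing, nothing predicts age:
$\sigma_j \sim \text{age}$; $\text{vol}_j \sim \text{age} + \sigma_j$;
$\text{PAL} \sim \text{age} + \boldsymbol\sigma + \mathbf{vol}$. Indirect
effects are products of direct estimates (e.g. age→$\sigma_j$→vol$_j$ =
$\hat a_j \hat b_j$). Inference is bias-corrected percentile bootstrap over
subjects (default 2000 resamples, seed recorded); with `n_boot = 0` a fast
analytic mode uses OLS t-tests and delta-method (Sobel) p-values — used
where thousands of replicate fits are needed (null-calibration tests).
Benjamini–Hochberg FDR is applied across all paths of a model. No latent
variables, fit indices or error-covariance estimation: this is
deliberately the regression core of the published analysis, not an SEM
reimplementation.

## The synthetic stated world

`cohort_preset()` defaults encode the conditions the analysis is designed
for, and they are fixed — tests measure the pipeline against this world
rather than tuning the world to the pipeline:

* **Demographics**: 99 HC (69.2 ± 8.55 y) and 49 MCI (72.2 ± 9.03 y),
  pooled from two studies (55/45 split) whose raw metric scales differ by
  deliberate affine offsets that Z-pooling must undo.
* **Heterogeneity**: baseline $\sigma_0 \approx 0.12$ per subfield,
  between-subject SD 0.03, equicorrelated across subfields (0.5), with
  age slopes equal to the square roots of the target age-$R^2$ values
  (0.146–0.206) and age-adjusted group effects $d$ of 0.62 (DG), 0.63
  (CA), 0.92 (SUB), 1.07 (EC), 0.95 (BA35).
* **Midpoint**: median T2 78–90 ms by subfield; group deficits only in
  SUB and EC (−1.47, −0.82), no age slope.
* **Volume**: generated on the ICV-ratio scale (the scale the path model
  analyses), with $\sigma$→volume slopes set so the generating product
  age→$\sigma$→volume equals the target indirect effects (−0.062 to
  −0.076); raw volume is derived as ratio × a subject's ICV, so the
  uncorrected-volume analyses see head-size variance.
* **Memory**: PAL accuracy and reaction time driven by volumes (CA→RT
  negative, BA35→accuracy positive) plus direct age effects; higher
  accuracy is better, longer RT worse.
* **Acquisition**: 10 echoes at 12–120 ms, first echo excluded; additive
  Gaussian noise at proton-density SNR 100 (a Rician switch exists). The
  paper-gap here is real — no noise level is stated anywhere — and SNR
  100 is a defensible figure for high-resolution hippocampal TSE at 3 T;
  at this level per-voxel T2 noise inflates $\hat\sigma$ by under 2%,
  consistent with treating subject-level $\sigma$ as reliable.
* **Anatomy**: per-hemisphere deviations (SD 0.15 standardized) around
  subject-level truths; label geometries are jittered ellipsoid families
  (blob, ribbon, sheet) sized so the analysis labels lose 20–50% of
  voxels to erosion. Reduced-volume options (`mask_scale` for
  proportional shrinking, `mask_voxels` to pin every region at a fixed
  pre-erosion size, plus shared mask geometry per cohort) keep replicate
  studies tractable; shared geometry removes volume variation, so volume
  metrics are dropped from Z-pooling in that mode.

What a green test does **not** establish: realism of anatomy beyond the
erosion band (no curved laminae, no partial-volume mixing at boundaries,
no B1/stimulated-echo effects, no multi-compartment T2), and no claim
that the clinical effect sizes themselves are reproduced from data — the
generator *encodes* the published effect sizes and the tests verify the
pipeline recovers what was encoded, through the full voxel-level chain.

## Numerical choices

* T2 validity bounds (1, 2000) ms; out-of-bounds ⇒ invalid, excluded.
* MLE convergence: `reltol 1e-8` on $(\mu, \log\sigma)$; $\sigma$ floor
  $10^{-4}$; grid-search oracle agreement asserted to $10^{-3}$ in tests.
* Erosion connectivity: 6-face default; grid boundary counts as outside.
* Stepwise ties: larger partial F, then alphabetical.
* Bootstrap: subject-level resampling, bias-corrected percentile CIs;
  p-values by inverting the BC interval; resamples with any zero-variance
  column are dropped and the result is flagged if they exceed 1%.
* Determinism: every stochastic entry point takes a seed; identical
  preset + seed gives bit-identical outputs at every level (tested).

## Known limitations

* The full-factorial REML mixed model of the original analysis is not
  reproduced; group/age effects come from hemisphere-averaged ANCOVA on
  Z-pooled metrics. At the default world the two approaches target the
  same marginal contrasts, but degrees of freedom and p-values are not
  comparable to a Satterthwaite mixed model.
* Whether volume statistics should use eroded or full masks is not
  settled; the package measures volumes on full masks and exposes the
  convention.
* Summary-mode cohorts bypass voxel-level estimation noise entirely;
  imaging-mode replicates carry it, at ~1–2% attenuation of group d at
  the default SNR and voxel counts.
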
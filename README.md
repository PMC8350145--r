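# t2het — quantitative T2 heterogeneity of medial temporal lobe subfields

`t2het` is an R package for quantitative T2 relaxometry of hippocampal and
medial-temporal-lobe (MTL) subfields, aimed at researchers studying early
microstructural change in ageing and mild cognitive impairment (MCI). Its
core statistic is **T2 heterogeneity (T2σ)**: the shape parameter σ of a
log-logistic distribution fitted to the voxelwise T2 values inside an
eroded subfield mask,

    f(x | μ, σ) = (1/σ) (1/x) e^z / (1 + e^z)²,   z = (log x − μ) / σ,

where exp(μ) is the subfield's median T2 in ms ("midpoint", T2μ) and σ
measures the spread of log T2 — a marker that widens with microstructural
degeneration even while the median stays normal.

The package covers the whole chain:

1. **T2 mapping** — voxelwise log-space mono-exponential fits
   (`S(TE) = S0·exp(−TE/T2)`) of multi-echo volumes, first-echo exclusion
   for CPMG trains, sum-of-echoes structural image, validity flagging.
2. **Masking** — CA1–CA3 pooling, one-voxel 6-connected label erosion
   (other labels count as outside), per-subfield sample extraction and
   volumes (un-eroded mask).
3. **Distribution fits** — log-logistic maximum likelihood per subfield ×
   hemisphere, with degeneracy flags and minimum-voxel rules.
4. **Cohort statistics** — reference-stratum Z-pooling across studies
   (left-DG-of-HC anchor), age-adjusted group contrasts with Cohen's d
   and Bonferroni correction, per-subfield age regressions, forward
   stepwise prediction of cognitive decline, partial correlations, and a
   regression-based path model (age → T2σ → volume → paired-associate
   memory) with bias-corrected bootstrap CIs and Benjamini–Hochberg FDR.
5. **Synthetic data** — multi-echo phantoms, subfield-shaped label masks
   whose one-voxel erosion removes 20–50% of voxels, and full cohorts
   with configurable effect sizes and path coefficients, so everything
   above is testable without clinical data.

Minimal NIfTI-1 I/O (`.nii`/`.nii.gz` + JSON sidecars) is built in and
cross-validated against nibabel in the test suite.

## Worked example

```r
library(t2het)
preset <- cohort_preset(n_hc = 40, n_mci = 20, mask_scale = 0.2,
                        shared_mask = TRUE)   # reduced-size phantoms
cohort <- gen_cohort(preset, mode = "imaging", seed = 7)

subj <- cohort$get_subject(1)
subj$L$mask
#> label mask 50x32x25: DG=814 SUB=458 EC=611 BA35=509 CA=1119

rows <- run_subject(subj, run_config(), subject_id = "S001",
                    icv = cohort$meta$icv[1])
rows[1:4, c("subfield", "hemisphere", "n_voxels", "t2_sigma",
            "median_ms", "volume_mm3")]
#>   subfield hemisphere n_voxels  t2_sigma median_ms volume_mm3
#> 1       DG          L      496 0.1117213  80.61678  159.96728
#> 2       CA          L      663 0.1968871  83.03035  219.90588
#> 3      SUB          L      215 0.1569604  72.59016   90.00616
#> 4       EC          L      352 0.1776328  83.55567  120.07372

res <- run_cohort(cohort, run_config(), analyses = c("group", "age"))
print(res$group_stats$t2_sigma_z, digits = 3)
#>   subfield    t df        p   p_bonf cohens_d direction
#> 1       DG 2.82 57 0.006630 0.033152    0.775    MCI-HC
#> 2       CA 2.75 57 0.007976 0.039880    0.756    MCI-HC
#> 3      SUB 2.26 57 0.027583 0.137917    0.622    MCI-HC
#> 4       EC 4.03 57 0.000164 0.000822    1.110    MCI-HC
#> 5     BA35 3.76 57 0.000400 0.001999    1.035    MCI-HC
```

Reading the output: each metric row is one subfield × hemisphere of one
subject — `n_voxels` valid T2 voxels survived erosion, `t2_sigma` is the
fitted heterogeneity, `median_ms = exp(μ)` the absolute T2. The group
table tests MCI − HC on hemisphere-averaged, Z-pooled, age-adjusted
heterogeneity: at this small n the pipeline already recovers the graded
vulnerability built into the generator (EC and BA35 largest d, DG/CA
smallest), with Bonferroni-corrected p-values. (The per-subfield d values
wobble around their generating targets of 0.62–1.07 at n = 60; the
acceptance suite averages 100 replicates at n = 148.)

A command-line front-end mirrors the stages:

```sh
Rscript inst/cli/t2het.R simulate --mode summary --out run/ --seed 4
Rscript inst/cli/t2het.R stats --metrics run/metrics.csv \
    --meta run/metadata.csv --analysis all --out run/ --seed 4
```

(installed: `Rscript $(Rscript -e 'cat(system.file("cli","t2het.R",package="t2het"))') ...`)

## Scope

No segmentation (masks are consumed, not produced), no scanner
reconstruction or bias-field correction, no registration/resampling
(map/mask pairs must share a grid), no mixed-effects or SEM machinery —
see `vignettes/t2-heterogeneity-methods.Rmd` for the model, the synthetic
world, and the design decisions.
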
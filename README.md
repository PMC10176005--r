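# qmritrack

Longitudinal quantitative MRI (qMRI) analysis of multiple sclerosis (MS)
brain, built around the multiparameter mapping (MPM) protocol. MPM
acquires three colocalized multi-echo FLASH series (MT-, PD- and
T1-weighted) and yields four voxelwise parameter maps — magnetization
transfer saturation (MTsat, percent units), proton density (PD, p.u.),
and the relaxation rates R1 and R2\* (s⁻¹) — that are sensitive to
myelin, iron and free-water content. `qmritrack` implements the full
two-timepoint analysis a longitudinal MS qMRI study needs, plus a
synthetic phantom cohort with known ground truth to validate every
stage.

## What the package computes

**Map estimation.** Per voxel, a joint log-linear fit of all three
multi-echo series with one shared decay slope and one TE=0 intercept per
contrast (the ESTATICS approach):

ln S_c(TE) = ln S_c(0) − TE·R2\*

The intercepts feed the small-flip-angle closed forms

S_c ≈ A·α_c·(TR_c·R1)/(α_c²/2 + TR_c·R1),
δ = (A·α_MT/S_MT(0) − 1)·R1·TR_MT − α_MT²/2,

solved for amplitude A, R1 and MTsat δ; PD is A rescaled so a reference
tissue (NAWM) hits a conventional percent-unit median.

**Mask algebra.** Tissue posteriors are binarized by strict-threshold
argmax (> 0.2); lesion components under 10 mm³ are removed; the
focal FLAIR lesion, initial peripheral (T0) and later peripheral (T1)
areas and lesion-free NAWM are built as exact set differences, and
*enlarging* lesions — present in all three lesion areas — are selected
per 26-connected component.

**Volumetry.** TIV, brain parenchymal fraction (BPF), gray-matter
fraction (GMF) and lesion fraction (LF), with annualized percentage
changes and one-sample t tests.

**Disease activity.** The NEDA-3 composite (no relapse, no new/enlarged
lesion, no sustained EDSS progression; 1.0-point threshold at baseline
EDSS ≤ 4.0, 0.5 above) evaluated at mid- and end-interval; a subject
scores 0 only when activity is present at both evaluations.

**Inference in normal-appearing tissues.** Per subject, tissue (NAWM,
NACGM, NADGM) and parameter, the annual rate of change (ARoC) of the
median value; the regression Y = β₀ + β₁·X_status + ε; permutation
inference p = #(R²_π > R²_obs)/(n+1) with n = 5000 shuffles (each
required to differ from the observed labels); Benjamini–Hochberg FDR
over the 12-test family; Welch t tests post hoc.

**Lesion microstructure.** Per-lesion area medians at both timepoints,
log-transformed, modelled with a linear mixed model (fixed: area, time,
area×time; random intercepts for participant and for each repeated
series; Kenward–Roger degrees of freedom) and all pairwise area
contrasts with Tukey adjustment.

## Worked example

Simulate a 17-subject two-timepoint cohort whose stable/improving
(status 1) subjects carry the programmed NAWM/NACGM drifts of
+0.039 p.u./yr MTsat and +0.295 s⁻¹/yr R2\*, then run the
normal-appearing-tissue inference:

```r
library(qmritrack)
cfg <- phantomConfig(gridShape = c(16L, 16L, 16L), nLesions = 0L,
                     seed = 31L)
cohort <- generatePhantom(cfg)
cohort
#> PhantomCohort: 17 subjects, grid 16 x 16 x 16, 0 lesion(s)/subject
#>   disease-activity status: 14 stable/improving, 3 active
tab <- cohortArocTable(cohort, seed = 5)
res <- runNabtInference(tab, cohort@clinical[c("subject_id", "status")],
                        nPerm = 5000, seed = 6)
res[res$rejected, c("tissue", "parameter", "beta1", "r2", "p_perm",
                    "posthoc_p")]
#>   tissue parameter  beta1    r2 p_perm posthoc_p
#> 1   NAWM     MTsat 0.0389 0.995      0  9.92e-06
#> 4   NAWM    R2star 0.3097 0.995      0  4.09e-10
#> 5  NACGM     MTsat 0.0390 0.998      0  1.22e-13
#> 8  NACGM    R2star 0.2889 0.995      0  5.97e-09
```

Exactly the four cells with a programmed status effect are FDR-rejected;
the estimated status coefficients β₁ recover the programmed per-year
drifts, and the other eight tests stay null. The full pipeline
(simulate → fit maps → segment areas → volumetrics → status → inference
→ lesion model) runs with

```sh
Rscript scripts/run_pipeline.R --out pipeline-out --seed 1
```

and writes per-stage CSVs plus a JSON manifest.

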
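# cacscore

Automated coronary artery calcium (CAC) scoring on **non-ECG-gated chest
CT**. Millions of chest CTs are acquired every year for lung screening and
other indications; the coronary calcium they incidentally image is a strong
cardiovascular risk marker, yet it is rarely quantified because manual
Agatston scoring is designed for dedicated ECG-gated studies. `cacscore`
implements a fully automatic pipeline that detects, quantifies and
risk-categorizes CAC on such opportunistic scans, plus a synthetic phantom
generator with analytically known scores for validation, and the standard
agreement statistics for comparing automatic scores against a reference.

It is aimed at medical-image-analysis researchers who need (a) a
reproducible, inspectable Agatston/CAC-DRS implementation for non-gated CT,
(b) a controlled digital phantom substrate with exact ground truth, and
(c) the evaluation machinery used in diagnostic-agreement studies.

## Method

The pipeline runs four stages on a calibrated HU volume:

1. **Multi-organ segmentation.** Heart, aorta and epicardial fat masks come
   from a pluggable backend: masks produced by any external model can be
   injected from NIfTI files, or the built-in density/geometry reference
   backend (thresholding + connected components + closing) can be used on
   phantom-like data. Epicardial fat is derived from the heart mask as the
   voxels inside the adipose window (default [-190, -30] HU) within a shell
   around the heart boundary.
2. **Coronary territory splitting.** Iterating from the most superior
   slice, the aorta's axial cross-section progresses circular → elliptical
   → semi-elliptical → absent. The first elliptical slice is the reference;
   a localization slice a few mm below it anchors the split. A morphological
   closing of the fat mask yields the coronary corridor, and corridor voxels
   inside the heart are assigned to RCA / LAD / LCX angular sectors around
   the per-slice heart centroid, oriented by the aorta centroid. The aorta
   mask itself is labelled AORTA throughout.
3. **Calcium candidate cascade.** Voxels ≥ 130 HU are candidates; per-slice
   morphological opening removes speckle; components that are both small
   and faint are dropped; components larger than 10,000 voxels are bone
   seeds, dilated in 3D so adjacent bone fragments merge and are eliminated
   together; partially eroded lesions are restored by connected-component
   recovery; the cardiac (heart ∪ aorta) mask removes extra-cardiac
   calcium; each remaining component is attributed to the majority artery
   territory.
4. **Agatston scoring and CAC-DRS grading.** For every lesion, every axial
   slice and every in-plane connected component contributes
   `area (mm²) × w(peak HU)` with the standard density weights
   `w = 1/2/3/4` for peak HU in `[130,200) / [200,300) / [300,400) /
   [400,∞)`. Per-artery scores are summed; the total (RCA + LAD + LCX; the
   aorta is reported separately) maps to CAC-DRS grade
   0 / I / II / III / IV at boundaries 0, 1–100, 101–400, 401–1000, >1000.

The evaluation module computes Dice overlap, 5×5 risk-category confusion
matrices, unweighted Cohen's kappa with an asymptotic (or bootstrap) 95% CI,
per-grade sensitivity/specificity/PPV/NPV/F1, exact/within-one agreement
fractions and presence/absence diagnostics.

## Worked example

```r
library(cacscore)

# a 256 x 256 x 60 digital chest phantom, 10 HU noise, three lesions
ph  <- generate_phantom(phantom_spec(noise_sd = 10, seed = 7))
res <- run_pipeline(ph$volume, cac_config(), verbose = TRUE)
#> [segmentation] heart 159256, aorta 16007, fat 58201 voxels
#> [region_split] reference slice 7, localization 11, corridor 58492 voxels
#> [calcium] candidates 50495 -> denoised 50492 -> deboned 19556 -> recovered 19559; 3 lesions
#> [scoring] total 174.4, grade II

print(res$report)
#> Agatston report
#>   RCA        82.3
#>   LAD        47.0
#>   LCX        45.1
#>   AORTA       0.0
#>   total     174.4  (RCA + LAD + LCX; aorta excluded)
#>   CAC-DRS category: II

ph$truth$expected[c("RCA", "LAD", "LCX", "total", "grade")]
#> $RCA 82.32  $LAD 47.04  $LCX 45.08  $total 174.44  $grade "II"
```

The phantom's analytic ground truth (82.3 / 47.0 / 45.1 Agatston units,
total 174.4, CAC-DRS category II) is reproduced exactly by the full
pipeline: every lesion survives the candidate cascade intact, the spine and
rib bone is eliminated, and each lesion lands in its own artery territory.
`lesion_table(res$lesions)` lists the per-lesion voxel counts, peak HU and
score contributions.

A command-line interface is installed with the package
(`<library>/cacscore/exec/cacscore`) with `score`, `phantom` and `evaluate`
subcommands.

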
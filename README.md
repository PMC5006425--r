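# adipoct

Automated quantification of visceral (VFA) and subcutaneous (SFA) fat from
abdominal CT, and prediction of long vs short chemotherapy outcome from the
resulting adiposity features.

## What it does

Manual tracing of fat compartments on every abdominal CT slice is slow and
reader-dependent. `adipoct` segments both compartments automatically with a
four-step per-slice scheme:

1. **Trunk mask** — line scans from the four image edges stop at the first
   pixel above −140 HU; the intersection of row and column spans, restricted
   to its largest 4-connected component and hole-filled, is the body trunk
   (the CT bed is a separate component and is dropped).
2. **Fat / non-fat masks** — trunk pixels with HU in [−140, −40] are fat;
   the rest (muscle, organs, bowel gas) are non-fat.
3. **Visceral mask** — 4-connected non-fat components smaller than 200 px
   are removed, then the mask is dilated (disk, r = 3), hole-filled, and
   eroded (disk, r = 3), yielding a cover of the visceral region.
4. **Compartment split** — VFA = fat ∧ visceral; SFA = fat ∧ (trunk ∖
   visceral).

From the pooled slices it computes the feature vector
f1 = BMI, f2 = SFA/trunk, f3 = VFA/trunk, f4/f5 = mean/SD HU of SFA,
f6/f7 = mean/SD HU of VFA (optional f8 = SFA/VFA), and evaluates outcome
prediction by **median dichotomization** of survival months, **SFFS**
feature selection nested in **leave-one-case-out** cross-validation of a
logistic model, the empirical **Mann–Whitney AUC** with bootstrap CI, and an
**exact binomial null** for the significance of the accuracy
(P(X ≥ k), X ~ B(n, 0.5)).

A synthetic abdominal phantom (air / bed / SFA ring / muscle wall / visceral
cavity with organs and gas pockets, exact ground-truth masks) and a cohort
simulator make every stage testable without patient data. Volumes are read
from NIfTI or single-series DICOM directories (rescale slope/intercept
applied, slices ordered spatially).

## Worked example

```r
library(adipoct)

# synthetic abdominal volume, 256^2 x 5 slices, 5 HU noise
ph  <- generate_phantom(phantom_config(hu_noise_sd = 5, seed = 2))
seg <- segment_case(ph$volume)
seg
#> <segmentation_result> 5 slice(s)
#>   total pixels: trunk 115140, SFA 40980, VFA 53680

round(compute_features(seg, bmi = 26.1), 3)
#>      f1      f2      f3      f4      f5      f6      f7
#>  26.100   0.356   0.466 -99.989   4.991 -90.017   4.974

area_cm2(mean(seg$counts$sfa), seg$pixel_spacing)   # 184.4 cm^2, matches truth

# simulated 32-case cohort: 1 informative feature (effect size 3) + 6 noise
co  <- generate_cohort(cohort_config(seed = 11))
lab <- dichotomize(co$outcomes$months)              # 16 long / 16 short
loco_evaluate(as.matrix(co$features[, -1]), lab, seed = 7)
#> <cv_result> leave-one-case-out over 32 cases
#>   accuracy 1.000 (p vs chance 2.33e-10), AUC 1.000 (95% CI 1.000-1.000)
#>   PPV 1.000, NPV 1.000
#>   selection frequency: feat1=32/32 folds
```

f2/f3 are the fraction of the trunk occupied by subcutaneous and visceral
fat; f4–f7 recover the simulated compartment HU distributions (−100 ± 5 and
−90 ± 5 HU). In the cohort run, the informative feature is selected in all
32 folds and the held-out accuracy is far above the binomial chance level.

A YAML-driven pipeline (`run_pipeline()`, or the `inst/scripts/adipoct`
command line with subcommands `simulate`, `segment`, `features`, `predict`,
`evaluate-correlation`, `run`) chains the stages and writes NIfTI label
maps, CSV tables and JSON metrics next to a config snapshot.

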
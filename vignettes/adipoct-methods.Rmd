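---
title: "Methods: fat segmentation and outcome prediction in adipoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fat segmentation and outcome prediction in adipoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Abdominal adiposity — in particular the balance between visceral fat (VFA,
inside the abdominal cavity) and subcutaneous fat (SFA, beneath the skin,
outside the muscle wall) — is a candidate marker for how cancer patients
respond to antiangiogenic chemotherapy. Tracing both compartments by hand on
every axial CT slice of an abdominal section is slow and poorly reproducible,
so `adipoct` implements an automated per-slice scheme that segments the two
compartments from Hounsfield-unit (HU) CT volumes, summarizes them into a
small adiposity feature vector, and evaluates how well those features predict
a dichotomized survival outcome.

## Segmentation model

Every slice in the operator-selected abdominal range (upper bound below the
lungs, lower bound above the umbilicus; slice indices in this package are
1-based and inclusive at both ends) is processed independently by four steps:

1. **Trunk detection.** Each row is scanned left-to-right and right-to-left,
   and each column top-to-bottom and bottom-to-top; a scan stops at the first
   pixel with HU *strictly greater than* `body_threshold` (default −140 HU).
   Pixels between the two stopping points of a row (column) are row (column)
   candidates; the trunk is the intersection of the two candidate sets,
   restricted to its largest 4-connected component and hole-filled. The
   intersection-of-spans rule assumes the trunk cross-section is roughly
   convex along rows and columns; the largest-component rule removes the CT
   bed, which is above the threshold but spatially disconnected from the body.
2. **Fat / non-fat banding.** Trunk pixels with HU in the *inclusive* band
   `[fat_low, fat_high]` (defaults −140 and −40 HU, the standard adipose
   range) form the fat mask; all other trunk pixels — muscle, organs, and
   also sub-(−140 HU) interior pixels such as bowel gas — form the non-fat
   mask. The boundary value −140 HU is resolved deliberately: it stops a
   trunk scan (strict `>`) but counts as fat (inclusive `>=`); one convention
   had to be fixed and this one keeps both published operating points
   meaningful.
3. **Visceral mask construction.** 4-connected components of the non-fat
   mask smaller than `min_component_size` pixels (default 200) are removed —
   these are isolated specks (vessels, skin, noise) inside the subcutaneous
   ring. The surviving mask is dilated with a disk of `dilation_radius`
   (default 3 px), hole-filled (background components not connected to the
   image border become foreground), and eroded with a disk of
   `erosion_radius` (default 3 px). The result covers the whole visceral
   region: the muscle wall and everything inside it. Because processing is
   per-slice, the structuring element is a 2D disk; the equal default radii
   make the dilate/fill/erode sequence a morphological closing bracket, so
   the outer boundary of the mask returns approximately to the muscle wall's
   outer edge.
4. **AND-logic split.** VFA = fat ∧ visceral mask; SFA = fat ∧ (trunk ∖
   visceral mask). On every slice `sfa ∪ vfa = fat`, `sfa ∩ vfa = ∅`, and
   `fat ∪ nonfat = trunk` — these partition invariants are asserted in the
   test suite.

`min_component_size` is in pixels; its physical area equivalent is
`min_component_size × spacing² / 100` cm² and depends on the reconstruction
field of view, so it is configurable rather than fixed in mm².

## Feature vector

From the pooled masks of all selected slices and the patient's BMI:

| feature | definition | units |
|---|---|---|
| f1 | body mass index | kg/m² |
| f2 | SFA pixels / trunk pixels | fraction |
| f3 | VFA pixels / trunk pixels | fraction |
| f4, f5 | mean and SD of HU over all SFA pixels | HU |
| f6, f7 | mean and SD of HU over all VFA pixels | HU |
| f8 (optional) | SFA pixels / VFA pixels | ratio |

The "whole body size" denominator of f2/f3 is the trunk pixel count summed
over the selected slices — the only whole-body measure the scheme produces.
HU moments are pooled across slices rather than averaged per slice, and the
SD uses the population divisor N; both choices make the features invariant to
slice-order permutation and to duplicating identical slices. f8 is off by
default so that the default pool is the seven-feature set f1–f7.

## Outcome prediction

Survival months (PFS or OS) are dichotomized at the cohort median; values
exactly at the median go to the *long* class (the `>=` rule), which with an
even number of distinct values yields an exact half/half split. Prediction is
evaluated by leave-one-case-out (LOCO) cross-validation: in each of the *n*
folds, sequential floating forward selection (SFFS) and the logistic model —
including the feature z-scoring parameters — see only the *n* − 1 training
cases, and the held-out case receives a probability score from the trained
model. Fold hygiene is asserted directly in the tests by refitting folds from
scratch.

SFFS adds the feature that maximizes the criterion, then floats backward,
removing features while removal improves on the best value recorded for the
smaller subset size. The criterion is the resubstitution AUC of the logistic
scorer on the training fold; the search explores subsets up to `max_subset`
(default 4) and returns the best-criterion subset encountered, with ties
broken toward smaller subsets and lower feature indices, making the procedure
fully deterministic. The criterion and stop rule were open design choices;
resubstitution AUC is the simplest criterion consistent with using AUC as the
evaluation index, and the small default cap guards against overfitting the
31-case training folds.

Held-out scores are thresholded at 0.5 (long = positive class) for the
confusion matrix, accuracy, PPV and NPV. Significance of the accuracy is the
exact upper tail of a Binomial(n, 0.5) null, computed by direct summation of
the binomial mass. The ROC summary is the *empirical* Mann–Whitney AUC (ties
count one half) with a class-stratified case-level percentile bootstrap
(2000 resamples, seeded) for the 95% CI. This is a deliberate design
decision: maximum-likelihood binormal ROC fitting is a separate estimation
model, and the empirical AUC is assumption-free and exactly reproducible;
bootstrap CIs are therefore not comparable to binormal-model CIs.

## The phantom and cohort simulators

`generate_phantom()` emulates what the segmentation scheme actually relies
on: compartments with distinct HU bands in the correct topology. Each slice
holds an air background (−1000 HU), an optional bed slab (0 HU) separated
from the body by an air gap, an elliptical trunk whose outermost ring is SFA
(−100 HU), a muscle wall (40 HU), and a visceral cavity of VFA (−90 HU) with
organ blobs (50 HU) and optional gas pockets (−600 HU) placed strictly
inside the cavity. The same 2D geometry repeats across slices, so
ellipse-ring formulas give analytic expected areas (the generator's
pixel-counted areas agree within 2% pixelization error). Gaussian HU noise is
truncated at ±3 SD, so for `hu_noise_sd ≤ 10` no compartment can cross the
−140/−40 HU thresholds and the ground truth remains exact under noise.

What the phantom does *not* emulate: realistic organ shapes, partial-volume
voxels at compartment boundaries, contrast enhancement, beam hardening, or
anatomies whose trunk violates row/column convexity. Perfect Dice scores on
phantoms therefore validate the mask logic and threshold conventions, not
performance on clinical images.

`generate_cohort()` simulates the statistical structure of the prediction
task: 32 cases (the published cohort size) split evenly into long/short
survival classes, a 7-feature pool with one informative feature whose class
means differ by 3 SDs plus six independent N(0, 1) noise features, and
survival months drawn uniformly on class-specific intervals meeting at the
midpoint of the class medians (defaults 40 and 18 months, overall median
near 29 months), so median dichotomization recovers the true classes. The
effect size of 3 represents a strongly informative marker; recovery tests
also run effect size 0 cohorts, whose LOCO accuracy must stay at chance.

## Numerical choices and degenerate inputs

- Constant feature columns z-score to zero, so a constant predictor degrades
  to intercept-only behaviour (score = class prevalence); aliased GLM
  coefficients are treated as zero; separation warnings are suppressed since
  saturated scores are valid for ranking.
- An empty SFA or VFA compartment leaves its HU moments `NA` rather than
  failing, except where the feature is explicitly requested (f8 with no VFA
  errors).
- Two empty masks have Dice 1 by convention.
- A predictive value whose predicted class is empty is `NA`.
- Configs are YAML; stage outputs are flat NIfTI/CSV/JSON files written next
  to a config snapshot, so a run is reproducible byte-for-byte from its
  output directory.

## Problem sizes used in validation

The recovery suite runs 96²-pixel 2-slice phantoms for unit tests and a
256²-pixel 5-slice phantom for the end-to-end check; prediction recovery uses
32-case cohorts, with the chance-level band estimated over 20 seeds. These
sizes were chosen so the full validation runs in well under a minute while
keeping per-class counts (16/16) identical to the published cohort.

## Known limitations

- The trunk scan assumes one dominant body component; arms resting on the
  abdomen or severe truncation artifacts would merge or split components.
- `min_component_size` interacts with pixel spacing; at very coarse spacing
  genuine interior structures can fall under the filter.
- The visceral mask includes the muscle wall by construction; VFA is
  unaffected (muscle is not fat), but the mask itself is a region cover, not
  a muscle/cavity separation.
- Bootstrap AUC CIs on 32 cases are wide and seed-dependent in their last
  digits; they are reported with a fixed seed for reproducibility.
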
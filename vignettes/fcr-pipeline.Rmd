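---
title: "From rectified EMG to the functional connectivity ratio: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rectified EMG to the functional connectivity ratio: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcrkit)
```

# The measurement model

## MEP quantification

A TMS pulse to one motor cortex elicits a motor evoked potential (MEP) in
the contralateral — and, after stroke, sometimes the ipsilateral — vastus
lateralis. The package quantifies each trial by two windowed areas of the
full-wave-rectified EMG trace:

* **MEP area**: trapezoidal integral over a window after the stimulus
  (default 20–60 ms, the lower-limb latency regime for this muscle);
* **pre-trigger area**: the same integral over a pre-stimulus window
  (default −110 to −10 ms) capturing tonic background activity.

The trial's response is the unitless ratio MEP area / pre-trigger area.
Normalizing by the subject's own background makes the response invariant to
amplifier gain and electrode impedance: multiplying a whole trace by any
positive constant leaves the ratio unchanged (a property the test suite
checks directly). Trials whose pre-trigger area is at machine epsilon are
flagged invalid and excluded from block means with a warning, rather than
producing an unstable division or failing a whole cohort run.

Windows are given in ms relative to the stimulus and mapped to the sample
grid as closed intervals `[start, end]`, so a constant c mV over a w ms
window integrates to exactly c·w mV·ms at any sampling rate. The area
operator itself is trapezoidal; with EMG sampled at kHz rates the
difference from any other Newton–Cotes rule is far below the noise floor.

## Recruitment curves and the FCR

Responses are averaged within each stimulation-intensity block (ratio
first, then mean), and an unweighted ordinary-least-squares line is fitted
to block means over intensity expressed as % of motor threshold. The fit
needs at least three points at two distinct intensities; fit quality is the
Pearson correlation r between intensity and response. Fits with r ≤ 0.85
are **retained but flagged** — a reusable tool has to define behaviour for
curves a study would simply report as clean — and cohort reports count the
flags. Intensities are normalized per stimulation configuration to that
configuration's own motor threshold, which is what makes slopes from
different coil positions comparable.

For each leg,

$$\mathrm{FCR} = \frac{\text{slope of ipsilateral recruitment curve}}
                      {\text{slope of contralateral recruitment curve}},$$

where "ipsilateral" for the paretic leg means the contralesional
hemisphere. FCR > 1 is labelled ipsilateral-predominant, FCR < 1
contralateral-predominant, and exactly 1 balanced — a deliberate knife-edge
with no tolerance band, matching the binary >1/<1 reading the statistic is
designed for. A negative contralateral slope invalidates the ratio and is
an error, not a number. Reciprocity (swapping the two fits gives the
reciprocal FCR, product 1 to 1e−12) is exposed as a self-check
(`fcr_swap_check()`).

The motor-threshold estimator returns the lowest tested intensity at which
at least half the trials exceed the response criterion (MEP area more than
0.1 mV·ms above the pre-trigger area, configurable). With a response that
is exactly zero at threshold and linear above it, the estimate is the first
grid point *above* the true threshold — the estimator cannot see a response
that is identically zero, so its resolution is one grid step.

## FA asymmetry, lesion volume, overlap

Mean fractional anisotropy is computed over manually-style delineated,
strictly binary ROI masks of the posterior limb of the internal capsule
(PLIC, which carries the corticospinal tract) in each hemisphere, plus an
anterior-limb (ALIC) control ROI expected to show no lesion effect. The
asymmetry index

$$\mathrm{FA_{asym}} = \frac{FA_{unaffected} - FA_{affected}}
                            {FA_{unaffected} + FA_{affected}}$$

is 0 for symmetric hemispheres, bounded in [−1, 1], and antisymmetric under
swapping its arguments. Lesion volume is voxel count × voxel volume; lesion
overlap with the corticospinal tract is the volume of lesion voxels whose
CST probability reaches a threshold expressed as a fraction of the map's
maximum (default 0.1, so maps scaled to any positive maximum behave
identically — the absolute threshold used in the original analyses of this
kind is not standardly reported). All volumes entering one computation must
share grid shape and voxel dimensions; the package assumes volumes are
pre-registered to a common space and performs no warping or partial-volume
weighting.

## The cohort battery

* **Spearman rho** with average ranks for ties, computed from the
  covariance of the rank vectors; the two-tailed p uses the t
  approximation `t = rho·sqrt((n−2)/(1−rho²))`, adequate at n ≈ 13–200
  (an exact permutation p would change nothing material at these sizes).
* **Paired t** on differences, df = n − 1.
* **2×2 within-subject ANOVA** of recruitment slopes over leg × side of
  stimulation, by direct sums-of-squares decomposition; only the
  interaction F (df 1, n−1) is reported, and for this design it equals the
  squared paired t on each subject's difference of differences — the test
  suite asserts that identity to 1e−10 against `stats::aov` as an
  independent route. When interaction and error sums of squares both
  vanish (all cells equal within subjects) F is reported as 0.
* **Multiplicity correction** is multiplicative with capping:
  `min(1, p × family_size)`. The family defaults to the number of
  correlations in the battery and is a single declared argument — the
  family sizes behind any given published corrected p are typically
  unstated, so raw and corrected p are both always reported.
* **Stepwise regression** is forward selection on partial-F p values
  (enter < 0.05, remove > 0.10 — the common defaults of the commercial
  packages this procedure mimics), with aliased candidates dropped under a
  warning and an intercept-only model as a legitimate outcome.

# The synthetic cohort generator

## What it emulates

One latent severity per subject, drawn over `severity_range`, drives
everything that should co-vary in a real cohort:

| quantity | link to severity | calibration |
|---|---|---|
| paretic-leg true FCR | monotone increasing | mean 1.7, range 0.27–2.6 |
| non-paretic true FCR | independent | mean 0.55, range 0.2–0.83 |
| lesioned-PLIC FA | decreasing | group mean 0.42 vs intact 0.54 |
| Fugl-Meyer (0–34) | decreasing + noise | mean 23.8, range 12–34 |
| walking speed (m/min) | decreasing + noise | mean 39.8, range 5.4–89.75 |
| lesion volume (mm³) | increasing × heavy log-normal jitter | loosely coupled by design |

Monotone links use a power map `lo + (hi − lo)·u^a` with the exponent
chosen in closed form so the mean over a full-range uniform severity equals
the calibrated mean while the endpoints hit the calibrated range. Severity
itself is a stratified uniform draw (one draw per equal-width stratum,
order shuffled), so cohort-level means are stable across seeds at the
modest n this package targets; individual subjects remain random. The
non-paretic FCR is a scaled Beta draw with matching mean. Lesion size
carries a log-normal jitter (SD 0.8 on the log scale) precisely so that
lesion volume is *not* a reliable severity marker — the generative analogue
of the empirical finding that simple lesion volumetrics track impairment
poorly.

EMG traces have a tonic pre-stimulus baseline (0.05 mV), a post-stimulus
silent period (the cortical silent period that follows an MEP in a
tonically active muscle), and a Gaussian-envelope burst centred at 40 ms
(SD 6 ms) whose within-window trapezoidal area is calibrated to
`true_slope × (intensity − 100)` times the deterministic pre-trigger area.
The calibration constant linking slope to mV·ms is fixed at 1 so recovered
and true slopes are directly comparable. Two consequences the tests lean
on: at 100 %MT the MEP area is exactly zero, and with noise off the fitted
slope recovers the true slope to machine precision (asserted at 1e−6
relative over 100 subjects, end to end). Additive Gaussian trace noise
(default SD 0.01 mV) enters both windows; because it is
intensity-independent it inflates the intercept, not the slope, so
cohort-level FCR bias stays below 5% at the default noise (also asserted).

FA phantoms are small grids (default 32×32×16 voxels at 2 mm isotropic)
with proportionally placed PLIC/ALIC boxes (refused if a custom grid cannot
hold them disjointly), per-voxel Gaussian noise (SD 0.02, clamped to
[0, 1] — truncated-Gaussian rather than Rician noise, adequate at ROI-mean
scale), a severity-scaled spherical lesion written *before* the ROI values
so ROI means stay exact, and a CST probability map with a lateral Gaussian
profile (SD 2 voxels) descending through the lesioned PLIC with maximum 1.

## What it does not emulate

No DWI acquisition, tensor fitting, or tractography — FA and the CST map
are generated directly. No registration error, no Rician noise floor, no
EMG filtering artifacts, stimulus artifacts, or trial rejection. No
biomechanical gait model behind walking speed. Passing tests therefore
demonstrate that the *pipeline algebra* is correct and that the statistics
recover a known embedded structure; they say nothing about robustness to
acquisition pathologies that the generator does not model.

# Numerical and design choices

* **Windows closed at both ends** on the sample grid, so constant-signal
  areas are exact; the generator calibrates burst areas with the same
  convention, which is what makes noiseless recovery exact rather than
  merely close.
* **Degenerate inputs** are contracts, not crashes: constant response
  curves fit with slope 0 and undefined r (flagged); constant columns in a
  cohort make the affected correlation `NA` with a note while the rest of
  the report completes; an all-equal 2×2 design has F = 0.
* **Determinism**: every generator stage derives a per-subject, per-stage
  sub-seed from the configuration seed, so identical configurations are
  bit-identical at every stage and subjects can be regenerated
  independently of cohort order.
* **Laterality at exactly 1** is "balanced" with no tolerance band; a
  band would manufacture a third class the downstream analysis never uses.
* **Problem sizes**: the shipped checks use 50-subject cohorts for ROI
  recovery (±0.01 on group-mean FA) and 200-subject low-noise cohorts for
  FCR recovery (±0.05 on group means) — sizes at which the stratified
  severity draw keeps sampling noise comfortably inside those bands on a
  desktop-scale run.
* The reference table's printed group means disagree slightly with the
  means of its own printed columns (e.g. paretic FCR 1.7 reported vs 1.46
  from the column); `reference_descriptives()` shows both and the package
  deliberately takes no side. Generator calibration follows the reported
  text values.
* Correlations recomputed from the rounded printed FA column differ from
  the originally reported ones by 0.02–0.04; `reference_correlations()`
  reports them with the gap flagged rather than asserting equality the
  rounding makes impossible.

# Known limitations

* The EMG model is linear in intensity over the tested grid; saturating
  (sigmoidal) recruitment at high intensities is out of scope because the
  statistic is defined on straight-line slopes.
* ROI masks are boxes, not anatomical tracings; this is irrelevant to the
  pipeline algebra but means phantom FA spatial statistics are not
  realistic beyond their means and noise.
* The Spearman p is approximate (t distribution); for n < 10 with many
  ties an exact method would be preferable if p itself, rather than rho,
  were the quantity of interest.
* Lesion volumes on the default 32×32×16 grid are necessarily far smaller
  than real human lesions in mm³; only their relative ordering and overlap
  logic matter at phantom scale.

```{r example, eval = FALSE}
# a complete desk-scale run
coh <- run_cohort(gen_config(n_subjects = 13, seed = 42))
print(coh$report)
autoplot(coh$report)

# the reference cohort
reference_correlations()
reference_descriptives()
```
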
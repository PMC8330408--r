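---
title: "Quantitative videofluoroscopic swallowing analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative videofluoroscopic swallowing analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspektr)
```

## The measurement problem

A videofluoroscopic swallowing study (VFSS) records a lateral X-ray video of
a barium swallow, typically at 30 frames per second. Trained raters annotate
each bolus: the frame numbers of key physiological events (the bolus passing
the mandibular ramus, hyoid burst onset, upper esophageal sphincter (UES)
opening and closure, laryngeal vestibule closure (LVC) onset and offset,
maximum UES opening, maximum pharyngeal constriction, swallow rest), a
frame-by-frame pixel track of the hyoid bone, pixel contours of the
pharyngeal lumen and of post-swallow residue, a UES diameter segment, and
ordinal safety scores (the 8-point Penetration--Aspiration Scale, PAS, and
LVC integrity). `aspektr` turns such annotations into a standard set of
derived swallowing parameters, quantifies dual-rater agreement, and fits the
hierarchical regression models used to separate the effects of age, sex and
sip volume on swallowing physiology.

The package deliberately starts *after* image processing: pixel tracking
from fluoroscopy video is a manual (or separately automated) task, and
annotations are the package's input. There is no video or DICOM decoding
here.

## Derived parameters

### Timing

All intervals are measured on the acquisition frame grid. A duration of $k$
frames at rate $f$ is reported as

$$\mathrm{ms}(k) = \left\lceil k \cdot \tfrac{1000}{f} \right\rceil,$$

the ceiling convention, which at 30 fps produces the value grid 0, 34, 67,
100, 134, ... ms. The convention is configurable (`frames_to_ms()` also
offers round and floor), but ceiling is the default because the standard
reporting grid in this literature (67, 134, 367, 467, 534, 634 ms) is
exactly $\lceil k \cdot 100/3 \rceil$. Frames are 0-based and intervals are
closed--open, so a same-frame interval is 0 ms.

Five interval parameters are derived from event pairs: swallow reaction time
(bolus past mandibular ramus to hyoid burst onset), the hyoid-burst-to-UES-opening
interval, UES opening duration, time-to-LVC (burst onset to the first frame
of most complete LVC) and LVC duration. Swallow reaction time is *signed*:
the hyoid burst can precede bolus arrival, and clamping negative values at
zero would bias cohort means upward, so the package stores them as negative
milliseconds.

### Anatomical scaling

Fluoroscopic magnification and body size are removed by expressing all
lengths as a percentage of the participant's C2--C4 cervical spine length
$L$ (units written %(C2--4)) and all areas relative to $L^2$ (%(C2--4)$^2$).
`anatomical_transform()` re-expresses a pixel point in a participant frame
with origin at the anterior-inferior corner of C4 and the Y-axis along the
spine toward C2. Input pixel coordinates are assumed to follow the image
convention (y grows downward); superior is positive Y after the transform,
and a configuration flag (`anterior = "left"` or `"right"`) selects which
image side is anterior, since recordings do not state the projection
direction. Every scaled output of the package is invariant under similarity
transforms of the raw pixel data -- rotation, translation, uniform scaling
and y-flips applied consistently to all coordinates -- which the test suite
checks directly.

Polygon areas use the shoelace formula; polygons with fewer than three
vertices count as absent (area 0), and total residue is always the sum of
the vallecular, pyriform-sinus and other-pharyngeal components.

### Hyoid kinematics

For each tracked frame the hyoid's radial XY position is the Euclidean norm
of its transformed coordinates. Peak XY hyoid position is the maximum over
the window from hyoid burst onset to swallow rest. Hyoid XY speed is the
change from the minimum to the peak position divided by the hyoid burst
duration.

Two definitional choices here were genuinely open and are package defaults
rather than field-mandated rules:

* **Hyoid burst duration** is defined as the interval from burst onset to
  the frame of peak radial position. This matches the speed definition's
  numerator window (minimum-to-peak change over the burst) and makes speed
  and burst duration mutually consistent; it is also the quantity used in
  the correlated-outcome families below.
* **The pre-peak minimum** is taken within the burst (onset to peak frame),
  not over the whole track: the ten lead-in frames annotated before the
  burst are context, not movement.

A zero-frame burst makes speed undefined; the package returns `NA` with a
warning rather than an infinite or imputed value. When a bolus contains
multiple swallows, event-based timing and kinematics refer to the initial
swallow's events, while residue is measured at the final swallow-rest frame;
the worst PAS score across the bolus' swallows is carried as `pas_max`.

## Dual-rater agreement and consensus

Each bolus is rated independently by two raters. Before consensus, the
package reports per item (each event, each derived measure, each score):
percent absolute agreement within a tolerance, mean absolute difference, and
the intraclass correlation. The ICC form is **ICC(2,1)** -- two-way random
effects, absolute agreement, single measure -- because raters are drawn from
a pool and randomly assigned, so rater must be a random factor, and a
systematic rater offset should count against agreement.

Discrepancies exceeding per-item thresholds are flagged. The default
thresholds (event frames ±3, UES diameter ±4 %(C2--4), areas ±10
%(C2--4)$^2$, residue ±1 %(C2--4)$^2$, exact match for PAS, LVC integrity
and swallow count) are anchored to the agreement bounds conventionally
reported for this protocol; the original threshold specification lives in a
protocol document outside this package, so they are configurable and should
be treated as defaults, not canon.

Flagged items require an explicit resolution (in a live study, the outcome
of a consensus meeting). Unflagged continuous items merge by the rounded
mean (round-half-to-even); categorical items take rater A's value; pixel
geometry merges coordinate-wise. `run_pipeline()` automates resolutions by
the same rounded-mean rule so the simulated pipeline can run end to end --
an explicit stand-in for human adjudication, not a model of it.

## Statistical stage

Analyses run on **participant means**: each continuous parameter is averaged
over the participant's boluses, giving one row per participant, because
boluses within a participant are not independent. The only bolus-level model
is the logistic regression for multiple swallows per bolus, where sip volume
varies bolus to bolus and a per-ml effect is only estimable at that level.

Descriptives are medians and quartiles (linear interpolation between order
statistics, the `type = 7` convention; configurable). A Pearson correlation
screen over all parameter pairs reports $|r| > 0.25$; outcomes that travel
together share a Bonferroni-corrected alpha,
$\alpha_m = \mathrm{round}(0.05/m, 3)$ for a family of $m$ outcomes. The
default families are declarative configuration, not recomputed from the
screen, because the connected components of the $|r| > 0.25$ graph would
chain distinct families together (LVC duration correlates with members of
both timing families): the early-timing family of 3 ($\alpha = 0.017$), the
opening/kinematics family of 5 ($\alpha = 0.01$), and the area/residue
family of 5 ($\alpha = 0.01$), with total residue analysed under the residue
family's alpha.

`hlm()` fits the hierarchical regression for one outcome: stage 1 age only,
stage 2 adds sex, stage 3 adds sip volume, each by ordinary least squares,
reporting coefficients, $R^2$, and $\Delta R^2$. Sex is coded male = 1,
female = 0, so the sex coefficient is the male--female difference.
$R^2$ is non-decreasing across stages by construction, and the package
asserts it. The sip stage is omitted for pharyngeal area at rest (a measure
taken outside swallowing activity) and for sip volume itself. Significance
of each predictor is judged at its entry stage against the outcome's family
alpha. Logistic models for PAS and LVC integrity are available but the
pipeline skips them when the minority class is too small to support
estimation (fewer than 5 participants), reporting why.

`two_by_two_or()` provides the post-hoc odds ratio for multiple swallows by
dichotomized sip volume (strictly greater than 16 ml versus not), with the
Woolf log-normal confidence interval and the Haldane--Anscombe 0.5
correction when a cell is empty (reported in the output, never silent).

## The synthetic cohort generator

No annotation data ship with the package; instead `generate_cohort()`,
`generate_parameters()`, `synthesize_annotations()` and `simulate_rater()`
produce a fully synthetic study whose *measured* quantities are calibrated,
so every stage of the pipeline is testable at desk scale.

The default cohort is 76 participants (38 male, 38 female), ages uniform on
21--82 years, 3 thin-liquid boluses each, recorded at 30 fps. Each
continuous parameter follows

$$y = \beta_0 + \beta_{\mathrm{age}} (\mathrm{age} - 70)
      + \beta_{\mathrm{sex}} \cdot \mathrm{male}
      + \beta_{\mathrm{sip}} (\mathrm{sip} - 14) + \varepsilon,$$

with intercepts anchored at age 70 to the published older-cohort medians
(e.g. UES opening duration 500 ms, UES diameter 23 %(C2--4), pharyngeal
area at rest 63 %(C2--4)$^2$), and the default slopes encoding the
study-scale effects: +4 ms/yr swallow reaction time, +1.4 ms/yr UES opening
duration, +2.4 ms/yr LVC duration, +0.11 %(C2--4)/yr and +0.27 %(C2--4)/ml
UES diameter, +0.31 %(C2--4)$^2$/yr and +11 %(C2--4)$^2$ (male) pharyngeal
area at rest, −2.4 ms/ml for the hyoid-burst-to-UES-opening interval, and a
+4.69 ml male--female sip-volume difference. Sip volume is centred at 14 ml
(near the published median of 13.58 ml) so intercepts stay interpretable.

Two reported numbers needed a decision:

* The published age slope for pharyngeal area at maximum constriction
  (3.5 %(C2--4)$^2$ per year) is not compatible with the same source's
  median of 2 %(C2--4)$^2$ for the 60-plus cohort (a 60-year age span would
  dwarf the median 60-fold). The generator default is 0.035 %(C2--4)$^2$/yr,
  reading the printed figure as a decimal-scale inconsistency; the
  discrepancy is documented here rather than silently corrected, and the
  slope is configurable.
* The multiple-swallows effect described as "increasing the odds by a factor
  of 0.09 per ml" cannot literally be an odds multiplier (a factor below 1
  decreases odds). It is interpreted as a log-odds slope of 0.09 per ml
  (odds ratio ≈ 1.094), which is consistent in direction and magnitude with
  the accompanying dichotomized odds ratio of 2.8 for large versus small
  sips. The generator's logistic intercept (−1.386) sets roughly 20 percent
  of boluses to be multiple-swallow at the centring volume.

**Noise calibration.** For the four age effects with a published variance
share (6 percent for swallow reaction time, 12 percent UES opening duration,
8 percent LVC duration, 10 percent UES diameter), the residual SD on the
participant-mean scale is derived, not guessed:

$$\sigma^2 = \beta_{\mathrm{age}}^2 \, \mathrm{Var}(\mathrm{age}) \,
             \frac{1 - R^2}{R^2},$$

with $\mathrm{Var}(\mathrm{age}) = 61^2/12$ for the uniform age range. The
hyoid-burst-to-UES-opening SD is calibrated the same way against its
13 percent sip-volume share. This makes variance explained itself a
recoverable quantity. Note that the calibration fixes the *population*
$R^2$; the mean *sample* $R^2$ at $n = 76$ sits slightly above it, as sample
$R^2$ does. Parameters with no published variance share (time-to-LVC, burst
duration, hyoid position and speed, areas, residue) use residual SDs chosen
once to respect the published interquartile ranges.

Residuals are correlated across parameters through a configured correlation
matrix (validated symmetric positive semi-definite at construction, with a
nearest-PSD hint on failure) whose defaults reproduce the signs and
magnitudes of the published cross-parameter correlations, e.g. ≈0.5 between
time-to-LVC and the hyoid-burst-to-UES-opening interval and −0.6 between
time-to-LVC and LVC duration. The residual is split into a participant
effect (80 percent of the participant-mean variance) and bolus noise (the
remainder, inflated by the bolus count so the participant-mean variance
comes out at the calibrated $\sigma^2$).

Non-negative parameters are truncated at zero rather than resampled; the
truncation rate is attached to the output and asserted below 5 percent under
defaults. Truncation is physically meaningful here -- a quarter of real
constriction-area and residue measurements are exactly zero -- but it also
attenuates fitted slopes for parameters whose mean sits close to zero. That
is why the residue intercepts (1.0 / 0.5 / 0.3 %(C2--4)$^2$) sit slightly
above the published medians of 0, and why the strict coefficient-recovery
assertions cover the six well-separated effects (swallow reaction time, UES
opening duration, LVC duration and UES diameter age slopes; the sip-volume
sex effect; the hyoid-burst-to-UES-opening sip slope) and not the
constriction-area slope, which is structurally attenuated by its own
truncation.

**Annotation synthesis.** `synthesize_annotations()` inverts the measurement
stage exactly: event frames are placed so the frame-grid durations equal the
(pre-snapped) true timings; the hyoid follows a half-cosine radial
trajectory from the implied minimum to the true peak, giving the true speed;
each region is a rectangle of the prescribed scaled area and the UES
diameter a segment of the prescribed scaled length; and the whole scene is
embedded in a randomly rotated, translated pixel frame with a sampled spine
length (normal, mean 100 px, SD 8 px). The round-trip identity
`summarize_bolus(synthesize_annotations(v)) = v` (timing exact, geometry to
$10^{-6}$ relative) is the package's central integration test. Timings are
snapped to the frame grid inside `generate_parameters()` so the true table
downstream statistics see is the same one annotations can realize.

**Rater noise.** `simulate_rater()` adds discretized normal jitter (SD 1
frame) to event frames with order-repairing clamps, 1 px normal jitter to
every coordinate, a 3 percent chance of shifting the worst-swallow PAS score
by one point, and a 1.5 percent chance of flipping LVC integrity -- rates
chosen so two independently perturbed raters agree exactly on PAS about
94 percent of the time and within a few frames on events, matching the
pre-consensus agreement conventionally reported for this protocol.

**What the generator does not emulate.** Contours are rectangles, not
anatomy; the hyoid trajectory is a smooth radial arc without tissue noise;
residuals are Gaussian (published summaries give no distributional
information beyond medians, quartiles and effects, so normality is an
assumption); missing data, swallow-count ambiguity and frame-rate drift are
absent. Passing tests therefore demonstrate that the *pipeline* is correct
and that the *analysis recovers known effects under its assumptions* -- not
that the generator reproduces real fluoroscopic data.

## Numerical choices and degenerate inputs

* Frame-to-ms uses a $10^{-9}$ guard before the ceiling so exact multiples
  are not pushed up by binary representation.
* Coincident C2/C4 landmarks, non-finite coordinates, empty rating vectors,
  single-class logistic outcomes, zero-margin 2×2 tables and rank-deficient
  designs all raise typed, named errors; zero-variance ICC inputs return
  `NA` with a warning.
* Missing events yield missing parameters (never imputed), logged with the
  participant and bolus identifiers.
* Ties in consensus merging resolve by round-half-to-even, so a (100, 103)
  frame pair merges to 102.

## Problem sizes used in the checks

The package's own validation uses: 200 simulated cohorts (seeds 1--200) for
effect-size recovery and variance-explained checks; 500 zero-effect cohorts
for the type-I-rate band at $\alpha = 0.05$; 240 records for the full
round-trip identity; and $4 \times 10^5$ Monte-Carlo points for the polygon
area oracle. These sizes keep Monte-Carlo error a small fraction of the
assertion tolerances and were fixed as part of the study design.

## Limitations

The package analyses annotations, not images; its agreement machinery
handles exactly two raters (no kappa or Krippendorff statistics, no
multi-rater designs); the regression stage is fixed-order hierarchical OLS
on participant means (no mixed-effects, imputation or Bayesian variants);
and the generator's defaults encode one study's effect structure -- useful
as a calibrated test bed and power-exploration tool, not as a normative
model of swallowing.
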
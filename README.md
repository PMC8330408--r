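# aspektr

Quantitative analysis of videofluoroscopic swallowing studies (VFSS) in R.

Clinicians and deglutition researchers rate VFSS recordings by marking event
frames (hyoid burst onset, UES opening and closure, laryngeal vestibule
closure, swallow rest, ...), tracking the hyoid frame by frame, and tracing
pixel contours of the pharynx and of post-swallow residue. `aspektr` turns
those per-bolus annotations into the standard derived parameter set
(frame-accurate timing in ms; hyoid kinematics, UES diameter and pharyngeal
areas in anatomically scaled %(C2–4) units), quantifies dual-rater agreement
before consensus, and models the influence of age, sex and sip volume on
each parameter. A calibrated synthetic cohort generator makes the whole
pipeline testable without patient data.

## The core models

**Anatomical scaling.** A pixel point `p` is re-expressed in a participant
frame with origin at the anterior-inferior corner of C4 and the Y-axis along
the C2–C4 spine (length `L`):

    x = 100 · (p − c4) · v / L ,  y = 100 · (p − c4) · u / L

with `u` the superior and `v` the anterior unit vector, so distances are
%(C2–4) and areas %(C2–4)². All scaled outputs are invariant under rotation,
translation, scaling and flips of the raw pixel data.

**Timing.** Durations of `k` frames at `f` fps are `ceil(k · 1000 / f)` ms —
the ceiling convention that generates the familiar 30 fps grid
(0, 34, 67, 100, 134, … ms). Swallow reaction time is signed.

**Agreement.** Percent absolute agreement within per-item tolerances, mean
absolute difference, and ICC(2,1) (two-way random effects, absolute
agreement, single measure):

    ICC = (MSR − MSE) / (MSR + (k−1)·MSE + k/n·(MSC − MSE)),  k = 2

**Hierarchical regression.** Per outcome, OLS on participant means in
stages — (1) age, (2) + sex (male = 1), (3) + sip volume — with R², ΔR² and
significance at Bonferroni family alphas `round(0.05/m, 3)` (families of 3
and 5 give 0.017 and 0.01). Multiple swallows per bolus are modelled by
bolus-level logistic regression, plus a 2×2 odds ratio for sips above vs
below 16 ml with a Woolf confidence interval.

## Worked example

Simulate a small dual-rated study and run the full pipeline (agreement →
consensus → measurement → participant means → regressions):

```r
library(aspektr)
cfg <- pipeline_config(cohort = cohort_config(n = 24, boluses = 3), seed = 42)
res <- run_pipeline(cfg)
#> simulate: 72 boluses from 24 participants (seed 42)
#> agree: 20 items over 72 pairs
#> consensus: 72 boluses, 28 flags resolved
#> measure: 72 parameter records
#> participant means: 24 rows
#> stats: 55 correlations above threshold
#> regressions: 16 outcomes

res$regressions$ueso_duration
#> Hierarchical regression for ueso_duration  (n = 24 , family alpha = 0.01 )
#>   stage1: R2 = 0.211 (delta 0.211)
#>   stage2: R2 = 0.275 (delta 0.064)
#>   stage3: R2 = 0.325 (delta 0.050)
#>   effects at alpha: age=no sex=no sip=no
```

The UES opening duration regression explains 21% of variance with age alone
(rising to 32% with sex and sip volume added), but at n = 24 none of the
predictors clears the family alpha of 0.01 — age effects of ~1.4 ms/yr need
the full cohort size to surface reliably. Pre-consensus agreement for a few
representative items:

```r
subset(res$agreement, item %in% c("pas_max", "ues_open", "ues_diameter"))
#>          item n_pairs pct_agreement mean_abs_diff       icc
#>      ues_open      72      97.22222    1.15277778 0.9549139
#>       pas_max      72      94.44444    0.05555556 0.8202532
#>  ues_diameter      72      94.44444    1.65564080 0.9720620
```

Raters agree on the UES-opening frame within the 3-frame tolerance 97% of
the time (mean difference ≈ 1.2 frames, ICC 0.95) and exactly on the worst
PAS score 94% of the time. `hlm()` objects support `summary()`, `coef()`,
`predict()`, `residuals()` and `simulate()`; `write_annotations()` /
`read_annotations()` round-trip annotation bundles as JSON, and
`write_parameter_csv()` emits the per-bolus parameter table with an optional
units header.

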
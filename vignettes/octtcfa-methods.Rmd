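---
title: "Methods: TCFA detection from OCT segmentation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCFA detection from OCT segmentation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`octtcfa` implements everything downstream of a multi-class OCT
segmentation model: per-frame plaque quantification, artefact-based
exclusion, thin-cap fibroatheroma (TCFA) calling at lesion, pullback and
patient level, reader-agreement statistics, and time-to-event outcome
analysis. This vignette records the measurement model, the tunable
parameters, the synthetic-data generator that stands in for patient data,
and the design choices made where more than one reasonable convention
exists.

## Measurement model

A segmentation frame is a square grid of class codes (background,
guidewire, lumen, intima, media, lipid, calcium, side branch, plaque
rupture, thrombus) with isotropic pixel spacing. Both plaque metrics are
defined about the **lumen centroid**, the arithmetic mean of lumen-pixel
coordinates; when the guidewire splits the lumen into several components
the centroid of all lumen pixels is still used.

Measurement discretises the frame into 360 angular bins of 1°. Each bin is
sampled along a ray from the centroid at radial steps of 0.5 px with
nearest-pixel lookup, recording the **lumen boundary radius** (the last
lumen-labelled sample of the initial contiguous lumen/guidewire run) and
the **first lipid radius**. Bins whose rays are dominated by the guidewire
(more than 30% guidewire samples) contribute no lipid evidence rather than
being imputed: the shadow hides tissue, and inventing lipid there would
bias the arc upward.

* **Lipid arc** = largest contiguous run of lipid-positive bins × 1°, with
  wraparound across 0°. Total lipid coverage (sum of all lipid bins) is an
  alternative convention; the contiguous-run definition is the common OCT
  reading convention and is what the package implements.
* **Minimum fibrous cap thickness** = min over lipid-positive bins of
  (first-lipid radius − lumen boundary radius) × pixel spacing. Candidate
  lumen/lipid pixel pairs that are direct 8-connected grid neighbours
  (Chebyshev distance ≤ 1 px) are excluded from the minimum, so a
  segmentation in which lipid touches the lumen cannot produce a
  zero-thickness cap: touching labels are a segmentation artefact, not a
  measurable cap. If lipid exists but every candidate pair is adjacent the
  cap is reported missing and the frame cannot qualify — a conservative
  degenerate-input rule that never occurs on masks with ≥ 1 px of intima.
* The cap is measured **radially from the lumen centroid**, not as an
  unconstrained 2-D nearest-pair distance; the unconstrained distance is a
  lower bound and is exercised only as a cross-check in the test oracles.
  Measuring along catheter A-lines instead of centroid rays is a plausible
  variant; the centroid convention is implemented because the cap is
  defined relative to the lumen, not the catheter position.

Coordinates are 0-based pixel indices (x = column, y = row); angles
increase counter-clockwise from +x. Ties at angular run boundaries are
resolved by half-open bins [k°, k+1°). On analytic test geometry these
choices recover a planted arc to within one bin and a planted cap to
within one pixel, and agree exactly with an exhaustive polar-transform
oracle under the same binning.

## Calling rules

All thresholds live in one object, `tcfa_thresholds()`, with the printed
inequality directions taken literally:

| parameter            | default | convention                          |
|----------------------|---------|-------------------------------------|
| `arc_min_deg`        | 90°     | inclusive (≥)                       |
| `cap_max_um`         | 65 µm   | strict (<)                          |
| `window_frames`      | 10      | consecutive frame positions         |
| `min_qualifying`     | 3       | within one window                   |
| `aline_artefact_max` | 0.25    | strict (>) — exactly 25% is retained|
| `retention_min`      | 0.50    | inclusive — exactly 50% is evaluable|

A unit (target lesion, or the complete imaged segment = whole pullback) is
TCFA-positive when some window of 10 consecutive frames holds ≥ 3
qualifying frames. By default the window slides over **retained** frames in
original order, with artefact-excluded frames removed rather than breaking
adjacency: exclusion means "unreadable", not "plaque absent", so two
qualifying frames separated by an unreadable gap remain neighbours. The
alternative (`window_mode = "original"`), in which excluded frames occupy
window positions as non-qualifying, is implemented and tested; the two
differ only when exclusions are frequent, which the artefact statistics
make rare. Patients are positive when any evaluable unit is positive;
patients with no evaluable unit leave that scope's analysis set, so the
target-lesion and complete-segment analysis sets may differ in size.

The AI rule and the reference-reader rule are deliberately distinct
objects: the reader's frame-level definition has no consecutive-frame
requirement (a single qualifying frame makes the lesion positive), while
the automated path requires the 3-of-10 window.

## Statistics

* **Cohen's κ** with the Fleiss–Cohen–Everitt asymptotic variance and a
  normal CI. No method is canonical for the κ standard error; this is the
  common large-sample default and was cross-checked against an independent
  implementation to machine precision. The package asserts it against
  published intervals only softly (± 0.02).
* **Proportion CIs** are Clopper–Pearson exact by default (Wilson as an
  option): exact intervals reproduce published predictive-value intervals
  at small denominators where Wald-type intervals do not.
* **Survival**: Kaplan–Meier, log-rank, and univariable Cox fits delegate
  to the `survival` package with Efron tie handling (Breslow optional);
  the package adds the monotone-likelihood guard (no events in one arm
  gives a flagged non-converged result rather than a silent huge HR).
* **C-statistic** of a binary exposure for the binary 2-year outcome —
  equal to (sensitivity + specificity)/2 — with DeLong variance and the
  paired DeLong test via `pROC`. Patients censored event-free before day
  700 cannot be classified at two years and are dropped from the binary
  outcome (configurable); events within 730 days count as positive. This
  convention is the package's own: DeLong applies to an AUC on a binary
  outcome, so some dichotomisation rule is unavoidable.
* p-values are two-sided; significance is never used as a filter.

## The synthetic cohort generator

No imaging data ship with the package; `simulate_cohort()` generates the
full latent structure of an observational OCT study and
`run_tcfa_pipeline()` rasterises and analyses it end to end. The defaults
encode the study scale the package targets:

* 414 patients; 1–3 target lesions each with probabilities 0.84/0.14/0.02
  (mean 1.18), one pullback per lesion, 540 frames per pullback;
* lesion lengths log-normal around a median of 200 frames (IQR roughly
  136–264);
* lesion-level TCFA prevalence 30.7%; an additional out-of-lesion TCFA
  plaque planted with probability 0.375 per patient, which lifts
  complete-segment prevalence to ≈ 59%. The split between these two
  parameters is not identifiable from summary statistics alone, so the
  out-of-lesion rate is an explicit configuration knob rather than a
  derived quantity;
* masks 704 × 704 px at 10 µm/pixel (65 µm ≈ 6.5 px), catheter at the
  image centre, 504 A-lines; the test and acceptance runs use 352 × 352 px
  at 20 µm/pixel, which halves resolution without changing any planted
  truth (see the guard band below);
* artefacts cluster by lesion: 25% of lesions draw per-frame artefact
  flags at rate 0.06, with the artefacted A-line fraction uniform on
  (0.05, 0.45). A homogeneous per-frame rate cannot simultaneously give a
  per-lesion excluded-frame median of 0% and a 90th percentile of ≈ 3%;
  lesion-level clustering reproduces both;
* follow-up: exponential event times with 2-year baseline risk 2.4% in
  complete-segment-negative patients and hazard ratio 5.5 for
  complete-segment TCFA carriers, administrative censoring at 730 ± 30
  days, and first-event types death/MI/revascularisation with
  probabilities 0.41/0.21/0.38. The target-lesion hazard ratio is **not**
  a separate dial: because target-lesion TCFA implies complete-segment
  TCFA, the marginal target-lesion HR ≈ 2 emerges from the nesting. The
  configured `true_hr_target_lesion = 2` is used directly only when a
  single exposure is simulated (e.g. parameter-recovery studies).

### Planted plaques and the threshold guard band

TCFA plaques carry 3–10 consecutive thin-cap frames (cap uniform on
40–60 µm) inside a thicker-capped lipid plaque; non-TCFA plaques are
either lipid-rich with caps on 90–150 µm or subtend arcs below 90°. Planted
caps deliberately avoid a band of about two pixels around the 65 µm
threshold: pixel-level measurement error (± 1 px by construction) could
otherwise flip a planted truth, and lesion truth must remain recoverable
exactly at both supported resolutions. Near-threshold behaviour — the
interesting clinical regime — is carried by the *reader* model instead.

### The reference reader

Manual TCFA reading errs in two distinguishable ways: the reader may not
locate the thinnest-cap frame (screening, not exhaustive measurement), and
a located frame is measured with error. The simulator mirrors both: with
probability `reader_frame_skill` (default 0.7) the reader finds the
thinnest-cap frame, otherwise reads a uniformly chosen plaque frame; the
chosen frame's cap and arc are perturbed with Gaussian noise (SDs 55 µm
and 20°) and the frame-level rule is applied. The three defaults were
calibrated once, jointly, against a lesion-level κ of ≈ 0.38 with the
observed asymmetry of discordance (about 45% of automated positives read
negative, about 17% of automated negatives read positive), and are not
revisited per run. With zero noise and skill 1 the reader reproduces
planted frame-rule truth exactly, which the tests exploit.

### What the generator does not emulate

Masks are ideal: no speckle or attenuation physics, no segmentation error
(the planted label *is* the truth), circular lumina with radial plaque
geometry, no calcium/rupture/thrombus classes planted, no FFR or
angiographic context, and no lesion-level event attribution. Passing tests
therefore demonstrate that the *rules and statistics* are implemented
correctly and that the pipeline recovers known truth through the imaging
path — not that any segmentation model is accurate on real OCT, and not
that real readers behave like the two-knob reader model.

## Numerical and reproducibility choices

* Rays terminate after 16 px of uninterrupted background beyond the lumen
  (the vessel wall is radially contiguous in every mask the package
  produces); full-length scanning is available and used by the test
  oracles.
* Frames with no planted plaque share one geometry per pullback and are
  quantified once — pure memoisation of a deterministic function.
* A single master seed drives everything; per-patient substreams are
  derived by stable string hashing of patient identifiers, so a cohort is
  reproducible and insensitive to patient iteration order. Identical seeds
  give byte-identical masks, tables and reports.
* Problem sizes in the shipped tests: the end-to-end acceptance run uses
  414 patients at 352² resolution (about a minute on one CPU); Cox
  parameter recovery uses 500 replicates of n = 414; the noise-free
  truth-recovery run uses 60 patients. These sizes keep Monte-Carlo error
  comfortably inside the asserted tolerances.

## Known limitations

* The cap is radial from the lumen centroid; for strongly eccentric lumina
  a 2-D nearest-pair cap can be smaller. The difference is bounded by the
  eccentricity and is zero for the generator's circular lumina.
* κ confidence intervals use the asymptotic SE; small-sample coverage is
  verified by simulation (93–97% at n = 300) but exact methods exist.
* The C-statistic dichotomisation drops early event-free censorings
  (about the single lost-to-follow-up pattern the design anticipates);
  heavy censoring would need a censoring-aware concordance instead.
* `window_mode = "retained"` vs `"original"` is a genuine ambiguity when
  exclusions are common; both are implemented, the default is documented,
  and at the calibrated artefact rates the choice is immaterial.
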
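---
title: "Ratiometric Ca2+ transient analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric Ca2+ transient analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Fura-2 is a ratiometric Ca2+ indicator: its excitation optimum shifts from
~380 nm (Ca2+-free) to ~340 nm (Ca2+-bound). Imaging a dye-loaded embryo
alternately at both excitation wavelengths and dividing the 340-nm image by
the 380-nm image pixel by pixel yields a ratio image `R = F340 / F380` that
increases monotonically with intracellular free Ca2+ and cancels
common-mode factors: dye concentration, path length, illumination
intensity, and photobleaching that affects both channels equally. caltrace
works entirely in these relative ratio units. No absolute [Ca2+]
calibration (dissociation-constant based conversion) is attempted, because
the downstream analysis — counting localized release events — only needs
relative changes.

A session is a pair of aligned image stacks at a fixed inter-frame
interval, 15 s by default, matching the acquisition protocol this pipeline
reimplements (blastula sessions of 300 image pairs; somite-stage sessions
of roughly 1000 pairs, i.e. 2 h and beyond). Typical sessions here are
480 frames, the 2-hour span the analysis targets.

## Ratio computation and masking

Background pixels carry no dye, so their ratio is numerical noise. Two
masks protect the analysis:

* **Embryo mask** (`compute_embryo_mask`): pixels whose time-mean 380-nm
  intensity is positive and at or above the `quantile_q` (default 0.1)
  quantile of the time-mean image, hole-filled. If the mask covers less
  than `min_fill` (default 5%) of the frame, the input is treated as a
  degenerate (empty) field of view.
* **Denominator floor** `eps`: a pixel-frame is valid only if
  `F380 >= eps`. The default, 1% of the channel's 99th percentile, is
  relative so it behaves identically across bit depths. Invalid pixels are
  excluded from every downstream statistic; they render black in
  pseudocolor output.

Optional spatial smoothing before detection is deliberately **off** by
default: the original analysis does not document any pre-filter, and
smoothing couples noise across pixels, which would invalidate the pooled
noise model below.

## The subtractive transient detector

`detect_events` implements a subtractive (frame-differencing) analysis:

1. Difference consecutive ratio frames, `D[t] = R[t] - R[t-1]`, on pixels
   valid in both frames.
2. Estimate one pooled noise scale robustly,
   `sigma = 1.4826 * median(|D - median(D)|)` over all valid difference
   pixels. The median absolute deviation ignores the sparse true events;
   1.4826 rescales it to a Gaussian standard deviation.
3. Threshold: a pixel is *rising* when `D[t] > k_sigma * sigma`
   (`k_sigma = 4`). Only increases are considered; release events are
   positive-going in the ratio.
4. Per frame, 8-connected components of rising pixels with at least
   `min_area_px` pixels (default 4) become detections.
5. Detections in consecutive frames whose footprints overlap by at least
   `link_min_overlap` (default 0.25) of the smaller footprint are linked
   into one event, so a spreading rise is a single event. Linking operates
   on *detection* footprints only. Separately, a pixel remains part of an
   ongoing event while its ratio stays above its pre-onset baseline plus
   the threshold — so event duration measures how long Ca2+ stays
   elevated, not merely the rising phase. A fresh rise on top of an
   already-elevated plateau is deliberately a *new* event: transients
   firing within a sustained high-Ca2+ domain are counted, not absorbed
   into the domain's event. `max_gap_frames` (default 0) controls whether
   a single sub-threshold frame splits an event.
6. Each event is measured — onset/offset frames (0-based), duration
   `(offset - onset + 1) * dt_s`, maximum footprint area, peak amplitude
   above the per-pixel pre-onset baseline, centroid of the peak-frame
   footprint — and labeled by the persistence rule.

**The 30-second rule.** A transient is a localized increase persisting no
longer than `d_max_s = 30` s; anything longer is sustained release. The
bound is inclusive, and durations count elevated frames, so at 15-s
sampling a 2-frame event is exactly 30 s (transient) and a 3-frame event
is 45 s (sustained). This makes the classification a sharp 2-frame
boundary at the default sampling rate.

**Footprint size never disqualifies an event.** Morphant phenotypes
include conspicuously *larger* areas of increased release that are still
transients; `area_px` is recorded, and an optional `max_area_px` exists
only for sensitivity analyses.

**Numerical edge cases.** On noise-free input the MAD is zero and the
threshold degenerates to "any increase", which is what makes exact
oracle comparisons possible. An all-invalid stack yields an empty event
table (not an error); fewer than 2 frames is a contract violation.

## Composite maps and the ROI contrast

`accumulate_composite` counts, per pixel, the transient events whose union
footprint covered it — each event incrementing each of its pixels exactly
once, so `sum(counts)` equals the summed footprint sizes (a conservation
property the tests assert). Sustained events are excluded by default
(switchable), since the composite is a map of *transient* activity.

`roi_contrast` implements the localized-suppression assay: a region of
interest is derived from the lineage-tracer reference exposure
(`roi_from_reference`: pixels at or above 50% of the image maximum,
largest 8-connected component), events are assigned inside/outside by the
pixel nearest their centroid, and rates per hour plus session-mean valid
ratios are reported per region. Centroid assignment is exact and makes the
in/out rates partition the total count; fractional-overlap assignment was
considered and rejected as it breaks this exact accounting.

## Developmental staging and group statistics

Somite number is the developmental clock: `stage(t) = s0 +
somites_per_hour * t / 3600`. Defaults `s0 = 2`, `somites_per_hour = 5`
make a 2-h session span somites 2 to 12, consistent with sessions that
start at the 2-6 somite stage and reach the 12-15 somite stage; both are
plain configuration because reported session lengths vary. Events are
assigned to a stage window by onset time; windows are half-open
`[s_lo, s_hi)` so adjacent windows partition a session exactly. The
headline quantity, transients per hour from somite 6 to 12, is
`rate_per_hour(table, clock, 6, 12)`.

Two tests cover the published comparisons:

* `fisher_exact_2x2`: the exact conditional test with the two-tailed
  p-value by the sum-of-small-probabilities rule (all tables with the same
  margins whose point probability is at most the observed one, ties within
  relative tolerance 1e-7). This is the dominant software convention; the
  suite verifies agreement with an independent enumeration oracle to
  1e-10 over every table with total at most 40.
* `anova_oneway_tukey`: textbook one-way ANOVA sums of squares with
  `stats::pf`, and Tukey HSD (Tukey-Kramer for unequal n) through the
  studentized-range distribution `stats::ptukey`. All pairs are reported
  regardless of the omnibus F, the standard HSD practice. `tidy()` returns
  the pairwise table, `glance()` the omnibus row.

Per-embryo counts behind the published group means are not available, so
the exact published F and p are not recomputable; what is testable — and
tested — is the decision pattern: with n = 3 per group and true rates 5.3
vs 21.7 per hour over 1.2-h windows, the Tukey contrast is significant at
alpha = 0.05 in well over 90% of simulated replicates.

## The synthetic movie generator

`simulate_scene` is the stand-in for raw imaging data that were never
deposited. It emulates, with known ground truth:

* an elliptical embryo on a dark background, baseline Ca2+ level
  `baseline_c = 0.15` (normalized units);
* sustained high-Ca2+ domains: two lateral presomitic stripes present
  throughout, plus four intersomitic boundary bands appearing sequentially
  and persisting, all at `delta_c = 0.15`. Geometry is configuration, not
  hard-coded biology;
* stochastic localized transients: homogeneous Poisson arrivals at
  `transient_rate_per_hour`, uniform marks — disc radius 2-3 px, duration
  1-2 frames (15-30 s), amplitude 0.25-0.4. Kinetics are rectangular
  because 15-s sampling cannot resolve sub-frame rise/decay and the
  detector is threshold/duration based;
* `morphant_mode`: radii +3 px and amplitudes x1.5, modeling the
  morphant's larger, stronger release events while durations stay in the
  transient range;
* `roi_suppression`: arrivals whose center falls in a disc ROI are thinned
  to `rate_multiplier` (default 0.1) of the ambient rate, and a 540-nm
  tracer reference image of the ROI is attached — the simulated analog of
  a suppressor-expressing clone marked by lineage tracer;
* optics: a linear two-state indicator model,
  `F = g_free (1 - c) + g_bound c` per channel with opposed gains
  (340 nm: 400 free / 2000 bound counts; 380 nm: 2000 / 400) plus a
  camera offset of 10 counts. The ~2000-count photon budget gives ~2%
  shot noise per channel, a realistic operating point for cooled-CCD
  ratio imaging, and leaves transient onsets at >10 robust SDs of the
  frame-difference noise;
* noise and drift: per-pixel per-frame Poisson shot noise, and exponential
  photobleaching applied to both channels with `tau_bleach_s = 36000`
  (~18% loss over 2 h — gentle exposure; bleaching cancels in the ratio
  except through the camera offset). A strong-bleach setting is possible
  but inflates late-session noise in dim high-Ca2+ regions, where a
  pooled threshold is then locally miscalibrated; the default keeps the
  scene within the regime the subtractive algorithm assumes (noise
  roughly homogeneous across the embryo).

Everything is seeded: identical `scene_params` give bit-identical stacks
and ground-truth logs. `score_detection` matches detected to true events
greedily (onset within 1 frame, centroid within 4 px by default) for
precision/recall/F1.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: cell movement and morphogenesis, indicator
compartmentalization and loading gradients, saturating or sub-frame
kinetics, spatially correlated (read/pattern) noise, focus drift, and the
wave-like propagation of release between neighboring cells. The morphant
mode reproduces the *statistics* of larger events, not their biophysics.

## Validation strategy and problem sizes

The detector is validated exactly against an independent brute-force
oracle: per-pixel thresholding against the pre-event baseline plus 3D
(26-connected) component labeling, on noise-free piecewise-constant scenes
up to 16x16x20 with events that are either spatially separated or
separated in time — the regime where per-frame linking and 3D labeling
provably coincide (with overlap-threshold linking, no such equivalence can
hold for arbitrarily entangled scenes; the tie-break there is the linker's
by design). Two hundred randomized scenes are compared per run.

Stochastic properties run at the study's conditions: 2-h, 128x128
sessions across the published rate span {1.3, 1.8, 5.3, 21.7}/h with 20
seeds per rate for rate recovery (mean estimate within the 95%
Monte-Carlo interval of the true rate; event-level precision and recall
at least 0.9); 50 seeds for the ROI-suppression contrast; 200 replicates
for the group-contrast power. Unit tests use smaller 64x64 sessions for
speed. These sizes were chosen to give stable Monte-Carlo estimates while
keeping a full check runnable on a laptop in minutes.

## Known limitations

* The pooled noise scale assumes roughly homogeneous ratio noise across
  the embryo; very bright sustained domains or strong bleaching violate
  this and can produce local false positives. A per-pixel noise model
  would handle it at the cost of the simple, auditable pooled threshold.
* Linking uses a single-frame overlap criterion; events that skip more
  than `max_gap_frames` frames fragment. Whether the original counting
  treated a one-frame dropout as one or two transients is not documented;
  the default (split) is the conservative choice and is configurable.
* Event merging: two transients overlapping in space and time are one
  detection. At the published rates this is vanishingly rare; at much
  higher rates counts would bias low.
* The stage clock is linear; real somitogenesis rate varies with
  temperature and stage. Calibrate `somites_per_hour` per experiment.
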
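---
title: "Oscillogram-based Cobb measurement and Lenke typing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillogram-based Cobb measurement and Lenke typing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillocobb)
```

## The measurement model

The package measures adolescent idiopathic scoliosis from corner-point
annotations of spine radiographs. Its core object is the *oscillogram*:
the ordered series of the 34 endplate tilt angles of T1–L5, cranial to
caudal. Every downstream quantity is a functional of this series plus
the vertebral centroids:

* **Tilt.** For an endplate with left corner $(x_1, y_1)$ and right
  corner $(x_2, y_2)$ in raster coordinates (origin top-left, $y$ down),
  $\theta = \operatorname{atan2}(y_2 - y_1,\, x_2 - x_1)$ in degrees.
  Positive tilt means the endplate slopes down toward image-right. The
  tilt is invariant under translation and uniform scaling of the
  landmarks, so pixel and millimetre annotations need no conversion; a
  global rotation of the radiograph by $\varphi$ shifts every tilt by
  $\varphi$.
* **End vertebrae and Cobb angle.** A scoliotic curve makes the tilt
  series swing from one extreme to the other: its end vertebrae appear
  as a peak–trough pair and the Cobb angle is the difference of the two
  extreme tilts. This is the classical Cobb construction restricted to
  the annotated endplate lines.
* **Regions.** Proximal thoracic (PT), main thoracic (MT) and
  thoracolumbar/lumbar (TL/L) readings are taken over fixed endplate
  spans: PT = T1-sup…T6-inf, MT = T5-sup…T12-inf, TL/L = T10-sup…L4-inf.
  The spans overlap on purpose — adjacent curves share end vertebrae.
  `region_cobb()` (span maximum minus span minimum) is the brute-force
  definition; `detect_curves()` must agree with it whenever a span
  contains a single peak–trough pair, and never exceed it.
* **Classification.** A curve is *structural* when its Cobb angle stays
  strictly above 25° on side-bending views; the *major* curve (largest
  coronal Cobb) is structural by definition. The (PT, MT, TL/L)
  structural pattern and the major region map onto Lenke types 1–6. The
  sagittal thoracic modifier thresholds T5–T12 kyphosis — the absolute
  tilt difference between endplates 24 (T12 inferior) and 9 (T5
  superior) of the sagittal oscillogram — at 10° and 40°, strict on both
  sides, so the boundary values themselves read `N`.

### Assumptions

The method assumes complete annotations (all 17 vertebrae, 4 corners
each), an approximately upright field of view (a rotated radiograph
shifts all tilts uniformly and biases nothing *relative*, but absolute
kyphosis and the modifier assume a level horizon), and that curve apices
fall in their customary bands (apex T2–T5 → PT, T6–T11 → MT, T12–L4 →
TL/L; T1 and L5 apices map to the nearest region). Whether image-left is
patient-left depends on the projection (AP vs PA), which the annotation
does not record; for this reason convexity is reported in image terms
and never enters the classification, which is mirror-invariant.

## Tunable parameters

All angles are degrees; defaults live in `run_config()`.

| parameter | default | role |
|---|---|---|
| `min_prominence` | 5 | topographic prominence below which a local extremum of the 34-point series is treated as jitter. At the default landmark noise scale (~2 px on ~95 px endplates) pure noise produces tilt wiggles of a few degrees; 5° suppresses them without swallowing genuine end vertebrae. |
| `min_cobb` | 10 | smallest peak–trough difference accepted as a curve; below this the region reports the span range as a "no curve" fallback. Curves under ~10° are clinically not scoliosis. |
| `structural_threshold` | 25 | the bending-view rule; strict inequality. |
| `modifier_low`, `modifier_high` | 10, 40 | sagittal modifier band; strict on both sides. |
| `lock_end_vertebrae_on_bending` | FALSE | re-detect extrema freely on each bending view (default) or evaluate the bending tilt difference at the coronal end endplates. |

The thresholds 25/10/40 are the classification rules themselves; the
prominence and minimum-Cobb values are detection settings with no
canonical source, chosen once as above. No smoothing is applied by
default — 34 points is short, and smoothing would blunt exactly the
extrema the method reads.

## Numerical and design choices

* **Ties break cranial** everywhere (span argmax/argmin, apex
  selection), making outputs deterministic.
* **Curve ownership of slopes.** A detected curve owns the monotone
  slopes flanking its extremum pair: its interval is widened to the
  neighbouring retained extremum (inclusive — shared end vertebrae) or
  the series end, then clipped to its region's span, and the end
  endplates are re-located at the interval's extreme tilts. This handles
  two real geometries cleanly: a spine that enters the image already
  tilted (the boundary shoulder has no prominent extremum but carries
  the curve's full tilt), and a pair straddling a region boundary. It
  also guarantees `detect_curves()` ≤ `region_cobb()` with equality in
  the single-pair case — the property the test suite checks over
  hundreds of randomized spines.
* **End vertebrae as endplates.** The reported ends are whichever
  endplate (superior or inferior) carries the extreme tilt; the
  classical superior-of-upper / inferior-of-lower convention is not
  forced, because the oscillogram selects endplates, not surfaces.
* **Bending residual = minimum over available bending views.** The
  side labels are not tied to curve convexity (and patient side is
  unresolvable anyway); the minimum captures the best achieved
  correction, which is what the structural rule is about. The view used
  is recorded.
* **Degenerate input.** A vertical endplate (left and right corners at
  the same x) raises an error naming the vertebra rather than returning
  ±90°: at radiographic scales it can only be an annotation mistake.
  A flat spine yields zero Cobb everywhere and an explicit
  "no curve ≥ min_cobb" note instead of a type.
* **Unmapped patterns.** The six types cover the patterns with a
  thoracic or thoracolumbar major curve; anything else (e.g. a PT-major
  case) returns `NA` with a note, never a guess. A major-curve Cobb tie
  breaks MT → TL/L → PT and is flagged in the notes.
* **Lumbar modifier.** Always `NA`: A/B/C requires the centre sacral
  vertical line, which needs pelvic landmarks outside the T1–L5 model.
* **The original Lenke sagittal structural criteria** (regional
  kyphosis T2–T5 / T10–L2) are not applied — the oscillogram protocol
  uses only the bending rule. `run_config()` reserves a switch for a
  canonical variant, off by default.

## The synthetic spine generator

`simulate_case()` is the test bed for everything else, so its design is
worth spelling out.

The tilt profile along normalized spine length $s \in [0,1]$ is a sum of
per-curve lobes
$$\theta(s) = \sum_k c_k\, A_k\, f\!\left(\frac{s - s_k}{w_k}\right),
\qquad f(u) = u\, e^{(1-u^2)/2},$$
with $c_k = \pm 1$ by convexity, amplitude $A_k$ (degrees), apex
position $s_k$ and width $w_k$. $f$ is a normalised derivative of a
Gaussian: zero at the apex (apex endplates are the most level), extreme
values $\mp A_k$ at $s_k \mp w_k$ (the end vertebrae), decaying beyond.
A Gaussian *bump* in tilt would instead put the extreme tilt at the
apex, which matches neither anatomy nor the end-vertebra semantics, so
the lobe form is the derivative. An isolated curve therefore contributes
a coronal Cobb of about $2A_k$; overlapping curves interact, and the
generator's ground truth is always computed from the summed, noise-free
tilt series by the same region max−min rule as `region_cobb()` — which
is what makes "measurement reproduces truth exactly at zero noise" a
meaningful end-to-end property rather than two independent
approximations.

Geometry: vertebral boxes (default 25 × 35 mm, 8 mm discs; T1–L5 =
553 mm) are placed along the centerline obtained by integrating the
lean angle, with the whole spine scaled to 1500 px — a typical digital
full-spine radiograph — so landmark noise is specified in pixels at
that scale (default sd 1.5 px; the stress tests use 2 px). The
`wedging_fraction` (default 0.3) sets how much of the local tilt is
expressed as endplate non-parallelism (vertebral wedging, as seen in
progressing deformities) versus rigid body rotation.

Bending views rescale each curve's amplitude by $1 - $`flexibility` on
its corrective side (bending toward the convexity) and leave the other
side unchanged — the simplest model that produces the
structural/nonstructural dichotomy. The sagittal view ramps smoothly
between T5 and T12, flat across both end vertebrae, so the target
kyphosis is met exactly whatever the wedging.

The six `preset_for_type()` parameter sets are deliberately *clear-cut
prototypes*: amplitudes and flexibilities were chosen (guided by
typical AIS cohort magnitudes — main thoracic curves around 40–50°,
thoracolumbar around 35–45°) so that structural residuals sit roughly
5° or more above the 25° switch-point, nonstructural residuals
comparably below it, and major curves are separated by at least ~8°.
Because the three regions' readings couple through the overlapping
spans (a structural MT curve's corrected bending amplitude leaks into
both neighbouring spans), nonstructural residuals cannot be pushed
arbitrarily low; the presets accept this and keep the margins instead.
Kyphosis targets vary by type between 18° and 30°, all modifier `N`.

What the generator does *not* emulate: rib and scapular occlusion,
vertebral rotation and its projection effects, annotation biases that
are correlated across corners (its noise is i.i.d. Gaussian per
coordinate), non-Gaussian outliers, and the joint distribution of curve
parameters in any real cohort. Passing the recovery tests therefore
demonstrates correctness of the geometry and the rules under the stated
noise model, not clinical performance on radiographs.

## Agreement statistics

`icc()` implements ICC(2,1) — two-way random effects, absolute
agreement, single measure — as the default form, the standard choice
for method-comparison designs where systematic offsets between raters
must count against agreement; ICC(3,1) and the average-measure forms
are options. Estimates come from the ANOVA mean squares and confidence
intervals from the classical F-distribution formulation; the raw
estimator is reported unclamped. The test suite checks the estimator
against a from-scratch ANOVA oracle and against values frozen from an
independent Python implementation on a fixed matrix. Applying an ICC to
integer-coded Lenke types mirrors common agreement-table practice but
treats categories as interval data; `compare_measurements()` therefore
reports unweighted Cohen's kappa alongside. Missing indicators are
dropped listwise per indicator, with a message giving the count.

## Problem sizes

The shipped tests and the acceptance script use 500 randomized spines
for the detection-vs-oracle property, 300 simulated cases at 2 px
landmark noise for the stochastic recovery check (mean absolute Cobb
error and Lenke-type accuracy), 20 random matrices for the ICC oracle
property, and 1000 pairs for the closed-form MAE check; the whole suite
runs in a few minutes on one CPU. These sizes put the Monte-Carlo error
of each stochastic check well inside its assertion margin.

## Known limitations

* No landmark detection: the package starts from corner annotations,
  and its accuracy is bounded by theirs.
* Regions are assigned by apex bands and fixed spans; spines with
  anomalous apex positions (e.g. high PT apices at T1) fall back to the
  nearest region.
* The lumbar modifier and the original Lenke sagittal structural
  criteria are out of scope (above).
* Coronal balance, vertebral rotation and 3-D reconstruction are not
  modelled; the oscillogram is a strictly 2-D construction per view.
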
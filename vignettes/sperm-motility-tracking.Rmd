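---
title: "Multistage sperm motility tracking: model, parameters and design"
author: "SpermMotility package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage sperm motility tracking: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpermMotility)
```

## The problem

Computer-assisted sperm analysis (CASA) estimates sperm motility from
microscopy video of a semen sample. Motility is the clinically most
informative of the classical semen parameters: the WHO classifies each sperm
as *fast progressive* (mean velocity at or above 25 µm/s), *slow
progressive* (moving, but slower) or *immotile*, and a sample is called
normal when the motile fraction — (FP + SP) / (immotile + FP + SP) — reaches
40 %.

This package implements a two-stage tracker for such videos:

1. **Detection.** A per-pixel adaptive Gaussian mixture background model
   separates moving sperm heads from everything static (background,
   immotile cells, debris). The binary foreground mask is cleaned with
   morphological opening and closing, 8-connected regions are labeled, head
   centres are computed from image moments, and regions whose elliptical
   area is below 150 px² are discarded as debris.
2. **Tracking and motility.** Detections on every 10th frame are linked by
   a Euclidean distance gate (125 px) and an area-similarity gate (ratio
   ≤ 1.2). Tracks are converted to step velocities, averaged, classified
   into WHO classes, and aggregated into the sample-level normal/abnormal
   call.

A detection-evaluation module scores detections against ground truth
(accuracy, sensitivity, specificity) and summarizes per-sample results as
mean ± population standard deviation.

## The background model

Each pixel holds $K = 3$ Gaussians $(\pi_k, \mu_k, \Sigma_k)$ over 8-bit
intensity. For every new frame:

* components are ranked by $\pi_k / \sqrt{\Sigma_k}$ (high weight, low
  variance first);
* the **background** is the shortest prefix of that ranking whose cumulative
  weight reaches the *background ratio* $BG_T$;
* the pixel **matches** the first ranked component with
  $|x - \mu| \le \lambda \sqrt{\Sigma}$ ($\lambda = 2.5$);
* weights decay, $\pi \leftarrow (1 - \alpha)\pi$, with $+\alpha$ added to
  the matched component ($\alpha = 0.05$); the matched component's mean and
  variance move toward the observation with rate
  $\rho = \alpha \exp(-(x-\mu)^2 / 2\Sigma)$ — the match density normalized
  by its own peak, so $\rho \in (0, \alpha]$ and a perfectly matching
  observation adapts fastest;
* a pixel matching no component replaces its lowest-weight component with a
  new Gaussian centred at the observation (variance 225, weight 0.05), and
  weights are renormalized;
* the pixel is **foreground** iff it matched no background component.

The model is seed-free and bit-for-bit reproducible. Two numerical floors
guard degenerate states: variances never fall below 4 (intensity²), and new
components always receive weight 0.05 before renormalization.

### Start-up schedule

The mixture is bootstrapped from the first frame with full weight, so any
object present at frame 1 writes its own intensity into the "background".
With a constant $\alpha$, the true background revealed when that object
moves away would need roughly $2/\alpha$ frames to take over, leaving a
*ghost trail* that merges with the head and distorts its area during the
first sampled frames. We therefore use the standard start-up schedule of
adaptive mixture models: the effective learning rate is
$\max(\alpha, 1/t)$ at frame $t$, which makes the early model an
(approximately) unweighted running estimate and clears bootstrap ghosts
within the burn-in period. It can be disabled
(`backgroundParams(adaptiveStart = FALSE)`).

### Automatic choice of the background ratio

$BG_T$ is the one stage-1 parameter that genuinely depends on the sample.
The optimizer evaluates the grid 10 %, 20 %, …, 100 %: for each value a
fresh model is trained on the burn-in prefix (30 frames by default), the
first post-burn-in frame is classified, cleaned and counted, and the value
with the most valid detections wins; ties go to the smallest value
(stricter foreground). Because the update equations do not involve $BG_T$,
all grid values see the identically trained model — the search is a pure
threshold selection, and a brute-force re-evaluation of the grid reproduces
the optimizer's choice exactly (this is asserted in the test suite). The
grid includes 100 % for completeness even though at $BG_T = 1$ every
component is background and only unmatched pixels are foreground.

Classifying one frame per grid value mirrors the design of the protocol
this package implements (one evaluation frame per video); a burn-in is
nevertheless required because a mixture model without history cannot
separate movers from statics.

## Detection choices

* **Morphology.** Opening-then-closing with a disk structuring element of
  radius 3 (7 × 7). The disk preserves the rounded head outline; radius 3
  removes sub-head specks while leaving ≥ 150 px² heads intact. Line and
  square elements are available for comparison.
* **Connectivity.** Regions are 8-connected (a 4-connected labeling is
  merged across diagonal contacts), the common choice for blob detection.
* **Moments.** Centroids are $n_{10}/n_{00}$, $n_{01}/n_{00}$ over the
  region's pixels; ellipse semi-axes come from the eigenvalues of the
  second-central-moment matrix with the $1/12$ pixel-integration term on
  the diagonal, so even degenerate (single-pixel, collinear) regions have
  positive axes.
* **Area rule.** The 150 px² threshold is applied to the *elliptical* area
  $\pi a b$ with $a, b$ the moment SEMI-axes, inclusively (exactly
  150 px² is kept). Reading the rule with full axes would overstate the
  area fourfold and make the threshold correspond to implausibly small
  heads; the full-axis reading remains available via
  `filterDetections(axisConvention = "full")`. The raw pixel count is
  recorded alongside.

## Tracking choices

Association is greedy nearest-first: all (track, detection) pairs passing
both gates are sorted by distance (ties: smaller area ratio, then lower
track id, then detection order) and consumed one-to-one. A global optimal
assignment is deliberately not used — per-sperm closest-and-most-similar
matching with deterministic tie-breaks matches the method this package
implements, and the two coincide whenever objects are separated by more
than twice the gate (asserted against an exhaustive-matching oracle in the
tests).

Lost tracks are frozen, never resurrected: a sperm that leaves the field of
view and re-enters (or is missed once) continues as a *new* track. The
125 px distance gate was calibrated for a 10-frame stride; if the stride is
changed, `trackingParams(scaleGateWithStride = TRUE)` scales the gate
linearly, but by default it stays fixed.

The background model consumes **every** frame; only detection, association
and velocity use the stride. Velocities divide the micrometre displacement
by the elapsed time (stride/fps). A literal mode that divides the pixel
displacement by the frame rate alone — ignoring both the pixel scale and
the stride — is provided for comparison
(`stepVelocity(literal = TRUE)`) but is dimensionally not a physical
velocity, and is clearly labelled as such.

**Units.** The default pixel scale is 0.2 µm/px, plausible for a 640 × 480
camera at ×400 magnification; every velocity scales linearly with it, so it
is always an explicit, overridable parameter (`readFrames`,
`generateVideo`). A 0.2 *mm*/px setting, which some CASA write-ups print
(likely a unit slip), can be selected explicitly if needed.

**Immotile sperm.** By construction the detector only sees movers, so the
sample's immotile count cannot come from the tracker alone.
`summarizeSample()` takes a `totalSpermCount` (from ground truth, a static
count of the first frame, or operator input) and computes immotile =
total − tracks, plus any track with mean velocity under 1 µm/s.

## WHO boundaries

The FP boundary is *inclusive* ($v \ge 25$ µm/s is fast progressive), and
the sample-level rule is inclusive as well (motile fraction ≥ 0.40 is
normal): with ten published per-sample counts as a worked example, one
sample sits exactly at 40 % and is reported normal, which fixes the
boundary convention. Both thresholds are arguments, not constants.

## The synthetic-data generator

All tests run on generated video with exact ground truth. The generator
emulates the features the tracker actually exploits:

* bright elliptical heads (default semi-axes 8–11 px, i.e. head lengths of
  3.2–4.4 µm at 0.2 µm/px, the WHO head-size range; intensity 200 on
  background 60) moving along straight constant-velocity paths at 1–4
  px/frame (10–40 µm/s at 50 fps), reflecting off or exiting borders;
* immotile heads and sub-150 px² debris, static;
* i.i.d. Gaussian sensor noise (σ = 5), clipped to [0, 255];
* exact per-frame ground truth (continuous centres and rendered pixel
  areas), serialized as JSON.

Objects never overlap: static objects are rejection-sampled away from every
motile trajectory. This matches the tracker's declared scope — colliding or
merging sperm are a known failure mode of the method, not something the
generator should produce by accident. Deliberately *not* emulated: flagella
and midpieces (the method tracks heads only), focus drift, illumination
flicker (a static gradient is available behind a flag), Brownian jitter of
"immotile" cells, and collisions. Passing tests on this generator therefore
validate the algorithmic chain — background separation, moment geometry,
gating, bookkeeping, unit conversion — not robustness to those real-world
nuisances.

The benchmark scene used by the acceptance script places five motile heads
on horizontal lanes 96 px apart with staggered starts (all initial pairwise
separations > 250 px) at speeds 1.4–4.0 px/frame (14–40 µm/s, both WHO
classes, away from the 25 µm/s boundary), with three immotile heads and
twenty debris blobs, for 300 frames at 640 × 480. The lane geometry keeps
every pair at least 96 px apart at all times while per-stride displacements
stay ≤ 40 px, which makes greedy association provably unambiguous; headings
are chosen so no object bounces before the model has burned in, since an
object retracing its own path during start-up sits on unlearned background.

## Problem sizes and runtime

The default test suite works on small frames (up to 320 × 240) except for
one full-scale end-to-end run (640 × 480 × 300 frames, ≈ 1.5 min); the
acceptance script repeats that run plus a 60-frame optimizer check. The
mixture update is fully vectorized over pixels (three 307 200 × 3 matrices
at full frame size).

## Known limitations

* Touching or colliding heads merge into one region (no watershed split).
* Very slow objects (≪ 1 px/frame) are eventually absorbed into the
  background — inherent to adaptive background subtraction; such sperm are
  counted as immotile, consistent with the method's definition.
* AVI/MP4 containers are not decoded; videos are consumed as directories of
  lossless still frames (extract with ffmpeg or similar).
* No kinematic panel (VCL/VSL/ALH/LIN…): the pipeline reports one mean
  velocity per sperm, which is all the WHO three-class scheme needs.

## A worked example

```{r example, eval = FALSE}
cfg <- synthConfig(width = 320, height = 240, nFrames = 80, nMotile = 3,
                   nImmotile = 2, nDebris = 6, border = "reflect", seed = 7)
video <- generateVideo(cfg)
res <- trackVideo(video$frames, backgroundParams(burnInFrames = 20L))
motilityTable(res$tracks)
summarizeSample(res$tracks, totalSpermCount = 5)
```

The README shows the same example with the numbers it prints.
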
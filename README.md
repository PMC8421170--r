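# SpermMotility

Computer-assisted sperm analysis (CASA) for grayscale microscopy video, in
R. The package answers the clinical question behind a semen motility exam —
*how many sperm move, how fast, and is the sample normal?* — with a
two-stage pipeline:

1. **Detection** — a per-pixel adaptive Gaussian mixture background model
   separates moving sperm heads from the static scene. Each pixel carries
   K = 3 Gaussians (π, µ, Σ) ranked by π/√Σ; the shortest prefix whose
   cumulative weight reaches the *background ratio* BG_T models the
   background, and a pixel is foreground iff it matches no background
   component (match: |x − µ| ≤ λ√Σ, λ = 2.5). BG_T is optimized per sample:
   the value on the 10 %…100 % grid that maximizes the number of valid
   detections on the first post-burn-in frame wins. Masks are cleaned by
   morphological opening/closing (disk SE), heads are localized by image
   moments (centroid = (n₁₀/n₀₀, n₀₁/n₀₀)), and regions with elliptical
   area πab < 150 px² are discarded as debris.
2. **Tracking & motility** — detections on every 10th frame are linked
   greedily under a distance gate (‖S_c − S_p‖ ≤ 125 px) and an area-ratio
   gate (max/min ≤ 1.2). Track velocities (µm/s, via the pixel scale and
   frame rate) are averaged, classified per WHO (fast progressive ≥ 25 µm/s,
   slow progressive below, immotile ≈ 0), and the sample is called normal
   when the motile fraction reaches 40 %.

An evaluation module scores detections against ground truth
(accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN), specificity =
TN/(TN+FP), in percent) and summarizes per-sample results as mean ±
population SD. A seeded synthetic-video generator with exact ground truth
makes the whole pipeline testable without any external data.

For whom: anyone building or validating CASA-style motility analysis —
reproductive-medicine labs prototyping automated semen analysis, and
image-analysis researchers who need a transparent, fully testable reference
tracker.

## Worked example

```r
library(SpermMotility)

# three motile heads at 1.5 / 2.2 / 3.5 px/frame (15 / 22 / 35 um/s),
# two immotile cells, six sub-threshold debris blobs
init <- data.frame(x = c(40, 280, 160), y = c(60, 120, 180),
                   speed = c(1.5, 2.2, 3.5), heading = c(0, pi, 0))
cfg <- synthConfig(width = 320, height = 240, nFrames = 100, nMotile = 3,
                   nImmotile = 2, nDebris = 6, border = "reflect",
                   motileInit = init, seed = 7)
video <- generateVideo(cfg)        # frames + exact ground truth
res <- trackVideo(video$frames)    # BG_T auto, burn-in 30 frames
res$bgt
#> [1] 0.1
motilityTable(res$tracks)
#>   track_id mean_velocity velocity_sd n_obs        who_class
#> 1        1      15.00001  0.01014504     7 slow_progressive
#> 2        2      22.00005  0.05082204     7 slow_progressive
#> 3        3      33.00629  4.90208408     7 fast_progressive
summarizeSample(res$tracks, totalSpermCount = 5)
#> SampleSummary: 5 sperm | 1 fast progressive, 2 slow progressive, 2 immotile
#>   motile fraction 0.600 -> normal
```

Reading: the optimizer picked BG_T = 0.1 (10 %) for this clip; the three
motile heads were recovered as three tracks observed on all seven sampled
frames (31, 41, …, 91), with mean velocities of 15.0, 22.0 and 33.0 µm/s —
within a fraction of a percent of the true 15 / 22 / 35 µm/s (the fast
object's small deficit comes from border bounces shortening the sampled
chords). One sperm is WHO fast progressive (≥ 25 µm/s), two are slow
progressive. With the operator-supplied total of 5 sperm, the two
undetected (immotile) cells give a motile fraction of 3/5 = 60 % ≥ 40 %,
so the sample is classified normal.

Real videos enter as directories of lossless still frames:

```r
fs <- readFrames("frames/", fps = 50, pixelScaleUm = 0.2)
res <- trackVideo(fs)              # BG_T chosen automatically
writeTracks(res$table, "tracks.csv")
```

A thin CLI over the same functions lives in `inst/scripts/spermtrack.R`
(`track` and `eval` subcommands).

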
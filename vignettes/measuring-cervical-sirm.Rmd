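---
title: "Measuring cervical sagittal intervertebral rotational motion"
author: "cervimotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cervical sagittal intervertebral rotational motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Cervical kinematics are routinely assessed from three lateral radiographs of
the same patient: one in flexion, one in neutral posture, one in extension.
The quantity of interest is the **sagittal intervertebral rotational motion
(SIRM)**: how much each motion segment (C2/3 through C6/7) rotates in the
sagittal plane between two postures. Manual measurement requires an expert to
mark vertebral body corners on each of the three views, which is slow and a
major source of observer variability.

`cervimotion` implements the complete automated pipeline:

1. a fixed **22-landmark scheme** — the four body corners (`G1` anterior-
   superior, `G2` posterior-superior, `G3` anterior-inferior, `G4`
   posterior-inferior) of C3–C7 plus the two inferior corners of C2 (`B3`
   anterior, `B4` posterior);
2. **geometric-midplane angle computation**: the midplane of a typical
   vertebra is the line through the midpoint of its anterior corners and the
   midpoint of its posterior corners; C2 is represented by the line through
   B3 and B4. The segmental angle is the wrapped difference of the two
   adjacent line angles, and SIRM is the difference of segmental angles
   across two views;
3. a compact **heatmap-regression landmark detector** (multi-resolution
   convolutional network, 22-channel output, MSE loss, argmax decoding);
4. the full **evaluation battery**: landmark distance reliability, PCK/MPCK,
   reference-standard construction, ICC, Pearson r, MAE, RMSE, Bland–Altman
   limits of agreement, and paired rater-versus-model MAE comparisons;
5. an articulated **synthetic spine simulator** that makes every stage
   testable without access to clinical radiographs.

## Conventions and the sign of an angle

Image coordinates are 0-based pixels, origin top-left, y downward; all
geometry converts internally to a y-up millimetre frame (the flip cannot
change measured angles, only their sign convention). Before any angle is
computed a view is **facing-standardized**: if the anterior landmarks do not
lie at larger x than the posterior ones, the view is x-mirrored so the
patient faces the right-hand side of the image. Radiograph facing is an
acquisition accident, so angle signs must not depend on it; mirroring a view
and re-standardizing provably leaves every SIRM value unchanged.

SIRM is kept **signed**, with

- `SIRM(F/N) = theta_N − theta_F`
- `SIRM(N/E) = theta_E − theta_N`
- `SIRM(F/E) = theta_E − theta_F`

so the additivity `F/E = F/N + N/E` holds exactly for every segment, mirroring
the additive structure visible in published population tables (e.g. C4/5:
7.05° + 5.76° ≈ 12.81° ≈ the printed F/E mean). Published tables report SIRM
as positive magnitudes without stating a sign convention; keeping the signed
convention was a deliberate design choice because taking magnitudes destroys
additivity. Angles are wrapped into (−180°, 180°], with ties at the branch
cut mapped deterministically to +180°, and are computed with the two-argument
arctangent on millimetre-scaled coordinates so that the code stays correct if
pixel spacing ever becomes anisotropic.

## The synthetic spine generator

The simulator is the package's study population. Rigid rectangular vertebral
bodies (defaults: 16 mm wide, 13 mm tall, 5 mm inter-body gap — plausible
adult cervical sizes, configurable, with no provenance claim) are stacked
caudal-to-cranial as a kinematic chain; C2 is modelled by its inferior edge
only. The neutral view gives every segment a baseline lordosis of 2°; the
flexion and extension views are derived by subtracting the per-segment
flexion–neutral rotation `fn` and adding the neutral–extension rotation `ne`
respectively, which makes the three-view set internally consistent by
construction. Rotations are applied about the inter-body gap midpoint; since
only angles are measured, any rotation centre consistent with rigid vertebrae
yields the same SIRM.

Per-case rotations are drawn from per-segment normal distributions whose
means and SDs default to the published reference-standard population values
for the five segments (`sirmPopulationParams()`), e.g. `fn` at C4/5 ~
N(7.05, 3.69²) degrees. `fe` is set to `fn + ne` exactly.

**Annotation noise.** The only published calibration target for annotation
error is the percentage of inter-observer landmark distances within 1–3 mm
(97–98% within 2 mm). The noise model is isotropic Gaussian per landmark and
per axis; under that assumption 2-D displacement magnitudes are Rayleigh, and
`sigma = 0.74 mm` puts 97.4% of displacements within 2 mm. Because the
distance between *two* noisy annotators has per-axis SD `sigma * sqrt(2)`,
the multi-rater simulator draws each rater at `sigma / sqrt(2)`, so that
rater-to-rater distances — the quantity the published table actually reports —
hit the 97–98% figure. The Gaussian/Rayleigh form is an assumption: the
published data constrain only three threshold percentages, and real annotator
errors are likely correlated between corners of the same vertebra, which this
model ignores. Consequently the simulator's 1-mm percentage (~60%) is lower
than the published ~84%, and uncorrelated corner noise propagates into larger
angle noise than real annotators produce; passing tests demonstrate internal
consistency of the pipeline, not clinical equivalence.

**Rendering.** For the detector path each view is rasterized at 128×128 px
(1.25 mm/px, chosen so the full range of sampled motion and pose fits the
frame): filled body quadrilaterals and a schematic C2 wedge at bone intensity
over a vertical soft-tissue gradient, Gaussian blur, additive pixel noise.
Global per-view pose (rotation SD 4°, translation SD 3 mm) emulates
acquisition variability. A rare extreme pose draw that would push landmarks
out of frame is re-drawn (bounded, seed-stable retries; the motion profile is
never resampled).

## The detector at desk scale

The published detector is a full-size high-resolution network trained on
2,796 clinical radiographs with GPU hardware; neither the data nor that
compute is available or required here. The package implements the same
architectural idea at a scale that trains on one CPU in minutes: a stem
reducing 128×128 input to the 32×32 heatmap resolution, then two stages of
two parallel branches (high resolution at stride 4 width 16, low resolution
at stride 8 width 32) with cross-resolution fusion (1×1 conv + nearest
upsampling in one direction, strided 3×3 conv in the other) after every
stage, ending in a linear 1×1 head that regresses 22 heatmap channels.
Training minimizes the mean squared error between predicted and target
heatmaps (unnormalized Gaussians, peak 1, SD 2 heatmap cells — standard
practice at this output stride) with SGD (momentum 0.9, weight decay 5e-4,
one step decay of the learning rate by 0.3 after epoch 22), checkpointing
every epoch and returning the weights with minimum validation loss.

Two further choices address the dominant failure modes observed while fixing
the desk configuration. Corners of adjacent vertebral bodies are locally
near-identical, so two normalized coordinate channels are appended to the
input (`coordChannels = TRUE`), giving the trunk global positional context
for telling levels apart. And since heatmap argmax quantizes predictions to
the 4 px stride grid, decoding applies the classical quarter-offset
refinement by default (`subPixel = TRUE`): the peak is shifted a quarter cell
toward the larger neighbour on each axis. Plain argmax decoding remains one
flag away; with it, essentially all residual errors at desk scale sit in the
one-cell band (4–6 px) that the refinement recovers.

Numerical choices that mattered in practice:

- the 22-channel head is initialized near zero so the first predictions sit
  at the background level; with a conventionally-scaled random head the
  initial error signal is orders of magnitude above the target scale and the
  first SGD steps kill the rectifier trunk;
- rectifiers are leaky (slope 0.01) so collapsed units remain recoverable;
- inputs are standardized per image (zero mean, unit variance);
- the default learning rate is 1.0: because the loss is a *mean* over
  22×32×32 mostly-zero heatmap cells, its gradients are roughly three orders
  of magnitude smaller than in sum-scaled formulations, and the conventional
  1e-3 setting is equivalent to training a sum-scaled loss at ~1e-6, which
  does not move at this scale. The published base rate (1e-6, on the
  full-size problem) is likewise config-reachable but not trainable at desk
  scale.
- argmax ties break at the first row-major cell, deterministically.

Horizontal-flip augmentation is off by default: flipping a lateral view
swaps anterior/posterior semantics, and with facing standardization upstream
the ambiguity is better avoided entirely. Rotation/scale augmentation is
available but off in the desk defaults — the generator already varies global
pose, and at 200 training images augmentation cost its benefit in held-out
PCK.

Desk-scale problem sizes used throughout tests and the acceptance script:
84 synthetic cases (252 rendered views; ~200 train, ~50 validation),
35 training epochs, batch size 8. The held-out bar is PCK at a 4 px radius
(one heatmap stride). The published clinical figures (94–100% PCK at 2 mm)
are explicitly *not* reproducible at this scale and are not claimed.

## Agreement statistics

`agreementStats()` implements the method-comparison battery for one segment
and motion pair: mean difference (fixed as **model − reference**; the source
tables do not state the direction, and their t-statistic signs are not
consistent with a single convention), sample SD, MAE and RMSE per their
printed formulas, Bland–Altman limits `mean ± 1.96·SD`, a two-sided paired
t-test, Pearson r with Fisher-z CI, and ICC. The ICC form is **ICC(2,1)** —
two-way random effects, absolute agreement, single measures — the standard
choice for method comparison when the named variant is unstated; its CI uses
the usual F-based construction. MAE/RMSE CIs are nonparametric bootstrap
percentile intervals (2,000 resamples, seeded), since the published tables
print CIs without naming a method. Threshold comparisons (PCK, distance
reliability) use the ≤ convention so exact boundary distances count as
within. Degenerate inputs are flagged (`perfect-agreement`, `zero-variance`,
`DegeneratePairs`) rather than returning silent NaNs; p-values are reported
raw, two-sided, with no multiplicity correction.

`summaryRmse(d, s, n)` reconstructs RMSE from a reported mean difference and
SD via `RMSE² = d² + s²(n−1)/n`, which is how the internal consistency of
published agreement tables is checked (seven of fifteen printed rows are
rounding-consistent with their own mean/SD at 2 decimals; the others differ
in the last digit, as expected from rounding the inputs).

## A worked example

```{r, eval = FALSE}
library(cervimotion)

# simulate an observer study
ct <- buildCase(spineTemplate(), sampleMotionProfile(seed = 1), "case01")
truth <- sirmValues(measureCase(ct))
raters <- simulateRaters(ct, nRaters = 3, noiseModel(0.74), seed = 2)

# reference standard and agreement
ref <- referenceStandard(lapply(raters, getView, "neutral"))
reliabilityTable(lapply(raters, function(r) list(case01 = r)))

# end-to-end detector pipeline
dir <- tempfile()
generateDataset(dir, nCases = 84, seed = 11)
model <- trainDetector(loadDetectorSamples(dir, "train"),
                       loadDetectorSamples(dir, "val"))
pred <- predictLandmarks(model, loadDetectorSamples(dir, "val")[[1]]$image,
                         spacing = 1.25)
```

## Known limitations

- The simulator's vertebrae are rigid rectangles without osteophytes,
  fusion, or out-of-plane rotation; the renderer is schematic, not
  photorealistic. Detector performance on these renders says nothing about
  clinical radiographs.
- Landmark noise is isotropic, uncorrelated and Gaussian; real annotator
  error is none of these. Only the 2-mm inter-observer percentage is
  calibrated.
- The desk detector's accuracy bar is a pixel-radius PCK on synthetic
  renders; clinical PCK/MAE levels require the original data and compute.
- Translational intervertebral motion, disc height and centre-of-rotation
  metrics are out of scope.
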
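# cervimotion

Automated measurement of cervical **sagittal intervertebral rotational
motion (SIRM)** from flexion–neutral–extension lateral radiographs, with a
synthetic-spine simulator, a CPU-trainable heatmap-regression landmark
detector, and the complete observer-agreement evaluation battery.

## What it measures

Each motion segment C2/3–C6/7 is represented by a vertebral *midplane*: the
line through the midpoint of the anterior body corners and the midpoint of
the posterior corners (for C2, the line through its two inferior corners
B3–B4). With 22 landmarks per view (4 corners × C3–C7 + 2 for C2), the
segmental angle on a view is

    theta(Cn/Cn+1) = wrap(angle(midplane_Cn) − angle(midplane_Cn+1))

and SIRM for a motion pair is the difference of segmental angles across
views, signed so that additivity holds exactly:

    SIRM(F/N) = theta_N − theta_F
    SIRM(N/E) = theta_E − theta_N
    SIRM(F/E) = theta_E − theta_F = SIRM(F/N) + SIRM(N/E)

Landmarks come either from annotation files (CSV/JSON) or from the bundled
detector: a compact two-branch multi-resolution convolutional network that
regresses 22 Gaussian heatmaps (MSE loss, argmax decoding, affine mapping
back to the original frame).

Agreement between measurement sources is quantified exactly as in standard
method-comparison practice: landmark distance reliability (% within 1–3 mm),
PCK/MPCK, ICC(2,1), Pearson r, MAE, RMSE (with bootstrap CIs), Bland–Altman
limits of agreement, and paired rater-vs-model MAE t-tests.

## Worked example

```r
library(cervimotion)

# a synthetic case with known ground truth
profile <- sampleMotionProfile(seed = 1)
ct <- buildCase(spineTemplate(), profile, "case01")
m  <- measureCase(ct)
round(sirmValues(m), 2)
#>        F/E   F/N  N/E
#> C2/3  3.94  2.50 1.44
#> C3/4 13.30  6.88 6.42
#> C4/5 12.56  3.97 8.60
#> C5/6 20.13 14.01 6.12
#> C6/7 11.23  9.11 2.12
```

The three columns are the signed per-segment rotations (degrees) for the
flexion–extension, flexion–neutral and neutral–extension pairs; with zero
annotation noise they reproduce the generator's sampled profile exactly
(`F/N = profile$fn`, `N/E = profile$ne`), and `F/E` is their exact sum.

A full observer study and detector pipeline:

```r
raters <- simulateRaters(ct, nRaters = 3, noiseModel(0.74), seed = 2)

dir <- tempfile()
generateDataset(dir, nCases = 84, seed = 11)        # 252 rendered views
model <- trainDetector(loadDetectorSamples(dir, "train"),
                       loadDetectorSamples(dir, "val"))   # ~6 min on 1 CPU
val <- loadDetectorSamples(dir, "val")
pred <- predictLandmarks(model, val[[1]]$image, spacing = 1.25)
```

There is also a command-line entry point
(`inst/scripts/sirm-tool.R`) with subcommands `simulate`, `measure`,
`evaluate`, `train-detector` and `detect`.

## Scope

Clinical radiograph handling (DICOM/PACS), annotation tooling, and
full-scale GPU training are out of scope. The synthetic renders are
schematic; detector figures on them are internal-consistency checks, not
clinical performance claims. See the methods vignette
(`vignettes/measuring-cervical-sirm.Rmd`) for the model, its assumptions and
design decisions.
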
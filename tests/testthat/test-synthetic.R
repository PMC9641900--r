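test_that("motion profile sampling follows the stated distributions", {
  params <- sirmPopulationParams()
  # degenerate SDs: the draw equals the mean, and fe is the exact sum
  p0 <- sampleMotionProfile(transform(params, fn_sd = 0, ne_sd = 0), seed = 1)
  expect_equal(unname(p0$fn), params$fn_mean)
  expect_equal(unname(p0$ne), params$ne_mean)
  expect_equal(unname(p0$fe["C4/5"]), 7.05 + 5.76)

  expect_identical(sampleMotionProfile(seed = 5), sampleMotionProfile(seed = 5))

  z <- sampleMotionProfile(transform(params, fn_mean = 0, fn_sd = 0,
                                     ne_mean = 0, ne_sd = 0), seed = 2)
  expect_equal(max(abs(c(z$fn, z$ne, z$fe))), 0)

  expect_error(sampleMotionProfile(transform(params, fn_sd = -1), seed = 1),
               class = "NegativeSD")
})

test_that("perturbation displacement magnitudes follow the Rayleigh law", {
  ann <- buildViewLandmarks(spineTemplate(), zeroMotionProfile(), "neutral")
  expect_identical(perturbAnnotations(ann, noiseModel(0)), ann)

  # sigma 0.74 mm: P(|d| < 2 mm) = 1 - exp(-2 / 0.74^2) = 0.9741
  set.seed(31)
  disp <- replicate(500, {
    pert <- perturbAnnotations(ann, noiseModel(0.74))
    sqrt(rowSums((viewPoints(pert) - viewPoints(ann))^2)) * pixelSpacing(ann)
  })
  expect_equal(mean(disp < 2), 0.975, tolerance = 0.006)

  # two independent perturbations differ by Rayleigh with per-axis SD
  # sigma * sqrt(2): P(< 2 mm) = 1 - exp(-4 / (2 * 2 * 0.74^2)) = 0.839
  set.seed(32)
  dd <- replicate(500, {
    a <- perturbAnnotations(ann, noiseModel(0.74))
    b <- perturbAnnotations(ann, noiseModel(0.74))
    sqrt(rowSums((viewPoints(a) - viewPoints(b))^2)) * pixelSpacing(ann)
  })
  expect_equal(mean(dd < 2), 1 - exp(-4 / (4 * 0.74^2)), tolerance = 0.012)
})

test_that("simulated raters reproduce the inter-observer 2-mm percentage", {
  ct <- buildCase(spineTemplate(), sampleMotionProfile(seed = 8))
  raters <- simulateRaters(ct, nRaters = 3, noise = noiseModel(0.74), seed = 4)
  expect_equal(length(raters), 3L)
  expect_equal(raters[[2]]@neutral@annotator, "R2")
  # pooled pairwise distances over many replicates: within 2 mm in [95, 99]%
  dists <- c()
  for (s in 1:30) {
    rr <- simulateRaters(ct, 3, noiseModel(0.74), seed = 100 + s)
    for (i in 1:2) for (j in (i + 1):3) for (v in c("flexion", "neutral", "extension")) {
      d <- sqrt(rowSums((viewPoints(getView(rr[[i]], v)) -
                           viewPoints(getView(rr[[j]], v)))^2)) * 0.143
      dists <- c(dists, d)
    }
  }
  expect_gte(length(dists), 1000)
  pct <- 100 * mean(dists <= 2)
  expect_gte(pct, 95); expect_lte(pct, 99)
})

test_that("rendering is deterministic and leaves ground truth untouched", {
  ann <- buildViewLandmarks(spineTemplate(), zeroMotionProfile(), "neutral",
                            spacing = 1.25, imageSize = c(128L, 128L))
  r1 <- renderView(ann, renderConfig(seed = 5))
  r2 <- renderView(ann, renderConfig(seed = 5))
  expect_identical(r1$image, r2$image)
  expect_identical(r1$annotation, ann)
  expect_true(all(r1$image >= 0 & r1$image <= 1))

  # body centroid is brighter than a far background pixel (pre-noise)
  quiet <- renderView(ann, renderConfig(noiseSd = 0))$image
  ctr <- round(colMeans(viewPoints(ann)[paste0(5, "-G", 1:4), ]))
  expect_gt(quiet[ctr[2] + 1, ctr[1] + 1], quiet[3, 3])
})

test_that("generateDataset writes a disjoint, seed-stable, complete dataset", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generateDataset(d1, nCases = 10, seed = 7, render = FALSE)
  m2 <- generateDataset(d2, nCases = 10, seed = 7, render = FALSE)
  expect_equal(vapply(m1$cases, `[[`, "", "split"),
               vapply(m2$cases, `[[`, "", "split"))
  expect_identical(readLines(file.path(d1, "landmarks.csv")),
                   readLines(file.path(d2, "landmarks.csv")))
  splits <- vapply(m1$cases, `[[`, "", "split")
  expect_equal(sum(splits == "train"), 8L)
  expect_equal(sum(splits == "val"), 2L)
  ids <- vapply(m1$cases, `[[`, "", "case_id")
  expect_equal(anyDuplicated(ids), 0L)

  # ground truth in the manifest equals the measured SIRM (no noise)
  meas <- motionTable(lapply(readLandmarkCSV(file.path(d1, "landmarks.csv")),
                             measureCase))
  gt <- manifestSirmTable(readManifest(d1))
  key <- paste(gt$case_id, gt$segment)
  meas <- meas[match(key, paste(meas$case_id, meas$segment)), ]
  expect_equal(meas$sirm_FE_deg, gt$sirm_FE_deg, tolerance = 1e-9)
  expect_equal(meas$sirm_FN_deg, gt$sirm_FN_deg, tolerance = 1e-9)

  expect_error(generateDataset(withr::local_tempdir(), 4,
                               split = c(train = 0.5, val = 0.2), seed = 1),
               class = "InvalidSplit")

  # n = 0: valid empty dataset
  d0 <- withr::local_tempdir()
  m0 <- generateDataset(d0, nCases = 0, seed = 1, render = FALSE)
  expect_equal(m0$n_cases, 0L)
  expect_true(file.exists(file.path(d0, "manifest.json")))
})

test_that("rendered datasets round-trip through loadDetectorSamples", {
  d <- withr::local_tempdir()
  generateDataset(d, nCases = 2, seed = 3)
  s <- loadDetectorSamples(d)
  expect_equal(length(s), 6L)
  expect_equal(dim(s[[1]]$image), c(128L, 128L))
  expect_equal(nrow(s[[1]]$points), 22L)
  tr <- loadDetectorSamples(d, "train")
  vl <- loadDetectorSamples(d, "val")
  expect_equal(length(tr) + length(vl), 6L)
})

test_that("noisy measurement error against ground truth is in a sane band", {
  # three simulated raters; the reference standard's SIRM error against
  # ground truth lands in the same order as clinical reporting (0.5-3 deg)
  errs <- c()
  for (seed in 1:40) {
    ct <- buildCase(spineTemplate(), sampleMotionProfile(seed = 400 + seed),
                    caseId = sprintf("c%02d", seed))
    truth <- sirmValues(measureCase(ct))
    raters <- simulateRaters(ct, 3, noiseModel(0.74), seed = 700 + seed)
    refViews <- lapply(c("flexion", "neutral", "extension"), function(v)
      referenceStandard(lapply(raters, getView, v)))
    ref <- caseTriple(ct@caseId, refViews[[1]], refViews[[2]], refViews[[3]])
    errs <- c(errs, abs(sirmValues(measureCase(ref)) - truth))
  }
  mae <- mean(errs)
  expect_gte(mae, 0.5); expect_lte(mae, 3.0)
})
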
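# from-scratch ICC(2,1) oracle via explicit two-way ANOVA sums of squares,
# kept independent of the package's mean-squares implementation
iccOracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(y = as.vector(mat),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ subj + rater, data = long)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

test_that("reference standard averages coordinates and values", {
  a <- buildViewLandmarks(spineTemplate(), zeroMotionProfile(), "neutral")
  expect_equal(viewPoints(referenceStandard(list(a, a, a))), viewPoints(a))

  m1 <- matrix(0, 2, 2, dimnames = list(c("p", "q"), NULL))
  m2 <- matrix(2, 2, 2, dimnames = list(c("p", "q"), NULL))
  expect_equal(referenceStandard(list(m1, m2)),
               matrix(1, 2, 2, dimnames = list(c("p", "q"), NULL)))
  m3 <- matrix(0, 2, 2, dimnames = list(c("p", "z"), NULL))
  expect_error(referenceStandard(list(m1, m3)), class = "MismatchedLandmarks")
  expect_equal(referenceStandard(list(c(1, 2), c(3, 4))), c(2, 3))
})

test_that("distance reliability counts boundary distances as within", {
  a <- buildViewLandmarks(spineTemplate(), zeroMotionProfile(), "neutral")
  expect_equal(unname(distanceReliability(a, a)), c(100, 100, 100))

  # one of 22 landmarks displaced by exactly 1.5 mm
  pts <- viewPoints(a)
  pts["4-G2", 1] <- pts["4-G2", 1] + 1.5 / pixelSpacing(a)
  b <- methods::initialize(a, points = pts)
  rel <- distanceReliability(a, b)
  expect_equal(unname(rel["1mm"]), 100 * 21 / 22, tolerance = 1e-9)
  expect_equal(unname(rel["2mm"]), 100)

  # displacement exactly at the threshold counts as within
  # (power-of-two spacing keeps the boundary exact in floating point)
  a2 <- methods::initialize(a, pixelSpacing = 0.5)
  pts2 <- viewPoints(a2)
  pts2["4-G2", 1] <- pts2["4-G2", 1] + 2 / pixelSpacing(a2)
  c2 <- methods::initialize(a2, points = pts2)
  expect_equal(unname(distanceReliability(a2, c2)["2mm"]), 100)

  other <- methods::initialize(b, pixelSpacing = 0.5)
  expect_error(distanceReliability(a, other), class = "SpacingMismatch")
})

test_that("PCK and MPCK follow their definitions", {
  a <- buildViewLandmarks(spineTemplate(), zeroMotionProfile(), "neutral")
  expect_equal(pck(a, a, 0.5), 100)
  expect_equal(unname(mpck(a, a, 1)), rep(100, 6))

  # one displaced landmark: 3 mm off -> outside 2 mm, inside (<=) 3 mm
  # (spacing 0.5 keeps the px<->mm conversion exact at the boundary)
  a <- methods::initialize(a, pixelSpacing = 0.5)
  pts <- viewPoints(a)
  pts["2-B3", 2] <- pts["2-B3", 2] + 3 / pixelSpacing(a)
  b <- methods::initialize(a, points = pts)
  byLm <- pckByLandmark(b, a, 2)
  expect_equal(unname(byLm["2-B3"]), 0)
  expect_equal(unname(byLm["2-B4"]), 100)
  expect_equal(unname(pckByLandmark(b, a, 3)["2-B3"]), 100)
  # MC2 averages exactly the two C2 landmark PCKs
  expect_equal(unname(mpck(b, a, 2)["MC2"]), 50)
  expect_equal(unname(mpck(b, a, 2)[paste0("MC", 3:7)]), rep(100, 5))

  # monotone in the radius
  set.seed(13)
  noisy <- perturbAnnotations(a, noiseModel(1.2))
  vals <- vapply(c(0.5, 1, 2, 3, 5), function(r) pck(noisy, a, r), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("agreement statistics match hand-evaluated formulas", {
  st <- agreementStats(c(2, 2, 5), c(1, 2, 3), nBoot = 200)
  expect_equal(st$mae, 1)
  expect_equal(st$rmse, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(st$rmse, 1.2910, tolerance = 1e-4)
  expect_equal(st$mean_diff, 1)
  expect_true(st$mae <= st$rmse)

  # LoA: differences with mean 0.5, SD 1 -> [-1.46, 2.46]
  ref <- c(0, 0, 0)
  model <- c(-0.5, 0.5, 1.5)   # diffs mean 0.5, sd 1
  st2 <- agreementStats(model, ref, nBoot = 200)
  expect_equal(st2$loa_low, 0.5 - 1.96, tolerance = 1e-12)
  expect_equal(st2$loa_high, 0.5 + 1.96, tolerance = 1e-12)
  expect_equal(st2$loa_high - st2$loa_low, 2 * 1.96 * st2$sd_diff)

  # perfect agreement flag
  x <- c(1, 4, 2, 8)
  stp <- agreementStats(x, x, nBoot = 100)
  expect_equal(stp$flag, "perfect-agreement")
  expect_equal(stp$mae, 0); expect_equal(stp$rmse, 0)
  expect_equal(stp$icc, 1); expect_equal(stp$t_stat, 0)
  expect_equal(stp$p_value, 1)

  # zero variance flagged rather than silent NaN
  stz <- agreementStats(rep(2, 5), rep(1, 5), nBoot = 100)
  expect_equal(stz$flag, "zero-variance")
  expect_true(is.na(stz$icc))
})

test_that("ICC(2,1) agrees with a variance-components oracle", {
  set.seed(20)
  for (i in 1:20) {
    subj <- rnorm(10, sd = runif(1, 0.5, 3))
    mat <- cbind(subj + rnorm(10, sd = 0.7) + rnorm(1, sd = 0.3),
                 subj + rnorm(10, sd = 0.7) + rnorm(1, sd = 0.3))
    got <- cervimotion:::iccAbsoluteSingle(mat)$icc
    expect_equal(got, iccOracle(mat), tolerance = 1e-9)
  }
})

test_that("ICC and r behave sensibly on correlated data", {
  set.seed(77)
  truth <- rnorm(100, sd = 4)
  a <- truth + rnorm(100)
  b <- truth + rnorm(100)
  st <- agreementStats(a, b, nBoot = 200)
  expect_gt(st$icc, 0.85); expect_lt(st$icc, 1)
  expect_gt(st$r, 0.85)
  expect_true(st$icc_lo < st$icc & st$icc < st$icc_hi)
  expect_true(st$r_lo < st$r & st$r < st$r_hi)
  expect_true(st$rmse_lo <= st$rmse & st$rmse <= st$rmse_hi)
  # bootstrap CIs are seed-stable
  st2 <- agreementStats(a, b, nBoot = 200)
  expect_equal(st$mae_lo, st2$mae_lo)
})

test_that("limits of agreement cover ~95% of normal differences", {
  set.seed(55)
  ref <- rnorm(10000, 10, 3)
  model <- ref + rnorm(10000, 0.4, 1.3)
  st <- agreementStats(model, ref, nBoot = 50)
  d <- model - ref
  cover <- 100 * mean(d >= st$loa_low & d <= st$loa_high)
  expect_gte(cover, 94); expect_lte(cover, 96)
})

test_that("paired MAE comparison reproduces its defining layout", {
  # model identical to rater 1: degenerate pairs, p reported as 1
  r1 <- c(1, 2, 3, 4); r2 <- c(2, 3, 4, 5); r3 <- c(0, 1, 2, 3)
  cmp <- pairedMaeComparison(list(r1, r2, r3), r1)
  expect_equal(cmp$flag[1], "DegeneratePairs")
  expect_equal(cmp$p_value[1], 1)
  expect_equal(cmp$mae_rater[1], cmp$mae_model[1])

  # paired error differences (1, -1, 2, -2): t = 0, p = 1
  zero <- rep(0, 4)
  cmp2 <- pairedMaeComparison(list(c(2, 0, 3, 0), zero, zero),
                              c(1, 1, 1, 2))
  expect_equal(cmp2$t_stat[1], 0, tolerance = 1e-12)
  expect_equal(cmp2$p_value[1], 1, tolerance = 1e-12)

  # power: model uniformly closer to baseline at n = 100, effect >= 0.5 SD
  set.seed(66)
  base2 <- rnorm(100)
  rr <- base2 + rnorm(100, 0, 2)
  mm <- base2 + rnorm(100, 0, 0.8)
  cmp3 <- pairedMaeComparison(list(rr, base2, base2), mm)
  expect_lt(cmp3$p_value[1], 0.05)
  expect_gt(cmp3$mae_rater[1], cmp3$mae_model[1])

  expect_error(pairedMaeComparison(list(r1, r2, r3), c(1, 2)),
               class = "LengthMismatch")
})

test_that("summary RMSE identity holds exactly and on published rows", {
  expect_equal(summaryRmse(-0.52, 1.57, 100), 1.64, tolerance = 5e-3)
  expect_equal(summaryRmse(0, 2.5, 10), 2.5 * sqrt(9 / 10), tolerance = 1e-12)
  expect_equal(summaryRmse(3, 0, 10), 3)
  expect_error(summaryRmse(1, 1, 1), class = "InvalidN")

  # raw-diff RMSE equals the summary reconstruction to 1e-12
  set.seed(3)
  for (i in 1:10) {
    d <- rnorm(50, runif(1, -2, 2), runif(1, 0.1, 3))
    expect_equal(sqrt(mean(d^2)), summaryRmse(mean(d), sd(d), length(d)),
                 tolerance = 1e-12)
  }
})

test_that("reliability table pools landmarks across cases and rater pairs", {
  ct <- buildCase(spineTemplate(), sampleMotionProfile(seed = 21), "c1")
  raters <- simulateRaters(ct, 3, noiseModel(0.74), seed = 9)
  rc <- lapply(raters, function(r) stats::setNames(list(r), "c1"))
  tab <- reliabilityTable(rc)
  expect_equal(nrow(tab), 9L)   # 3 pairs x 3 views
  expect_true(all(tab$within_1mm <= tab$within_2mm))
  expect_true(all(tab$within_2mm <= tab$within_3mm))
  expect_true(all(tab$within_3mm <= 100))
})
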
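test_that("midplane passes through edge midpoints with the right angle", {
  # axis-aligned rectangle: line (0,2)-(10,2), angle 0
  rect <- rbind(G1 = c(0, 4), G2 = c(10, 4), G3 = c(0, 0), G4 = c(10, 0))
  ml <- midplane(rect)
  expect_equal(ml@anterior, c(0, 2))
  expect_equal(ml@posterior, c(10, 2))
  expect_equal(ml@angle, 0)

  # rotation oracle: rotating the corners by +10 deg about the centroid
  # rotates the midplane by exactly +10 deg
  rot <- rotatePts(rect, 10, centre = colMeans(rect))
  expect_equal(midplane(rot)@angle, 10, tolerance = 1e-12)
  for (deg in c(-137.25, -45, 33.3, 170)) {
    expect_equal(midplane(rotatePts(rect, deg, colMeans(rect)))@angle,
                 wrapOracle(deg), tolerance = 1e-9)
  }
  expect_error(midplane(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))),
               class = "DegenerateVertebra")
})

test_that("C2 line is oriented anterior to posterior", {
  expect_equal(c2Line(c(0, 0), c(12, 0))@angle, 0)
  expect_equal(c2Line(c(0, 0), c(12, 2))@angle, atan2(2, 12) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(c2Line(c(0, 0), c(12, 2))@angle, 9.462322, tolerance = 1e-6)
  expect_error(c2Line(c(3, 3), c(3, 3)), class = "DegenerateVertebra")
})

test_that("segmental angle is the wrapped difference of line angles", {
  mk <- function(angle) {
    d <- c(cos(angle * pi / 180), sin(angle * pi / 180))
    methods::new("MidplaneLine", anterior = c(0, 0), posterior = d,
                 angle = angle)
  }
  expect_equal(segmentalAngle(mk(25), mk(25)), 0)
  expect_equal(segmentalAngle(mk(10), mk(4)), 6)
  expect_equal(segmentalAngle(mk(-179), mk(179)), 2)
  # brute-force wrap oracle over random angle pairs
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, -180, 180); b <- runif(1, -180, 180)
    expect_equal(segmentalAngle(mk(a), mk(b)), wrapOracle(a - b),
                 tolerance = 1e-9)
  }
})

test_that("wrapAngle180 maps into (-180, 180] with ties at +180", {
  expect_equal(wrapAngle180(c(-180, 180, 540, -540, 0)),
               c(180, 180, 180, 180, 0))
  set.seed(7)
  x <- runif(200, -1000, 1000)
  w <- wrapAngle180(x)
  expect_true(all(w > -180 & w <= 180))
  expect_equal(sin(w * pi / 180), sin(x * pi / 180), tolerance = 1e-9)
  expect_equal(cos(w * pi / 180), cos(x * pi / 180), tolerance = 1e-9)
})

test_that("measureCase reproduces prescribed segmental angles and SIRM", {
  # no motion: all 15 SIRM values are zero
  same <- caseWithThetas(rep(2, 5), rep(2, 5), rep(2, 5))
  expect_equal(max(abs(sirmValues(measureCase(same)))), 0, tolerance = 1e-9)

  # prescribed thetas at C4/5: F=-5, N=2, E=6 -> SIRM FE=11, FN=7, NE=4
  thF <- c(1, 1, -5, 1, 1); thN <- c(2, 2, 2, 2, 2); thE <- c(3, 3, 6, 3, 3)
  m <- measureCase(caseWithThetas(thF, thN, thE))
  expect_equal(unname(thetaValues(m)[, "F"]), thF, tolerance = 1e-9)
  expect_equal(unname(thetaValues(m)[, "N"]), thN, tolerance = 1e-9)
  expect_equal(unname(thetaValues(m)[, "E"]), thE, tolerance = 1e-9)
  s <- sirmValues(m)
  expect_equal(unname(s["C4/5", ]), c(11, 7, 4), tolerance = 1e-9)
  expect_equal(unname(s["C2/3", ]), c(2, 1, 1), tolerance = 1e-9)
})

test_that("zero-noise generator round trip recovers the profile exactly", {
  for (seed in 1:5) {
    p <- sampleMotionProfile(seed = seed)
    s <- sirmValues(measureCase(buildCase(spineTemplate(), p)))
    expect_equal(unname(s[, "F/N"]), unname(p$fn), tolerance = 1e-9)
    expect_equal(unname(s[, "N/E"]), unname(p$ne), tolerance = 1e-9)
    expect_equal(unname(s[, "F/E"]), unname(p$fe), tolerance = 1e-9)
    expect_equal(s[, "F/E"], s[, "F/N"] + s[, "N/E"])  # exact additivity
  }
})

test_that("SIRM is invariant to rigid transforms, scaling and mirroring", {
  ct <- randomCase(9)
  base <- sirmValues(measureCase(ct))
  set.seed(99)
  transformed <- lapply(c("flexion", "neutral", "extension"), function(v) {
    ann <- getView(ct, v)
    deg <- runif(1, -60, 60); shift <- runif(2, -50, 50)
    pts <- rotatePts(viewPoints(ann), deg, centre = c(100, 100))
    pts <- sweep(pts, 2, -shift)
    methods::initialize(ann, points = pts)
  })
  rigid <- caseTriple("rigid", transformed[[1]], transformed[[2]],
                      transformed[[3]])
  expect_lt(max(abs(sirmValues(measureCase(rigid)) - base)), 1e-9)

  # uniform scaling (spacing change leaves angles untouched as well)
  scaled <- lapply(c("flexion", "neutral", "extension"), function(v) {
    ann <- getView(ct, v)
    methods::initialize(ann, points = viewPoints(ann) * 3.7)
  })
  sc <- caseTriple("scaled", scaled[[1]], scaled[[2]], scaled[[3]])
  expect_lt(max(abs(sirmValues(measureCase(sc)) - base)), 1e-9)

  # x-mirroring each view is undone by facing standardization
  ct2 <- buildCase(spineTemplate(), sampleMotionProfile(seed = 12),
                   spacing = 1.25, imageSize = c(128L, 128L))
  base2 <- sirmValues(measureCase(ct2))
  mirrored <- lapply(c("flexion", "neutral", "extension"), function(v)
    cervimotion:::mirrorView(getView(ct2, v)))
  mc <- caseTriple("mir", mirrored[[1]], mirrored[[2]], mirrored[[3]])
  expect_lt(max(abs(sirmValues(measureCase(mc)) - base2)), 1e-9)
})

test_that("motionTable flattens measurements with exact additivity", {
  tab <- motionTable(lapply(1:3, function(i) measureCase(randomCase(i))))
  expect_equal(nrow(tab), 15L)
  expect_equal(tab$sirm_FE_deg, tab$sirm_FN_deg + tab$sirm_NE_deg)
  expect_setequal(unique(tab$segment), segmentLabels())
})

test_that("degenerate vertebrae are reported with the segment", {
  ct <- randomCase(4)
  ann <- getView(ct, "neutral")
  pts <- viewPoints(ann)
  pts[paste0(5, "-G", 1:4), ] <- rep(c(40, 60), each = 4)
  bad <- caseTriple("bad", getView(ct, "flexion"),
                    methods::initialize(ann, points = pts),
                    getView(ct, "extension"))
  expect_error(measureCase(bad), class = "DegenerateVertebra")
  expect_error(measureCase(bad), regexp = "C5")
})
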
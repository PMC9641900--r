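# fixtures built in code: small cases, rotation oracle, wrap oracle

# rotate 2-D points about a centre by deg (closed form, y-up convention)
rotatePts <- function(pts, deg, centre = c(0, 0)) {
  th <- deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  sweep(t(R %*% t(sweep(pts, 2, centre))), 2, -centre)
}

# independent wrap oracle: brute-force search over k
wrapOracle <- function(deg) {
  k <- -3:3
  cand <- deg + 360 * k
  ok <- cand[cand > -180 & cand <= 180]
  ok[1]
}

# a case with prescribed per-view segmental angles via the generator:
# fn = thetaN - thetaF, ne = thetaE - thetaN per segment (baseline = thetaN)
caseWithThetas <- function(thetaF, thetaN, thetaE, caseId = "fix",
                           spacing = 0.143) {
  tpl <- spineTemplate(baselineLordosisDeg = 0)
  # realize arbitrary per-segment angles: flexion-view kinematics give
  # theta = baseline - fn = -fn, so set fn = -theta and relabel the view
  mk <- function(theta, view) {
    pr <- structure(list(fn = -theta, ne = numeric(5), fe = numeric(5)),
                    class = "MotionProfile")
    ann <- buildViewLandmarks(tpl, pr, "flexion", spacing = spacing)
    methods::initialize(ann, view = view)
  }
  caseTriple(caseId, mk(thetaF, "flexion"), mk(thetaN, "neutral"),
             mk(thetaE, "extension"))
}

randomCase <- function(seed, caseId = paste0("rc", seed)) {
  buildCase(spineTemplate(), sampleMotionProfile(seed = seed), caseId)
}
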
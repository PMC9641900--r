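#' Spine template for the synthetic generator
#'
#' Geometric template of the cervical spine used by the articulated landmark
#' simulator: rigid rectangular vertebral bodies C3-C7 stacked caudal to
#' cranial, C2 represented by its inferior edge only, and a fixed
#' inter-vertebral gap. Dimensions are plausible adult cervical sizes and are
#' fully configurable; they carry no provenance claim.
#'
#' @param bodyWidthMm anterior-posterior body width in mm (default 16)
#' @param bodyHeightMm body height in mm (default 13)
#' @param gapMm inter-vertebral (disc) gap in mm (default 5)
#' @param baselineLordosisDeg neutral-posture segmental extension angle in
#'   degrees applied to every segment (default 2)
#' @return a list of class \code{"SpineTemplate"}
#' @export
spineTemplate <- function(bodyWidthMm = 16, bodyHeightMm = 13, gapMm = 5,
                          baselineLordosisDeg = 2) {
  stopifnot(bodyWidthMm > 0, bodyHeightMm > 0, gapMm > 0)
  structure(list(bodyWidthMm = bodyWidthMm, bodyHeightMm = bodyHeightMm,
                 gapMm = gapMm, baselineLordosisDeg = baselineLordosisDeg),
            class = "SpineTemplate")
}

#' Population SIRM distribution parameters
#'
#' Per-segment means and standard deviations (degrees) of the signed
#' flexion-neutral and neutral-extension rotations used as the default
#' sampling distributions of \code{\link{sampleMotionProfile}}. The values
#' are the reference-standard population statistics for adult cervical SIRM
#' at C2/3-C6/7.
#'
#' @return \code{data.frame} with columns \code{segment}, \code{fn_mean},
#'   \code{fn_sd}, \code{ne_mean}, \code{ne_sd}
#' @export
sirmPopulationParams <- function() {
  data.frame(
    segment = segmentLabels(),
    fn_mean = c(3.87, 6.24, 7.05, 7.50, 7.79),
    fn_sd   = c(2.19, 3.49, 3.69, 4.08, 4.01),
    ne_mean = c(2.87, 4.73, 5.76, 4.43, 2.70),
    ne_sd   = c(1.74, 3.47, 3.84, 2.93, 1.90),
    stringsAsFactors = FALSE)
}

newMotionProfile <- function(fn, ne) {
  stopifnot(length(fn) == 5L, length(ne) == 5L, all(is.finite(c(fn, ne))))
  names(fn) <- names(ne) <- segmentLabels()
  structure(list(fn = fn, ne = ne, fe = fn + ne), class = "MotionProfile")
}

#' Zero-motion profile (all rotations 0)
#'
#' @return a \code{MotionProfile} with fn = ne = fe = 0 for every segment
#' @export
zeroMotionProfile <- function() newMotionProfile(rep(0, 5), rep(0, 5))

#' Sample a per-case motion profile
#'
#' Draws the signed flexion-neutral (fn) and neutral-extension (ne) rotation
#' of each segment independently from per-segment normal distributions and
#' sets the flexion-extension rotation to their exact sum, so the additivity
#' \code{fe = fn + ne} holds by construction.
#'
#' @param params distribution table as returned by
#'   \code{\link{sirmPopulationParams}}
#' @param seed optional RNG seed for reproducibility
#' @return a list of class \code{"MotionProfile"} with per-segment named
#'   numeric vectors \code{fn}, \code{ne}, \code{fe} (degrees)
#' @examples
#' p <- sampleMotionProfile(seed = 7)
#' all.equal(p$fe, p$fn + p$ne)
#' @export
sampleMotionProfile <- function(params = sirmPopulationParams(), seed = NULL) {
  cmAssert(all(params$fn_sd >= 0) && all(params$ne_sd >= 0), "NegativeSD",
           "distribution SDs must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  fn <- stats::rnorm(5, params$fn_mean, params$fn_sd)
  ne <- stats::rnorm(5, params$ne_mean, params$ne_sd)
  newMotionProfile(fn, ne)
}

#' Annotation noise model
#'
#' Isotropic Gaussian per-landmark annotation noise. \code{sigmaMm} is
#' calibrated to the inter-observer landmark distance scale: perturbing a
#' view with \code{sigmaMm} adds independent offsets with SD \code{sigmaMm}
#' per axis, so 2-D displacement magnitudes follow a Rayleigh law and 97.4\%
#' fall within 2 mm at the default 0.74 mm. The multi-rater simulator
#' (\code{\link{simulateRaters}}) draws each rater at \code{sigmaMm/sqrt(2)}
#' so that rater-to-rater distances have per-axis SD \code{sigmaMm}.
#'
#' @param sigmaMm per-axis Gaussian SD in mm (>= 0); default 0.74
#' @param seed optional RNG seed
#' @return a list of class \code{"NoiseModel"}
#' @export
noiseModel <- function(sigmaMm = 0.74, seed = NULL) {
  stopifnot(length(sigmaMm) == 1L, is.finite(sigmaMm), sigmaMm >= 0)
  structure(list(sigmaMm = sigmaMm, seed = seed), class = "NoiseModel")
}

# orientation helpers in the y-up mm frame; phi is the direction angle (deg)
# of the anterior-to-posterior body axis
dirVec <- function(phiDeg) c(cos(phiDeg * pi / 180), sin(phiDeg * pi / 180))
upVec  <- function(phiDeg) c(sin(phiDeg * pi / 180), -cos(phiDeg * pi / 180))

# per-view segmental angles theta (deg) implied by template + profile:
# neutral = baseline lordosis; flexion = baseline - fn; extension = baseline + ne
viewThetas <- function(template, profile, view) {
  base <- rep(template$baselineLordosisDeg, 5)
  switch(view,
         neutral   = base,
         flexion   = base - profile$fn,
         extension = base + profile$ne,
         cmStop("InvalidConfig", sprintf("unknown view '%s'", view)))
}

#' Build one view's landmarks by forward kinematics
#'
#' Realizes the articulated spine: C7 is placed at the global pose, each more
#' cranial vertebra is rotated relative to its caudal neighbour by the view's
#' segmental angle (rotation taken about the inter-body gap midpoint), and the
#' 22 scheme landmarks are emitted in pixel coordinates. The patient faces
#' the right-hand side of the image.
#'
#' @param template a \code{\link{spineTemplate}}
#' @param profile a \code{MotionProfile}
#' @param view "flexion", "neutral" or "extension"
#' @param pose length-3 numeric: global rotation (deg) and translation
#'   (x, y, mm) applied to the whole spine
#' @param spacing pixel spacing mm/px
#' @param imageSize integer (width, height) px, or NA for an unbounded frame
#' @param annotator annotator label recorded in the output
#' @return a \linkS4class{ViewAnnotation}
#' @export
buildViewLandmarks <- function(template, profile, view,
                               pose = c(0, 0, 0), spacing = 0.143,
                               imageSize = c(NA_integer_, NA_integer_),
                               annotator = "truth") {
  stopifnot(inherits(template, "SpineTemplate"), inherits(profile, "MotionProfile"))
  theta <- viewThetas(template, profile, view)   # C2/3 ... C6/7
  w <- template$bodyWidthMm; h <- template$bodyHeightMm; g <- template$gapMm

  # chain caudal -> cranial: C7 at the pose, phi = 180 means facing right
  phi <- numeric(6); names(phi) <- paste0("C", 7:2)
  ctr <- matrix(NA_real_, 6, 2, dimnames = list(paste0("C", 7:2), NULL))
  phi["C7"] <- 180 + pose[1]
  ctr["C7", ] <- c(pose[2], pose[3])
  segs <- rev(segmentLabels())                   # C6/7, C5/6, ... C2/3
  for (i in 1:4) {                               # C6 .. C3 bodies
    ca <- paste0("C", 8 - i); cr <- paste0("C", 7 - i)
    phi[cr] <- phi[ca] + rev(theta)[i]
    gapMid <- ctr[ca, ] + upVec(phi[ca]) * (h / 2 + g / 2)
    ctr[cr, ] <- gapMid + upVec(phi[cr]) * (g / 2 + h / 2)
  }
  phi["C2"] <- phi["C3"] + theta[1]
  gapMid2 <- ctr["C3", ] + upVec(phi["C3"]) * (h / 2 + g / 2)
  infMid2 <- gapMid2 + upVec(phi["C2"]) * (g / 2)

  pts <- matrix(NA_real_, 22, 2, dimnames = list(landmarkIds(), c("x", "y")))
  pts["2-B3", ] <- infMid2 - dirVec(phi["C2"]) * w / 2
  pts["2-B4", ] <- infMid2 + dirVec(phi["C2"]) * w / 2
  for (v in 3:7) {
    cv <- paste0("C", v)
    d <- dirVec(phi[cv]); u <- upVec(phi[cv])
    antMid <- ctr[cv, ] - d * w / 2
    posMid <- ctr[cv, ] + d * w / 2
    pts[paste0(v, "-G1"), ] <- antMid + u * h / 2
    pts[paste0(v, "-G2"), ] <- posMid + u * h / 2
    pts[paste0(v, "-G3"), ] <- antMid - u * h / 2
    pts[paste0(v, "-G4"), ] <- posMid - u * h / 2
  }

  # mm (y-up) -> pixel (y-down) frame
  imageSize <- as.integer(imageSize)
  if (!anyNA(imageSize)) {
    cx <- (imageSize[1] - 1) / 2
    y0 <- 0.88 * (imageSize[2] - 1)
  } else {
    cx <- 60 / spacing
    y0 <- 110 / spacing
  }
  px <- cbind(x = cx + pts[, 1] / spacing, y = y0 - pts[, 2] / spacing)
  rownames(px) <- rownames(pts)
  if (!anyNA(imageSize) &&
      (any(px[, 1] < 0 | px[, 1] > imageSize[1] - 1) ||
       any(px[, 2] < 0 | px[, 2] > imageSize[2] - 1)))
    cmStop("OutOfFrame", "landmarks fall outside the requested image size")
  new("ViewAnnotation", view = view, points = px, pixelSpacing = spacing,
      imageSize = imageSize, facing = "right", annotator = annotator)
}

#' Build a full three-view synthetic case
#'
#' @param template a \code{\link{spineTemplate}}
#' @param profile a \code{MotionProfile}
#' @param caseId case identifier
#' @param poses named list of per-view poses (rotation deg, tx mm, ty mm)
#' @param spacing pixel spacing mm/px
#' @param imageSize integer (width, height) px or NA
#' @param annotator annotator label
#' @return a \linkS4class{CaseTriple} whose measured SIRM equals the profile's
#'   \code{fn}, \code{ne}, \code{fn + ne} exactly (zero noise)
#' @export
buildCase <- function(template, profile, caseId = "synthetic",
                      poses = list(flexion = c(0, 0, 0), neutral = c(0, 0, 0),
                                   extension = c(0, 0, 0)),
                      spacing = 0.143,
                      imageSize = c(NA_integer_, NA_integer_),
                      annotator = "truth") {
  views <- lapply(viewLabels(), function(v)
    buildViewLandmarks(template, profile, v, pose = poses[[v]],
                       spacing = spacing, imageSize = imageSize,
                       annotator = annotator))
  caseTriple(caseId, views[[1]], views[[2]], views[[3]])
}

#' Perturb an annotation with Gaussian landmark noise
#'
#' Adds independent Gaussian offsets (SD \code{noise$sigmaMm} per axis,
#' converted to pixels) to every landmark. When the image size is known,
#' perturbed coordinates are clamped to the frame so the annotation stays
#' valid. Seed-reproducible via \code{noise$seed}.
#'
#' @param ann a \linkS4class{ViewAnnotation}
#' @param noise a \code{\link{noiseModel}}
#' @return a perturbed \code{ViewAnnotation}
#' @export
perturbAnnotations <- function(ann, noise = noiseModel()) {
  stopifnot(is(ann, "ViewAnnotation"), inherits(noise, "NoiseModel"))
  if (noise$sigmaMm == 0) return(ann)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  sigmaPx <- noise$sigmaMm / ann@pixelSpacing
  pts <- ann@points + matrix(stats::rnorm(44, 0, sigmaPx), 22, 2)
  sz <- ann@imageSize
  if (!anyNA(sz)) {
    pts[, 1] <- pmin(pmax(pts[, 1], 0), sz[1] - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), sz[2] - 1)
  }
  initialize(ann, points = pts)
}

#' Simulate multiple annotators of one case
#'
#' Each simulated rater re-annotates every view with independent Gaussian
#' landmark noise of per-axis SD \code{noise$sigmaMm / sqrt(2)}, so that the
#' displacement between any two raters has per-axis SD \code{noise$sigmaMm}
#' and the pairwise within-2-mm percentage matches the inter-observer
#' reliability the noise model is calibrated to.
#'
#' @param case a \linkS4class{CaseTriple} (ground truth)
#' @param nRaters number of raters (default 3)
#' @param noise a \code{\link{noiseModel}}
#' @param seed RNG seed
#' @return list of \code{CaseTriple}s, annotators "R1", "R2", ...
#' @export
simulateRaters <- function(case, nRaters = 3, noise = noiseModel(), seed = 1) {
  stopifnot(is(case, "CaseTriple"), nRaters >= 1)
  set.seed(seed)
  raterSigma <- noise$sigmaMm / sqrt(2)
  lapply(seq_len(nRaters), function(i) {
    views <- lapply(viewLabels(), function(v) {
      ann <- perturbAnnotations(getView(case, v),
                                noiseModel(sigmaMm = raterSigma))
      initialize(ann, annotator = paste0("R", i))
    })
    caseTriple(case@caseId, views[[1]], views[[2]], views[[3]])
  })
}
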
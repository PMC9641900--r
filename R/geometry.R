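#' Wrap an angle into (-180, 180]
#'
#' Ties at the branch cut map to +180 so the wrap is deterministic.
#'
#' @param deg angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrapAngle180 <- function(deg) {
  out <- deg - 360 * floor((deg + 180) / 360)
  out[out == -180] <- 180
  out
}

# convert a view's pixel coordinates to the y-up millimetre frame used by all
# angle computations (x_mm = x_px * s, y_mm = -y_px * s; the constant offset
# of flipping about any horizontal axis does not affect angles)
toMillimetreFrame <- function(ann) {
  pts <- ann@points * ann@pixelSpacing
  pts[, 2] <- -pts[, 2]
  pts
}

lineFromPoints <- function(anterior, posterior, what = "vertebra") {
  d <- posterior - anterior
  if (sqrt(sum(d^2)) <= 1e-9)
    cmStop("DegenerateVertebra",
           sprintf("%s: anterior and posterior points coincide", what))
  new("MidplaneLine", anterior = as.numeric(anterior),
      posterior = as.numeric(posterior),
      angle = wrapAngle180(atan2(d[2], d[1]) * 180 / pi))
}

#' Vertebral midplane from four body corners
#'
#' The midplane of a typical vertebra (C3-C7) is the line through the midpoint
#' of its two anterior corners (G1 anterior-superior, G3 anterior-inferior)
#' and the midpoint of its two posterior corners (G2, G4). This is the
#' geometric-midplanes construction: the resulting line runs along the body's
#' long (anterior-posterior) axis, the appropriate axis for sagittal rotation.
#'
#' @param corners 4 x 2 numeric matrix with rows G1, G2, G3, G4 (mm, y-up)
#' @return a \linkS4class{MidplaneLine}
#' @examples
#' midplane(rbind(c(0, 4), c(10, 4), c(0, 0), c(10, 0)))  # angle 0
#' @export
midplane <- function(corners) {
  stopifnot(is.matrix(corners), nrow(corners) == 4L, ncol(corners) == 2L)
  cmAssert(all(is.finite(corners)), "DegenerateVertebra",
           "corner coordinates must be finite")
  lineFromPoints((corners[1, ] + corners[3, ]) / 2,
                 (corners[2, ] + corners[4, ]) / 2)
}

#' C2 reference line from its two inferior corners
#'
#' C2 contributes only its anterior-inferior (B3) and posterior-inferior (B4)
#' corners; its reference line is the line through them, oriented
#' anterior-to-posterior.
#'
#' @param b3,b4 length-2 coordinates (mm, y-up)
#' @return a \linkS4class{MidplaneLine}
#' @export
c2Line <- function(b3, b4) lineFromPoints(b3, b4, what = "C2")

#' Signed segmental angle between two midplanes
#'
#' \code{theta = wrap(angle(cranial) - angle(caudal))} into (-180, 180].
#' In the facing-standardized (patient faces right), y-up frame a positive
#' theta corresponds to relative extension of the cranial vertebra.
#'
#' @param cranial,caudal \linkS4class{MidplaneLine}s from the same view
#' @return signed angle in degrees
#' @export
segmentalAngle <- function(cranial, caudal) {
  stopifnot(is(cranial, "MidplaneLine"), is(caudal, "MidplaneLine"))
  wrapAngle180(cranial@angle - caudal@angle)
}

# the five segmental angles of one (facing-standardized) view
viewSegmentalAngles <- function(ann) {
  pts <- toMillimetreFrame(ann)
  lines <- vector("list", 6L)           # C2 line + C3..C7 midplanes
  lines[[1]] <- tryCatch(c2Line(pts["2-B3", ], pts["2-B4", ]),
                         DegenerateVertebra = function(e)
                           cmStop("DegenerateVertebra", paste0("C2: ", conditionMessage(e))))
  for (v in 3:7) {
    corners <- pts[paste0(v, "-G", 1:4), ]
    lines[[v - 1L]] <- tryCatch(midplane(corners),
      DegenerateVertebra = function(e)
        cmStop("DegenerateVertebra", sprintf("C%d: %s", v, conditionMessage(e))))
  }
  theta <- vapply(1:5, function(i) segmentalAngle(lines[[i]], lines[[i + 1L]]),
                  numeric(1))
  names(theta) <- segmentLabels()
  theta
}

#' Measure a case: segmental angles and SIRM
#'
#' Computes, for each posture view, the signed segmental angle theta of the
#' five segments C2/3-C6/7 (C2/3 uses the C2 inferior-corner line against the
#' C3 midplane; the other segments use adjacent midplanes), then the sagittal
#' intervertebral rotational motion of each segment for the three motion
#' pairs: \code{SIRM(F/E) = theta_E - theta_F}, \code{SIRM(F/N) = theta_N -
#' theta_F}, \code{SIRM(N/E) = theta_E - theta_N}. Views are
#' facing-standardized first, so the result is invariant to x-mirroring.
#'
#' @param case a \linkS4class{CaseTriple}
#' @return a \linkS4class{MotionMeasurement}
#' @examples
#' ct <- buildCase(spineTemplate(), sampleMotionProfile(seed = 1), "demo")
#' sirmValues(measureCase(ct))
#' @export
measureCase <- function(case) {
  stopifnot(is(case, "CaseTriple"))
  theta <- vapply(viewLabels(), function(v)
    viewSegmentalAngles(standardizeFacing(getView(case, v))), numeric(5))
  colnames(theta) <- c("F", "N", "E")
  sirm <- cbind(
    `F/E` = theta[, "E"] - theta[, "F"],
    `F/N` = theta[, "N"] - theta[, "F"],
    `N/E` = theta[, "E"] - theta[, "N"])
  new("MotionMeasurement", caseId = case@caseId, theta = theta, sirm = sirm)
}

#' Tabulate motion measurements
#'
#' Flattens \linkS4class{MotionMeasurement}s into the standard long table with
#' one row per case and segment.
#'
#' @param measurements a \code{MotionMeasurement} or list of them
#' @return \code{data.frame} with columns \code{case_id}, \code{segment},
#'   \code{theta_F_deg}, \code{theta_N_deg}, \code{theta_E_deg},
#'   \code{sirm_FE_deg}, \code{sirm_FN_deg}, \code{sirm_NE_deg}
#' @export
motionTable <- function(measurements) {
  if (is(measurements, "MotionMeasurement")) measurements <- list(measurements)
  out <- do.call(rbind, lapply(measurements, function(m) {
    data.frame(case_id = m@caseId, segment = segmentLabels(),
               theta_F_deg = m@theta[, "F"], theta_N_deg = m@theta[, "N"],
               theta_E_deg = m@theta[, "E"], sirm_FE_deg = m@sirm[, "F/E"],
               sirm_FN_deg = m@sirm[, "F/N"], sirm_NE_deg = m@sirm[, "N/E"],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
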
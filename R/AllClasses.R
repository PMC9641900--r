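#' ViewAnnotation: one view's 22 landmark coordinates
#'
#' Holds the 22 landmark pixel coordinates of a single flexion, neutral or
#' extension lateral view, together with the pixel spacing in millimetres and
#' optional image metadata. Coordinates follow the raster convention: 0-based
#' pixel indices, origin at the top-left corner, x rightward, y downward.
#' All geometry converts internally to a y-up millimetre frame.
#'
#' @slot view one of \code{"flexion"}, \code{"neutral"}, \code{"extension"}
#' @slot points 22 x 2 numeric matrix (columns \code{x}, \code{y}), row names
#'   are the landmark ids of \code{\link{landmarkScheme}}
#' @slot pixelSpacing scalar pixel spacing in mm (> 0)
#' @slot imageSize integer (width, height) in pixels, or \code{NA} when unknown
#' @slot facing \code{"left"}, \code{"right"} or \code{"unknown"}
#' @slot annotator free-text annotator identifier
#' @exportClass ViewAnnotation
setClass("ViewAnnotation",
  representation(view = "character", points = "matrix",
                 pixelSpacing = "numeric", imageSize = "integer",
                 facing = "character", annotator = "character"),
  prototype(view = "neutral", pixelSpacing = 0.143,
            imageSize = c(NA_integer_, NA_integer_),
            facing = "unknown", annotator = "unspecified"))

setValidity("ViewAnnotation", function(object) {
  msgs <- character()
  if (!(object@view %in% viewLabels()))
    msgs <- c(msgs, sprintf("view must be one of %s",
                            paste(viewLabels(), collapse = ", ")))
  pts <- object@points
  ids <- landmarkIds()
  if (!is.numeric(pts) || ncol(pts) != 2L)
    msgs <- c(msgs, "points must be a numeric matrix with 2 columns")
  else {
    if (!identical(rownames(pts), ids))
      msgs <- c(msgs, "points rows must be the 22 scheme landmarks in channel order")
    if (!all(is.finite(pts)))
      msgs <- c(msgs, "all landmark coordinates must be finite")
    sz <- object@imageSize
    if (all(is.finite(pts)) && length(sz) == 2L && !anyNA(sz)) {
      if (any(pts[, 1] < 0 | pts[, 1] > sz[1] - 1L) ||
          any(pts[, 2] < 0 | pts[, 2] > sz[2] - 1L))
        msgs <- c(msgs, "landmark coordinates fall outside image bounds")
    }
  }
  if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msgs <- c(msgs, "pixelSpacing must be a single positive number")
  if (!(object@facing %in% c("left", "right", "unknown")))
    msgs <- c(msgs, "facing must be left, right or unknown")
  if (length(msgs)) msgs else TRUE
})

#' CaseTriple: the three posture views of one case
#'
#' @slot caseId case identifier
#' @slot flexion,neutral,extension the three \linkS4class{ViewAnnotation}s
#' @exportClass CaseTriple
setClass("CaseTriple",
  representation(caseId = "character", flexion = "ViewAnnotation",
                 neutral = "ViewAnnotation", extension = "ViewAnnotation"))

setValidity("CaseTriple", function(object) {
  msgs <- character()
  if (object@flexion@view != "flexion")   msgs <- c(msgs, "flexion slot must hold a flexion view")
  if (object@neutral@view != "neutral")   msgs <- c(msgs, "neutral slot must hold a neutral view")
  if (object@extension@view != "extension") msgs <- c(msgs, "extension slot must hold an extension view")
  sp <- c(object@flexion@pixelSpacing, object@neutral@pixelSpacing,
          object@extension@pixelSpacing)
  if (diff(range(sp)) > 1e-12)
    msgs <- c(msgs, "pixel spacing differs across the three views")
  if (length(msgs)) msgs else TRUE
})

#' MidplaneLine: a vertebral midplane
#'
#' The midplane of a typical vertebra is the line through the midpoint of the
#' two anterior corners and the midpoint of the two posterior corners; for C2
#' it is the line through the two inferior corners. Coordinates are stored in
#' the y-up millimetre frame; \code{angle} is the signed direction angle of
#' the anterior-to-posterior vector in degrees, wrapped to (-180, 180].
#'
#' @slot anterior,posterior the two defining points (x, y) in mm
#' @slot angle signed direction angle in degrees
#' @exportClass MidplaneLine
setClass("MidplaneLine",
  representation(anterior = "numeric", posterior = "numeric", angle = "numeric"))

setValidity("MidplaneLine", function(object) {
  msgs <- character()
  if (length(object@anterior) != 2L || length(object@posterior) != 2L)
    msgs <- c(msgs, "anterior and posterior must each be length-2 (x, y)")
  else if (sqrt(sum((object@anterior - object@posterior)^2)) <= 1e-9)
    msgs <- c(msgs, "midplane points coincide")
  if (length(msgs)) msgs else TRUE
})

#' MotionMeasurement: per-case segmental angles and SIRM
#'
#' Stores the signed segmental angle theta of each of the five segments
#' (C2/3-C6/7) on each posture view, and the sagittal intervertebral
#' rotational motion (SIRM) of each segment for the three motion pairs.
#' SIRM is signed, with \code{F/E = theta_E - theta_F},
#' \code{F/N = theta_N - theta_F} and \code{N/E = theta_E - theta_N}, so that
#' \code{F/E = F/N + N/E} holds exactly for every segment.
#'
#' @slot caseId case identifier
#' @slot theta 5 x 3 matrix of segmental angles (deg); rows C2/3-C6/7,
#'   columns \code{F}, \code{N}, \code{E}
#' @slot sirm 5 x 3 matrix of SIRM values (deg); columns \code{F/E},
#'   \code{F/N}, \code{N/E}
#' @exportClass MotionMeasurement
setClass("MotionMeasurement",
  representation(caseId = "character", theta = "matrix", sirm = "matrix"))

setValidity("MotionMeasurement", function(object) {
  msgs <- character()
  if (!identical(dim(object@theta), c(5L, 3L)) ||
      !identical(dim(object@sirm), c(5L, 3L)))
    msgs <- c(msgs, "theta and sirm must be 5 x 3 matrices")
  else {
    if (!all(is.finite(object@theta)) || !all(is.finite(object@sirm)))
      msgs <- c(msgs, "angles must be finite")
    if (any(object@theta <= -180 | object@theta > 180))
      msgs <- c(msgs, "theta must lie in (-180, 180]")
    addl <- object@sirm[, 1] - (object@sirm[, 2] + object@sirm[, 3])
    if (any(abs(addl) > 0))
      msgs <- c(msgs, "SIRM additivity F/E = F/N + N/E violated")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ViewAnnotation", function(object) {
  cat(sprintf("ViewAnnotation: %s view, 22 landmarks, spacing %.4g mm/px, facing %s\n",
              object@view, object@pixelSpacing, object@facing))
  cat(sprintf("  annotator: %s; image: %s\n", object@annotator,
              if (anyNA(object@imageSize)) "unknown size"
              else paste(object@imageSize, collapse = " x ")))
})

setMethod("show", "CaseTriple", function(object) {
  cat(sprintf("CaseTriple '%s': flexion/neutral/extension, spacing %.4g mm/px\n",
              object@caseId, object@neutral@pixelSpacing))
})

setMethod("show", "MotionMeasurement", function(object) {
  cat(sprintf("MotionMeasurement '%s' (deg)\n", object@caseId))
  m <- cbind(object@theta, object@sirm)
  colnames(m) <- c("theta_F", "theta_N", "theta_E", "FE", "FN", "NE")
  print(round(m, 3))
})

#' @describeIn ViewAnnotation-class landmark coordinate matrix (22 x 2, px)
#' @param object a \code{ViewAnnotation}
#' @export
setGeneric("viewPoints", function(object) standardGeneric("viewPoints"))
setMethod("viewPoints", "ViewAnnotation", function(object) object@points)

#' @describeIn ViewAnnotation-class pixel spacing in mm
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
setMethod("pixelSpacing", "ViewAnnotation", function(object) object@pixelSpacing)

#' @describeIn MotionMeasurement-class 5 x 3 SIRM matrix (deg), columns F/E, F/N, N/E
#' @param object a \code{MotionMeasurement}
#' @export
setGeneric("sirmValues", function(object) standardGeneric("sirmValues"))
setMethod("sirmValues", "MotionMeasurement", function(object) object@sirm)

#' @describeIn MotionMeasurement-class 5 x 3 segmental angle matrix (deg), columns F, N, E
#' @export
setGeneric("thetaValues", function(object) standardGeneric("thetaValues"))
setMethod("thetaValues", "MotionMeasurement", function(object) object@theta)

#' @describeIn CaseTriple-class case identifier
#' @param object a \code{CaseTriple}
#' @export
setGeneric("caseId", function(object) standardGeneric("caseId"))
setMethod("caseId", "CaseTriple", function(object) object@caseId)
setMethod("caseId", "MotionMeasurement", function(object) object@caseId)

#' @describeIn CaseTriple-class extract one view ("flexion", "neutral", "extension")
#' @param view view name
#' @export
setGeneric("getView", function(object, view) standardGeneric("getView"))
setMethod("getView", "CaseTriple", function(object, view) {
  view <- match.arg(view, viewLabels())
  slot(object, view)
})
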
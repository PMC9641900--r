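#' Validate raw landmark coordinates into a ViewAnnotation
#'
#' Checks a named coordinate set against the 22-landmark scheme and returns a
#' validated \linkS4class{ViewAnnotation}. Missing, duplicated or non-finite
#' landmarks and non-positive pixel spacing are rejected with classed errors
#' (\code{MissingLandmark}, \code{DuplicateLandmark}, \code{NonFiniteLandmark},
#' \code{NonPositiveSpacing}).
#'
#' @param rawPoints named list or matrix of landmark coordinates: either a
#'   22 x 2 matrix with landmark ids as row names, or a list mapping landmark
#'   id to a length-2 numeric (x, y) in pixels
#' @param spacing pixel spacing in mm (> 0)
#' @param view view name: "flexion", "neutral" or "extension"
#' @param imageSize optional integer (width, height) in px
#' @param facing "left", "right" or "unknown"
#' @param annotator annotator identifier
#' @return a validated \code{ViewAnnotation}
#' @examples
#' pts <- buildViewLandmarks(spineTemplate(), zeroMotionProfile(), "neutral")
#' ann <- validateAnnotation(viewPoints(pts), spacing = pixelSpacing(pts))
#' @export
validateAnnotation <- function(rawPoints, spacing, view = "neutral",
                               imageSize = c(NA_integer_, NA_integer_),
                               facing = "unknown", annotator = "unspecified") {
  ids <- landmarkIds()
  if (is.matrix(rawPoints)) {
    nm <- rownames(rawPoints)
    coords <- lapply(seq_len(nrow(rawPoints)), function(i) rawPoints[i, , drop = TRUE])
    names(coords) <- nm
    rawPoints <- coords
  }
  cmAssert(length(rawPoints) > 0, "MissingLandmark", "no landmarks supplied")
  nm <- names(rawPoints)
  cmAssert(!is.null(nm) && all(nzchar(nm)), "MissingLandmark",
           "landmark coordinates must be named by landmark id")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    cmStop("DuplicateLandmark",
           sprintf("duplicated landmark(s): %s", paste(dup, collapse = ", ")))
  missing <- setdiff(ids, nm)
  if (length(missing))
    cmStop("MissingLandmark",
           sprintf("missing landmark(s): %s", paste(missing, collapse = ", ")))
  extra <- setdiff(nm, ids)
  if (length(extra))
    cmStop("UnknownLandmark",
           sprintf("unknown landmark(s): %s", paste(extra, collapse = ", ")))
  pts <- t(vapply(rawPoints[ids], function(p) as.numeric(p)[1:2], numeric(2)))
  dimnames(pts) <- list(ids, c("x", "y"))
  if (!all(is.finite(pts)))
    cmStop("NonFiniteLandmark",
           sprintf("non-finite coordinates for: %s",
                   paste(ids[!apply(is.finite(pts), 1, all)], collapse = ", ")))
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    cmStop("NonPositiveSpacing", "pixel spacing must be a single positive number")
  new("ViewAnnotation", view = view, points = pts, pixelSpacing = spacing,
      imageSize = as.integer(imageSize), facing = facing, annotator = annotator)
}

# mirror a view about the vertical image axis: x' = width - 1 - x
mirrorView <- function(ann) {
  w <- ann@imageSize[1]
  cmAssert(length(w) == 1L && is.finite(w), "UnknownImageWidth",
           "image width required to mirror a view")
  pts <- ann@points
  pts[, 1] <- w - 1 - pts[, 1]
  initialize(ann, points = pts,
             facing = switch(ann@facing, left = "right", right = "left", "unknown"))
}

#' Standardize patient facing
#'
#' Normalizes a view so that the patient faces the right-hand side of the
#' image (anterior landmarks at larger x) before any angle computation, making
#' downstream angle signs independent of how the radiograph was acquired or
#' stored. If the anterior landmarks already have larger mean x the input is
#' returned unchanged (with \code{facing = "right"}); otherwise the x-mirrored
#' copy is returned. The operation is idempotent.
#'
#' @param ann a \linkS4class{ViewAnnotation}
#' @return a \code{ViewAnnotation} with \code{facing = "right"}
#' @export
standardizeFacing <- function(ann) {
  stopifnot(is(ann, "ViewAnnotation"))
  pts <- ann@points
  mAnt <- mean(pts[anteriorIds(), 1])
  mPos <- mean(pts[posteriorIds(), 1])
  if (mAnt == mPos)
    cmStop("AmbiguousFacing",
           "anterior and posterior landmarks have equal mean x; facing undeterminable")
  if (mAnt > mPos) return(initialize(ann, facing = "right"))
  out <- mirrorView(ann)
  initialize(out, facing = "right")
}

#' Assemble a CaseTriple
#'
#' @param caseId case identifier
#' @param flexion,neutral,extension the three \linkS4class{ViewAnnotation}s
#' @return a validated \linkS4class{CaseTriple}
#' @export
caseTriple <- function(caseId, flexion, neutral, extension) {
  new("CaseTriple", caseId = as.character(caseId), flexion = flexion,
      neutral = neutral, extension = extension)
}

# ---- landmark table IO -----------------------------------------------------

#' Write annotations to the standard landmark CSV (+ JSON sidecar)
#'
#' The on-disk format is a UTF-8 comma-separated table with header
#' \code{case_id,view,landmark,x_px,y_px,annotator} and a sidecar JSON file
#' (same path with extension \code{.json}) carrying
#' \code{pixel_spacing_mm}, \code{width_px} and \code{height_px}.
#' Coordinates are written with full precision so a write/read round trip is
#' bit-exact.
#'
#' @param cases named list of \linkS4class{CaseTriple} objects (or a single one)
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeLandmarkCSV <- function(cases, path) {
  if (is(cases, "CaseTriple")) cases <- list(cases)
  rows <- do.call(rbind, lapply(cases, function(ct) {
    do.call(rbind, lapply(viewLabels(), function(v) {
      ann <- getView(ct, v)
      data.frame(case_id = ct@caseId, view = v,
                 landmark = rownames(ann@points),
                 x_px = ann@points[, 1], y_px = ann@points[, 2],
                 annotator = ann@annotator, stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  # full (17 sig. digit) precision => bit-exact round trip
  rows$x_px <- formatC(rows$x_px, digits = 17, format = "g")
  rows$y_px <- formatC(rows$y_px, digits = 17, format = "g")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  ref <- cases[[1]]@neutral
  meta <- list(pixel_spacing_mm = ref@pixelSpacing,
               width_px = ref@imageSize[1], height_px = ref@imageSize[2])
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

sidecarPath <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read annotations from the standard landmark CSV
#'
#' @param path CSV path written by \code{\link{writeLandmarkCSV}} (or
#'   hand-made in the same dialect); the JSON sidecar must be present unless
#'   \code{spacing} is given
#' @param spacing optional pixel spacing override in mm
#' @return named list of \linkS4class{CaseTriple} objects
#' @export
readLandmarkCSV <- function(path, spacing = NULL) {
  tab <- tryCatch(
    suppressWarnings(utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
      case_id = "character", view = "character", landmark = "character",
      x_px = "numeric", y_px = "numeric", annotator = "character"))),
    error = function(e) cmStop("ParseError", conditionMessage(e)))
  need <- c("case_id", "view", "landmark", "x_px", "y_px")
  if (!all(need %in% names(tab)))
    cmStop("ParseError", sprintf("landmark CSV must have columns %s",
                                 paste(need, collapse = ", ")))
  meta <- list(pixel_spacing_mm = spacing,
               width_px = NA_integer_, height_px = NA_integer_)
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    m <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(spacing)) meta$pixel_spacing_mm <- m$pixel_spacing_mm
    meta$width_px <- if (is.null(m$width_px)) NA_integer_ else m$width_px
    meta$height_px <- if (is.null(m$height_px)) NA_integer_ else m$height_px
  }
  if (is.null(meta$pixel_spacing_mm))
    cmStop("ParseError", "pixel spacing unavailable: no sidecar JSON and no override")
  sz <- as.integer(c(meta$width_px, meta$height_px))
  out <- list()
  for (cid in unique(tab$case_id)) {
    sub <- tab[tab$case_id == cid, ]
    views <- list()
    ok <- TRUE
    for (v in viewLabels()) {
      vs <- sub[sub$view == v, ]
      if (nrow(vs) == 0L) { ok <- FALSE; next }
      pts <- as.matrix(vs[, c("x_px", "y_px")])
      rownames(pts) <- vs$landmark
      views[[v]] <- validateAnnotation(
        pts[landmarkIds()[landmarkIds() %in% rownames(pts)], , drop = FALSE],
        spacing = meta$pixel_spacing_mm, view = v, imageSize = sz,
        annotator = if ("annotator" %in% names(vs)) vs$annotator[1] else "unspecified")
    }
    if (!ok) {
      warning(sprintf("case '%s' skipped: missing view(s)", cid), call. = FALSE)
      next
    }
    out[[cid]] <- caseTriple(cid, views$flexion, views$neutral, views$extension)
  }
  out
}
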
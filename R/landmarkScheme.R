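#' The 22-landmark cervical annotation scheme
#'
#' Lateral cervical radiographs are annotated with 22 vertebral body corner
#' landmarks. Each typical vertebra C3-C7 contributes its four body corners,
#' named \code{G1} (anterior-superior), \code{G2} (posterior-superior),
#' \code{G3} (anterior-inferior) and \code{G4} (posterior-inferior). C2, whose
#' body shape is atypical, contributes only its inferior corners, named
#' \code{B3} (anterior-inferior) and \code{B4} (posterior-inferior). Landmark
#' identifiers are strings \code{"<vertebra>-<role>"}, e.g. \code{"2-B3"} or
#' \code{"5-G1"}, and each landmark carries a fixed heatmap channel index
#' 0-21 that is stable across the package.
#'
#' @return A \code{data.frame} with one row per landmark and columns
#'   \code{landmark} (identifier), \code{vertebra} (integer 2-7), \code{role}
#'   (one of \code{anterior-superior}, \code{posterior-superior},
#'   \code{anterior-inferior}, \code{posterior-inferior}) and \code{channel}
#'   (0-based heatmap channel index).
#' @examples
#' sch <- landmarkScheme()
#' nrow(sch)              # 22
#' subset(sch, vertebra == 2)$landmark
#' @export
landmarkScheme <- function() {
  roleOf <- c(G1 = "anterior-superior",  G2 = "posterior-superior",
              G3 = "anterior-inferior",  G4 = "posterior-inferior",
              B3 = "anterior-inferior",  B4 = "posterior-inferior")
  codes <- c("2-B3", "2-B4",
             unlist(lapply(3:7, function(v) paste0(v, "-G", 1:4))))
  short <- sub("^[0-9]+-", "", codes)
  data.frame(
    landmark = codes,
    vertebra = as.integer(sub("-.*$", "", codes)),
    role     = unname(roleOf[short]),
    channel  = seq_along(codes) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Landmark identifiers in channel order
#'
#' @return Character vector of the 22 landmark ids, ordered by channel index.
#' @export
landmarkIds <- function() landmarkScheme()$landmark

# ids of landmarks with an anterior / posterior role (used for facing checks)
anteriorIds <- function() {
  sch <- landmarkScheme()
  sch$landmark[grepl("^anterior", sch$role)]
}
posteriorIds <- function() {
  sch <- landmarkScheme()
  sch$landmark[grepl("^posterior", sch$role)]
}

#' Segment labels for the five measured levels
#'
#' @return Character vector \code{c("C2/3","C3/4","C4/5","C5/6","C6/7")}.
#' @export
segmentLabels <- function() c("C2/3", "C3/4", "C4/5", "C5/6", "C6/7")

#' Motion pair labels
#'
#' @return Character vector \code{c("F/E","F/N","N/E")}.
#' @export
motionPairLabels <- function() c("F/E", "F/N", "N/E")

viewLabels <- function() c("flexion", "neutral", "extension")
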
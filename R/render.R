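#' Rendering configuration for synthetic views
#'
#' @param blurSigmaPx Gaussian blur SD in px applied to the ideal scene
#' @param noiseSd additive pixel noise SD (intensity units, image in [0, 1])
#' @param boneIntensity fill intensity of vertebral bodies
#' @param backgroundRange intensity range of the vertical soft-tissue gradient
#' @param c2HeightMm height of the schematic C2 wedge drawn above its
#'   inferior edge
#' @param seed RNG seed for the pixel noise
#' @return list of class \code{"RenderConfig"}
#' @export
renderConfig <- function(blurSigmaPx = 1.2, noiseSd = 0.03,
                         boneIntensity = 0.85,
                         backgroundRange = c(0.25, 0.45),
                         c2HeightMm = 9, seed = NULL) {
  structure(list(blurSigmaPx = blurSigmaPx, noiseSd = noiseSd,
                 boneIntensity = boneIntensity,
                 backgroundRange = backgroundRange,
                 c2HeightMm = c2HeightMm, seed = seed),
            class = "RenderConfig")
}

# ray-casting point-in-polygon, vectorized over points (poly: k x 2)
pointsInPolygon <- function(px, py, poly) {
  k <- nrow(poly)
  inside <- logical(length(px))
  j <- k
  for (i in seq_len(k)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

fillPolygon <- function(img, poly, value) {
  H <- nrow(img); W <- ncol(img)
  x0 <- max(0L, floor(min(poly[, 1]))); x1 <- min(W - 1L, ceiling(max(poly[, 1])))
  y0 <- max(0L, floor(min(poly[, 2]))); y1 <- min(H - 1L, ceiling(max(poly[, 2])))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  grid <- expand.grid(y = ys, x = xs)
  hit <- pointsInPolygon(grid$x, grid$y, poly)
  idx <- cbind(grid$y[hit] + 1L, grid$x[hit] + 1L)
  img[idx] <- value
  img
}

#' Render a synthetic lateral view
#'
#' Draws the filled vertebral-body quadrilaterals (and a schematic C2 wedge
#' above its inferior edge) at bone intensity over a vertical soft-tissue
#' background gradient, Gaussian-blurs the scene and adds pixel noise. The
#' ground-truth landmarks pass through unchanged.
#'
#' @param ann a \linkS4class{ViewAnnotation} with known image size
#' @param cfg a \code{\link{renderConfig}}
#' @return list with \code{image} (H x W matrix in [0, 1], row = y) and
#'   \code{annotation} (the input, unchanged)
#' @export
renderView <- function(ann, cfg = renderConfig()) {
  stopifnot(is(ann, "ViewAnnotation"))
  sz <- ann@imageSize
  cmAssert(!anyNA(sz), "OutOfFrame", "image size required for rendering")
  W <- sz[1]; H <- sz[2]
  bg <- cfg$backgroundRange
  img <- matrix(rep(seq(bg[1], bg[2], length.out = H), W), H, W)
  pts <- ann@points
  for (v in 3:7) {
    poly <- pts[paste0(v, c("-G1", "-G2", "-G4", "-G3")), , drop = FALSE]
    img <- fillPolygon(img, poly, cfg$boneIntensity)
  }
  b3 <- pts["2-B3", ]; b4 <- pts["2-B4", ]
  d <- b4 - b3
  up <- c(-d[2], d[1]); up <- up / sqrt(sum(up^2))   # superior in y-down px
  hPx <- cfg$c2HeightMm / ann@pixelSpacing
  poly2 <- rbind(b3, b4, b4 + up * hPx - 0.2 * d, b3 + up * hPx + 0.2 * d)
  img <- fillPolygon(img, poly2, cfg$boneIntensity)
  if (cfg$blurSigmaPx > 0)
    img <- EBImage::gblur(img, sigma = cfg$blurSigmaPx)
  if (cfg$noiseSd > 0) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    img <- img + matrix(stats::rnorm(H * W, 0, cfg$noiseSd), H, W)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, annotation = ann)
}

# PNG IO: images stored row-major [H, W] in [0,1]; png::writePNG expects the
# same orientation, so these are direct passes.
writeImagePNG <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
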
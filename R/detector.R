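#' Detector configuration
#'
#' Configuration of the compact multi-resolution heatmap-regression landmark
#' detector. The network keeps a high-resolution branch at heatmap
#' resolution throughout and exchanges information with a parallel
#' half-resolution branch after every stage, ending in a 22-channel heatmap
#' head read out by argmax. The desk-scale defaults (128 px input, two
#' branches, two stages) train on one CPU; the full-size configuration is
#' reachable through these fields.
#'
#' @param inputSize square network input size in px (default 128)
#' @param stride heatmap stride; must divide \code{inputSize} (default 4)
#' @param gaussianSigma SD of the target Gaussian bumps, in heatmap cells
#' @param channels widths of the high- and low-resolution branches
#' @param nStages number of fusion stages (default 2)
#' @param coordChannels append normalized x/y coordinate channels to the
#'   input (default TRUE): vertebral corners of adjacent levels are locally
#'   near-identical, and the coordinate channels give the trunk the global
#'   positional context needed to tell the levels apart
#' @param lr SGD learning rate
#' @param lrDecayAfter epoch after which the learning rate is multiplied by
#'   \code{lrDecayFactor} (Inf = constant rate)
#' @param lrDecayFactor step-decay factor
#' @param momentum SGD momentum
#' @param weightDecay SGD weight decay
#' @param epochs training epochs
#' @param batchSize minibatch size
#' @param augRotationDeg augmentation rotation range (+/- deg, 0 = off)
#' @param augScaleRange augmentation relative scale range (0 = off)
#' @param augFlip horizontal flip augmentation (off by default: flipping a
#'   lateral view reverses the anterior-posterior semantics of the labels)
#' @param subPixel quarter-offset sub-pixel decoding at prediction time (see
#'   \code{\link{decodeHeatmaps}})
#' @param seed RNG seed for weight initialization and shuffling
#' @return list of class \code{"DetectorConfig"}
#' @export
detectorConfig <- function(inputSize = 128L, stride = 4L, gaussianSigma = 2,
                           channels = c(16L, 32L), nStages = 2L,
                           lr = 1, lrDecayAfter = 22L, lrDecayFactor = 0.3,
                           momentum = 0.9, weightDecay = 5e-4,
                           epochs = 35L, batchSize = 8L,
                           augRotationDeg = 0, augScaleRange = 0,
                           augFlip = FALSE, coordChannels = TRUE,
                           subPixel = TRUE, seed = 1L) {
  stopifnot(inputSize %% stride == 0L, gaussianSigma > 0, length(channels) == 2L)
  structure(list(inputSize = as.integer(inputSize), stride = as.integer(stride),
                 nChannelsOut = 22L, gaussianSigma = gaussianSigma,
                 channels = as.integer(channels), nStages = as.integer(nStages),
                 coordChannels = isTRUE(coordChannels),
                 subPixel = isTRUE(subPixel),
                 lr = lr, lrDecayAfter = lrDecayAfter,
                 lrDecayFactor = lrDecayFactor,
                 momentum = momentum, weightDecay = weightDecay,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 augRotationDeg = augRotationDeg, augScaleRange = augScaleRange,
                 augFlip = augFlip, seed = as.integer(seed)),
            class = "DetectorConfig")
}

# ---- affine helpers (2x3 matrices acting on (x, y, 1)) ---------------------

affineIdentity <- function() cbind(diag(2), c(0, 0))

affineCompose <- function(a, b) {          # apply b first, then a
  A <- rbind(a, c(0, 0, 1)); B <- rbind(b, c(0, 0, 1))
  (A %*% B)[1:2, , drop = FALSE]
}

affineInvert <- function(a) {
  M <- a[, 1:2]; t <- a[, 3]
  Mi <- solve(M)
  cbind(Mi, -Mi %*% t)
}

applyAffine <- function(a, pts) {
  out <- t(a %*% rbind(t(pts), 1))
  dimnames(out) <- dimnames(pts)
  out
}

# bilinear inverse-mapping warp; coords are 0-based pixel centers
warpAffine <- function(img, affine, outSize, fill = NULL) {
  H <- nrow(img); W <- ncol(img)
  if (is.null(fill)) fill <- stats::median(c(img[1, ], img[H, ], img[, 1], img[, W]))
  inv <- affineInvert(affine)
  grid <- cbind(rep(0:(outSize[1] - 1), each = outSize[2]),   # x
                rep(0:(outSize[2] - 1), times = outSize[1]))  # y
  src <- applyAffine(inv, grid)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    v <- rep(fill, length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(x0, y0) + fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) + fx * fy * pick(x0 + 1, y0 + 1)
  matrix(v, nrow = outSize[2], ncol = outSize[1])   # filled y-fastest per x col
}

#' Preprocess an image (and landmarks) for the detector
#'
#' Resizes the image to the square network input and optionally applies a
#' random rotation/scale/flip augmentation about the input centre. The full
#' affine from original-image to network-input coordinates is recorded and
#' invertible; landmarks, when given, are mapped by the same affine.
#'
#' @param image grayscale matrix (rows = y)
#' @param landmarks optional 22 x 2 landmark matrix in original px
#' @param cfg \code{\link{detectorConfig}}
#' @param augment draw a random augmentation (training only)
#' @return list: \code{image} (inputSize x inputSize), \code{affine} (2 x 3,
#'   original -> input), \code{affineInv}, \code{landmarks} (mapped, or NULL)
#' @export
preprocessImage <- function(image, landmarks = NULL, cfg = detectorConfig(),
                            augment = FALSE) {
  cmAssert(length(dim(image)) == 2L && all(dim(image) > 0L), "EmptyImage",
           "image must be a non-empty matrix")
  S <- cfg$inputSize
  A <- rbind(c(S / ncol(image), 0, 0), c(0, S / nrow(image), 0))
  if (augment && (cfg$augRotationDeg > 0 || cfg$augScaleRange > 0 || cfg$augFlip)) {
    th <- stats::runif(1, -cfg$augRotationDeg, cfg$augRotationDeg) * pi / 180
    sc <- 1 + stats::runif(1, -cfg$augScaleRange, cfg$augScaleRange)
    fl <- cfg$augFlip && stats::runif(1) < 0.5
    ctr <- (S - 1) / 2
    R <- sc * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    if (fl) R <- R %*% diag(c(-1, 1))
    aug <- cbind(R, c(ctr, ctr) - R %*% c(ctr, ctr))
    A <- affineCompose(aug, A)
  }
  if (identical(dim(image), c(S, S)) &&
      isTRUE(all.equal(A, affineIdentity(), tolerance = 1e-12))) {
    warped <- image
  } else {
    warped <- warpAffine(image, A, c(S, S))
  }
  lm <- if (is.null(landmarks)) NULL else applyAffine(A, landmarks)
  list(image = warped, affine = A, affineInv = affineInvert(A), landmarks = lm)
}

# landmark (input px) <-> heatmap cell centre: p = stride*c + (stride-1)/2
inputToHeatmap <- function(p, stride) (p - (stride - 1) / 2) / stride
heatmapToInput <- function(c, stride) stride * c + (stride - 1) / 2

#' Build target heatmaps for a landmark set
#'
#' One unnormalized Gaussian bump (peak 1.0, SD \code{cfg$gaussianSigma}
#' heatmap cells) per channel, centred at the landmark mapped to heatmap
#' resolution.
#'
#' @param landmarks 22 x 2 matrix in network-input px
#' @param cfg \code{\link{detectorConfig}}
#' @return array (Hh, Wh, 22)
#' @export
makeTargetHeatmaps <- function(landmarks, cfg = detectorConfig()) {
  S <- cfg$inputSize; hs <- S %/% cfg$stride
  cmAssert(all(landmarks >= -0.5 & landmarks <= S - 0.5), "OutOfFrame",
           "landmarks fall outside the network input frame")
  hm <- array(0, c(hs, hs, nrow(landmarks)))
  xs <- 0:(hs - 1)
  for (k in seq_len(nrow(landmarks))) {
    cc <- inputToHeatmap(landmarks[k, ], cfg$stride)
    gx <- exp(-(xs - cc[1])^2 / (2 * cfg$gaussianSigma^2))
    gy <- exp(-(xs - cc[2])^2 / (2 * cfg$gaussianSigma^2))
    hm[, , k] <- outer(gy, gx)
  }
  hm
}

#' Decode heatmaps to landmark coordinates
#'
#' Per channel, the argmax cell (first occurrence in row-major order on ties)
#' is mapped back to original-image pixels through the recorded affine; the
#' peak activation is returned as a confidence. All-zero channels are flagged
#' (coordinates still returned, confidence 0).
#'
#' @param heatmaps array (Hh, Wh, 22)
#' @param affineInv 2 x 3 affine mapping network-input px to original px
#' @param stride heatmap stride
#' @param subPixel apply quarter-offset refinement: shift the decoded peak a
#'   quarter cell toward the larger of its two neighbours on each axis (the
#'   classical heatmap decoding refinement; off = plain argmax)
#' @return list: \code{points} (22 x 2, original px), \code{confidence},
#'   \code{allZero} (logical per channel)
#' @export
decodeHeatmaps <- function(heatmaps, affineInv = affineIdentity(), stride = 4L,
                           subPixel = FALSE) {
  K <- dim(heatmaps)[3]
  pts <- matrix(NA_real_, K, 2)
  conf <- numeric(K); zero <- logical(K)
  for (k in seq_len(K)) {
    plane <- heatmaps[, , k]
    tp <- t(plane)                         # row-major scan
    idx <- which.max(tp)
    cx <- (idx - 1) %% ncol(plane)
    cy <- (idx - 1) %/% ncol(plane)
    conf[k] <- plane[cy + 1, cx + 1]
    zero[k] <- all(plane == 0)
    if (zero[k]) conf[k] <- 0
    cc <- c(cx, cy)
    if (isTRUE(subPixel) && !zero[k]) {
      if (cx > 0 && cx < ncol(plane) - 1)
        cc[1] <- cc[1] + 0.25 * sign(plane[cy + 1, cx + 2] - plane[cy + 1, cx])
      if (cy > 0 && cy < nrow(plane) - 1)
        cc[2] <- cc[2] + 0.25 * sign(plane[cy + 2, cx + 1] - plane[cy, cx + 1])
    }
    pts[k, ] <- heatmapToInput(cc, stride)
  }
  pts <- applyAffine(affineInv, pts)
  rownames(pts) <- if (K == 22L) landmarkIds() else NULL
  colnames(pts) <- c("x", "y")
  list(points = pts, confidence = conf, allZero = zero)
}

# ---- network ---------------------------------------------------------------

convInit <- function(K, C, kh, kw, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (C * kh * kw))
  list(w = matrix(stats::rnorm(K * C * kh * kw, 0, scale), K, C * kh * kw),
       b = rep(0, K), kh = kh, kw = kw)
}

initDetectorParams <- function(cfg) {
  set.seed(cfg$seed)
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]
  cin <- if (isTRUE(cfg$coordChannels)) 3L else 1L
  p <- list(
    stem1 = convInit(c1, cin, 3, 3),
    stem2 = convInit(c1, c1, 3, 3),
    trans = convInit(c2, c1, 3, 3))
  for (s in seq_len(cfg$nStages)) {
    p[[paste0("b1_", s)]] <- convInit(c1, c1, 3, 3)
    p[[paste0("b2_", s)]] <- convInit(c2, c2, 3, 3)
    p[[paste0("f12_", s)]] <- convInit(c1, c2, 1, 1)
    p[[paste0("f21_", s)]] <- convInit(c2, c1, 3, 3)
  }
  # near-zero head: initial predictions start at the background level, which
  # keeps the first error signals small and the ReLU trunk alive
  p$head <- convInit(cfg$nChannelsOut, c1, 1, 1, scale = 1e-3)
  p
}

up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

down2sum <- function(g) {
  d <- dim(g)
  i1 <- seq(1, d[1], 2); i2 <- seq(2, d[1], 2)
  j1 <- seq(1, d[2], 2); j2 <- seq(2, d[2], 2)
  g[i1, j1, , drop = FALSE] + g[i2, j1, , drop = FALSE] +
    g[i1, j2, , drop = FALSE] + g[i2, j2, , drop = FALSE]
}

convF <- function(lay, x, stride = 1L, pad = 1L)
  conv2dForward(x, lay$w, lay$b, lay$kh, lay$kw, stride, pad)

# leaky rectifier: the small negative slope keeps units recoverable
relu <- function(x) { neg <- x < 0; x[neg] <- 0.01 * x[neg]; x }
reluGrad <- function(post) {
  g <- array(1, dim(post)); g[post < 0] <- 0.01; g
}

detectorForward <- function(params, x, cfg, keep = FALSE) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x <- (x - mean(x)) / (stats::sd(x) + 1e-8)   # per-image standardization
  if (isTRUE(cfg$coordChannels)) {
    S1 <- dim(x)[1]; S2 <- dim(x)[2]
    cy <- matrix(seq(-0.5, 0.5, length.out = S1), S1, S2)
    cx <- matrix(seq(-0.5, 0.5, length.out = S2), S1, S2, byrow = TRUE)
    x <- array(c(x, cx, cy), c(S1, S2, 3L))
  }
  cache <- list(x = x)
  z1 <- convF(params$stem1, x, stride = 2L); a1 <- relu(z1)
  z2 <- convF(params$stem2, a1, stride = 2L); a2 <- relu(z2)
  zt <- convF(params$trans, a2, stride = 2L); at <- relu(zt)
  cache$stem <- list(a1 = a1, a2 = a2, at = at)
  b1 <- a2; b2 <- at
  for (s in seq_len(cfg$nStages)) {
    zb1 <- convF(params[[paste0("b1_", s)]], b1); ab1 <- relu(zb1)
    zb2 <- convF(params[[paste0("b2_", s)]], b2); ab2 <- relu(zb2)
    zf12 <- convF(params[[paste0("f12_", s)]], ab2, pad = 0L)
    f1 <- relu(ab1 + up2(zf12))
    zf21 <- convF(params[[paste0("f21_", s)]], ab1, stride = 2L)
    f2 <- relu(ab2 + zf21)
    cache[[paste0("stage", s)]] <-
      list(b1in = b1, b2in = b2, ab1 = ab1, ab2 = ab2, f1 = f1, f2 = f2)
    b1 <- f1; b2 <- f2
  }
  out <- convF(params$head, b1, pad = 0L)
  cache$b1 <- b1
  if (keep) list(out = out, cache = cache) else out
}

detectorBackward <- function(params, cache, gout, cfg) {
  g <- list()
  bw <- function(name, x, gy, stride = 1L, pad = 1L) {
    lay <- params[[name]]
    r <- conv2dBackward(x, lay$w, gy, lay$kh, lay$kw, stride, pad)
    g[[name]] <<- list(w = r$gw, b = as.numeric(r$gb))
    r$gx
  }
  gb1 <- bw("head", cache$b1, gout, pad = 0L)
  gb2 <- NULL
  for (s in rev(seq_len(cfg$nStages))) {
    st <- cache[[paste0("stage", s)]]
    gf1 <- gb1 * reluGrad(st$f1)
    gf2 <- if (is.null(gb2)) array(0, dim(st$f2)) else gb2 * reluGrad(st$f2)
    # f2 = relu(ab2 + f21(ab1)); f1 = relu(ab1 + up2(f12(ab2)))
    gab1 <- gf1 + bw(paste0("f21_", s), st$ab1, gf2, stride = 2L)
    gab2 <- gf2 + bw(paste0("f12_", s), st$ab2, down2sum(gf1), pad = 0L)
    gb1 <- bw(paste0("b1_", s), st$b1in, gab1 * reluGrad(st$ab1))
    gb2 <- bw(paste0("b2_", s), st$b2in, gab2 * reluGrad(st$ab2))
  }
  st <- cache$stem
  gat <- gb2 * reluGrad(st$at)
  ga2 <- gb1 + bw("trans", st$a2, gat, stride = 2L)
  ga1 <- bw("stem2", st$a1, ga2 * reluGrad(st$a2), stride = 2L)
  bw("stem1", cache$x, ga1 * reluGrad(st$a1), stride = 2L)
  g
}

#' Train the landmark detector
#'
#' Minimizes the mean squared error between predicted and target heatmaps by
#' SGD with momentum and weight decay. The validation loss is evaluated each
#' epoch and the parameters with minimum validation loss are returned. Fully
#' seed-reproducible under single-threaded execution.
#'
#' @param trainSamples,valSamples lists of samples as from
#'   \code{\link{loadDetectorSamples}} (fields \code{image}, \code{points})
#' @param cfg \code{\link{detectorConfig}}
#' @param verbose print per-epoch losses
#' @return object of class \code{"sirmDetector"}: \code{cfg}, \code{params}
#'   (best checkpoint), \code{lossHistory} data.frame (epoch, train, val),
#'   \code{bestEpoch}
#' @export
trainDetector <- function(trainSamples, valSamples, cfg = detectorConfig(),
                          verbose = FALSE) {
  cmAssert(length(trainSamples) > 0 && length(valSamples) > 0, "EmptyDataset",
           "train and validation sets must be non-empty")
  params <- initDetectorParams(cfg)
  vel <- lapply(params, function(l) list(w = l$w * 0, b = l$b * 0))
  noAug <- cfg$augRotationDeg == 0 && cfg$augScaleRange == 0 && !cfg$augFlip

  prep <- function(s, augment = FALSE) {
    pp <- preprocessImage(s$image, s$points, cfg, augment = augment)
    lmClamped <- pmin(pmax(pp$landmarks, 0), cfg$inputSize - 1)
    list(x = pp$image, target = makeTargetHeatmaps(lmClamped, cfg))
  }
  trainPrep <- if (noAug) lapply(trainSamples, prep) else NULL
  valPrep <- lapply(valSamples, prep)

  evalLoss <- function(prepped) {
    mean(vapply(prepped, function(p) {
      pred <- detectorForward(params, p$x, cfg)
      mean((pred - p$target)^2)
    }, numeric(1)))
  }

  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  best <- list(val = Inf, params = params, epoch = 0L)
  nT <- length(trainSamples)
  for (ep in seq_len(cfg$epochs)) {
    lrEp <- cfg$lr * if (ep > cfg$lrDecayAfter) cfg$lrDecayFactor else 1
    set.seed(deriveSeed(cfg$seed, 50000L + ep))
    ord <- sample(nT)
    epLoss <- 0
    for (start in seq(1, nT, by = cfg$batchSize)) {
      idx <- ord[start:min(start + cfg$batchSize - 1L, nT)]
      gacc <- NULL
      bLoss <- 0
      for (i in idx) {
        p <- if (noAug) trainPrep[[i]] else prep(trainSamples[[i]], augment = TRUE)
        fw <- detectorForward(params, p$x, cfg, keep = TRUE)
        diffs <- fw$out - p$target
        l <- mean(diffs^2)
        cmAssert(is.finite(l), "NonFiniteLoss",
                 sprintf("non-finite training loss at epoch %d", ep))
        bLoss <- bLoss + l
        gout <- 2 * diffs / length(diffs)
        gr <- detectorBackward(params, fw$cache, gout, cfg)
        if (is.null(gacc)) gacc <- gr
        else for (nm in names(gr)) {
          gacc[[nm]]$w <- gacc[[nm]]$w + gr[[nm]]$w
          gacc[[nm]]$b <- gacc[[nm]]$b + gr[[nm]]$b
        }
      }
      nb <- length(idx)
      for (nm in names(gacc)) {
        gw <- gacc[[nm]]$w / nb + cfg$weightDecay * params[[nm]]$w
        gb <- gacc[[nm]]$b / nb
        vel[[nm]]$w <- cfg$momentum * vel[[nm]]$w - lrEp * gw
        vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b - lrEp * gb
        params[[nm]]$w <- params[[nm]]$w + vel[[nm]]$w
        params[[nm]]$b <- params[[nm]]$b + vel[[nm]]$b
      }
      epLoss <- epLoss + bLoss
    }
    valLoss <- evalLoss(valPrep)
    hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / nT, val = valLoss))
    if (valLoss < best$val) best <- list(val = valLoss, params = params, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", ep, epLoss / nT, valLoss))
  }
  structure(list(cfg = cfg, params = best$params, lossHistory = hist,
                 bestEpoch = best$epoch), class = "sirmDetector")
}

#' Predict landmarks on an image
#'
#' Runs preprocessing (no augmentation), the network forward pass and heatmap
#' decoding, returning a \linkS4class{ViewAnnotation} composable with
#' \code{\link{measureCase}}.
#'
#' @param model a trained \code{"sirmDetector"}
#' @param image grayscale matrix
#' @param spacing pixel spacing mm/px of the image
#' @param view view label recorded in the annotation
#' @return list: \code{annotation} (\code{ViewAnnotation}),
#'   \code{confidence} (22 peak activations), \code{allZero} (flags)
#' @export
predictLandmarks <- function(model, image, spacing, view = "neutral") {
  stopifnot(inherits(model, "sirmDetector"))
  pp <- preprocessImage(image, NULL, model$cfg, augment = FALSE)
  hm <- detectorForward(model$params, pp$image, model$cfg)
  dec <- decodeHeatmaps(hm, pp$affineInv, model$cfg$stride,
                        subPixel = isTRUE(model$cfg$subPixel))
  pts <- dec$points
  pts[, 1] <- pmin(pmax(pts[, 1], 0), ncol(image) - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), nrow(image) - 1)
  ann <- validateAnnotation(pts, spacing = spacing, view = view,
                            imageSize = c(ncol(image), nrow(image)),
                            annotator = "model")
  list(annotation = ann, confidence = dec$confidence, allZero = dec$allZero)
}

#' Save / load a detector checkpoint
#'
#' The checkpoint embeds the full \code{\link{detectorConfig}} together with
#' the weights and loss history.
#'
#' @param model a \code{"sirmDetector"}
#' @param path checkpoint file path
#' @return \code{saveDetector}: \code{path} invisibly; \code{loadDetector}:
#'   the restored model
#' @export
saveDetector <- function(model, path) {
  stopifnot(inherits(model, "sirmDetector"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveDetector
#' @export
loadDetector <- function(path) {
  cmAssert(file.exists(path), "InvalidConfig",
           sprintf("checkpoint not found: %s", path))
  m <- readRDS(path)
  cmAssert(inherits(m, "sirmDetector"), "InvalidConfig",
           "file is not a detector checkpoint")
  m
}
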
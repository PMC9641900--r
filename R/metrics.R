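#' Reference standard by averaging annotations
#'
#' The reference standard is the coordinate-wise (or value-wise) arithmetic
#' mean over two or more annotations of the same case and view, or over two
#' or more aligned measurement vectors.
#'
#' @param xs list of \linkS4class{ViewAnnotation}s, of landmark matrices with
#'   identical row names, or of equal-length numeric vectors
#' @return an object of the same kind holding the mean
#' @export
referenceStandard <- function(xs) {
  stopifnot(is.list(xs), length(xs) >= 2L)
  if (is(xs[[1]], "ViewAnnotation")) {
    mats <- lapply(xs, viewPoints)
    ref <- referenceStandard(mats)
    return(initialize(xs[[1]], points = ref, annotator = "reference"))
  }
  if (is.matrix(xs[[1]])) {
    ids <- rownames(xs[[1]])
    for (m in xs)
      if (!identical(sort(rownames(m)), sort(ids)))
        cmStop("MismatchedLandmarks", "annotations have different landmark sets")
    out <- Reduce(`+`, lapply(xs, function(m) m[ids, , drop = FALSE])) / length(xs)
    return(out)
  }
  n <- unique(vapply(xs, length, integer(1)))
  cmAssert(length(n) == 1L, "LengthMismatch", "vectors must have equal length")
  Reduce(`+`, xs) / length(xs)
}

pairDistancesMm <- function(a, b) {
  stopifnot(is(a, "ViewAnnotation"), is(b, "ViewAnnotation"))
  if (abs(a@pixelSpacing - b@pixelSpacing) > 1e-12)
    cmStop("SpacingMismatch", "annotations have different pixel spacing")
  d <- a@points - b@points
  sqrt(rowSums(d^2)) * a@pixelSpacing
}

#' Landmark distance reliability between two annotations
#'
#' Euclidean landmark-to-landmark distances in mm (pixels times spacing) and
#' the percentage of landmarks within each threshold. Distances exactly at a
#' threshold count as within (\code{<=} convention).
#'
#' @param a,b \linkS4class{ViewAnnotation}s of the same view
#' @param thresholdsMm distance thresholds in mm (default 1, 2, 3)
#' @return named numeric vector of percentages in [0, 100]
#' @export
distanceReliability <- function(a, b, thresholdsMm = c(1, 2, 3)) {
  d <- pairDistancesMm(a, b)
  out <- vapply(thresholdsMm, function(t) 100 * mean(d <= t), numeric(1))
  names(out) <- paste0(thresholdsMm, "mm")
  out
}

#' Pooled distance-reliability table across raters and views
#'
#' Pools landmark distances over cases per rater pair and view, mirroring the
#' standard inter-observer reliability layout.
#'
#' @param raterCases list (one element per rater) of named
#'   \linkS4class{CaseTriple} lists with matching case ids
#' @param thresholdsMm thresholds in mm
#' @return \code{data.frame}: \code{pair}, \code{view}, one column per
#'   threshold
#' @export
reliabilityTable <- function(raterCases, thresholdsMm = c(1, 2, 3)) {
  nr <- length(raterCases)
  stopifnot(nr >= 2L)
  rows <- list()
  for (i in seq_len(nr - 1L)) for (j in seq(i + 1L, nr)) {
    for (v in viewLabels()) {
      d <- unlist(lapply(names(raterCases[[i]]), function(cid)
        pairDistancesMm(getView(raterCases[[i]][[cid]], v),
                        getView(raterCases[[j]][[cid]], v))))
      pct <- vapply(thresholdsMm, function(t) 100 * mean(d <= t), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = sprintf("R%d vs R%d", i, j), view = v,
        t(stats::setNames(pct, paste0("within_", thresholdsMm, "mm"))),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of correct keypoints (PCK) and per-vertebra means (MPCK)
#'
#' PCK is the percentage of predicted landmarks falling within an r-mm radius
#' of the reference landmark (radius converted to pixels via the spacing;
#' \code{<=} convention). \code{pckByLandmark} pools all supplied
#' prediction/reference pairs per landmark id; \code{pck} pools everything;
#' \code{mpck} averages each vertebra's landmark PCKs (2 landmarks for C2,
#' 4 for C3-C7).
#'
#' @param preds,refs \linkS4class{ViewAnnotation}s or lists of them, aligned
#' @param radiusMm neighbourhood radius in mm
#' @return \code{pck}: scalar percentage; \code{pckByLandmark}: named vector
#'   of 22 percentages; \code{mpck}: named vector MC2-MC7
#' @export
pckByLandmark <- function(preds, refs, radiusMm) {
  if (is(preds, "ViewAnnotation")) preds <- list(preds)
  if (is(refs, "ViewAnnotation")) refs <- list(refs)
  cmAssert(length(preds) == length(refs), "LengthMismatch",
           "pred and ref lists must be aligned")
  d <- vapply(seq_along(preds), function(i) pairDistancesMm(preds[[i]], refs[[i]]),
              numeric(22))
  d <- matrix(d, nrow = 22)
  out <- 100 * rowMeans(d <= radiusMm)
  names(out) <- landmarkIds()
  out
}

#' @rdname pckByLandmark
#' @export
pck <- function(preds, refs, radiusMm) {
  perLm <- pckByLandmark(preds, refs, radiusMm)
  mean(perLm)
}

#' @rdname pckByLandmark
#' @export
mpck <- function(preds, refs, radiusMm) {
  perLm <- pckByLandmark(preds, refs, radiusMm)
  sch <- landmarkScheme()
  out <- vapply(2:7, function(v) mean(perLm[sch$landmark[sch$vertebra == v]]),
                numeric(1))
  names(out) <- paste0("MC", 2:7)
  out
}

# ---- agreement statistics --------------------------------------------------

# ICC(2,1): two-way random effects, absolute agreement, single measures,
# computed from the mean squares of the n x k two-way layout, with the
# standard F-based 95% confidence interval.
iccAbsoluteSingle <- function(mat, conf = 0.95) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  rowM <- rowMeans(mat); colM <- colMeans(mat)
  MSR <- k * sum((rowM - grand)^2) / (n - 1)
  MSC <- n * sum((colM - grand)^2) / (k - 1)
  SSE <- sum((mat - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf
  # Satterthwaite df for the absolute-agreement CI
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, lower = lower, upper = upper,
       MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Agreement statistics between two measurement vectors
#'
#' The full method-comparison battery for one segment and motion pair:
#' mean difference (model minus reference) and its sample SD, MAE
#' \eqn{\frac{1}{m}\sum|obs_i - pred_i|}, RMSE
#' \eqn{\sqrt{\frac{1}{m}\sum(obs_i - pred_i)^2}}, Bland-Altman 95% limits of
#' agreement (mean difference +/- 1.96 SD), ICC(2,1) (two-way random effects,
#' absolute agreement, single measures) with its F-based 95% CI, Pearson r
#' with Fisher-z 95% CI, a two-sided paired t-test, and seeded nonparametric
#' bootstrap percentile 95% CIs for MAE and RMSE.
#'
#' @param modelVals,refVals equal-length numeric vectors (n >= 3)
#' @param nBoot bootstrap resamples for the MAE/RMSE CIs (default 2000)
#' @param seed bootstrap seed
#' @return one-row \code{data.frame} with columns \code{n, icc, icc_lo,
#'   icc_hi, r, r_lo, r_hi, mean_diff, sd_diff, rmse, rmse_lo, rmse_hi, mae,
#'   mae_lo, mae_hi, loa_low, loa_high, t_stat, p_value, flag}
#' @examples
#' agreementStats(c(2, 2, 5), c(1, 2, 3), nBoot = 200)
#' @export
agreementStats <- function(modelVals, refVals, nBoot = 2000, seed = 1) {
  cmAssert(length(modelVals) == length(refVals), "LengthMismatch",
           "model and reference vectors must have equal length")
  n <- length(modelVals)
  cmAssert(n >= 3, "LengthMismatch", "need at least 3 paired values")
  d <- modelVals - refVals
  meanDiff <- mean(d)
  sdDiff <- stats::sd(d)
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  loa <- meanDiff + c(-1, 1) * 1.96 * sdDiff

  flag <- "ok"
  if (all(d == 0)) flag <- "perfect-agreement"
  zeroVar <- stats::sd(modelVals) == 0 || stats::sd(refVals) == 0
  if (zeroVar) flag <- "zero-variance"

  if (zeroVar) {
    icc <- c(icc = NA_real_, lower = NA_real_, upper = NA_real_)
    r <- rlo <- rhi <- NA_real_
  } else {
    ic <- iccAbsoluteSingle(cbind(modelVals, refVals))
    icc <- c(icc = ic$icc, lower = ic$lower, upper = ic$upper)
    ct <- stats::cor.test(modelVals, refVals, conf.level = 0.95)
    r <- unname(ct$estimate)
    if (is.null(ct$conf.int)) {        # Fisher-z CI needs n > 3
      rlo <- NA_real_; rhi <- NA_real_
    } else {
      rlo <- ct$conf.int[1]; rhi <- ct$conf.int[2]
    }
  }
  if (sdDiff == 0) {
    tStat <- 0; pVal <- 1
  } else {
    tt <- stats::t.test(modelVals, refVals, paired = TRUE)
    tStat <- unname(tt$statistic); pVal <- tt$p.value
  }
  set.seed(seed)
  bootMae <- bootRmse <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    db <- d[sample.int(n, n, replace = TRUE)]
    bootMae[b] <- mean(abs(db))
    bootRmse[b] <- sqrt(mean(db^2))
  }
  maeCi <- stats::quantile(bootMae, c(0.025, 0.975), names = FALSE)
  rmseCi <- stats::quantile(bootRmse, c(0.025, 0.975), names = FALSE)

  data.frame(n = n, icc = unname(icc[1]), icc_lo = unname(icc[2]),
             icc_hi = unname(icc[3]), r = r, r_lo = rlo, r_hi = rhi,
             mean_diff = meanDiff, sd_diff = sdDiff,
             rmse = rmse, rmse_lo = rmseCi[1], rmse_hi = rmseCi[2],
             mae = mae, mae_lo = maeCi[1], mae_hi = maeCi[2],
             loa_low = loa[1], loa_high = loa[2],
             t_stat = tStat, p_value = pVal, flag = flag,
             stringsAsFactors = FALSE)
}

#' Agreement report over segments and motion pairs
#'
#' Applies \code{\link{agreementStats}} per segment and motion pair to two
#' aligned long motion tables (as from \code{\link{motionTable}}).
#'
#' @param modelTab,refTab motion tables with matching \code{case_id} and
#'   \code{segment} rows
#' @param nBoot,seed passed to \code{\link{agreementStats}}
#' @return \code{data.frame} with columns \code{pair}, \code{segment} and the
#'   \code{agreementStats} battery
#' @export
agreementReport <- function(modelTab, refTab, nBoot = 2000, seed = 1) {
  key <- function(t) paste(t$case_id, t$segment)
  if (!setequal(key(modelTab), key(refTab)))
    cmStop("CaseMismatch", "model and reference tables cover different case/segment rows")
  refTab <- refTab[match(key(modelTab), key(refTab)), ]
  cols <- c(`F/E` = "sirm_FE_deg", `F/N` = "sirm_FN_deg", `N/E` = "sirm_NE_deg")
  rows <- list()
  for (p in names(cols)) for (s in segmentLabels()) {
    i <- modelTab$segment == s
    st <- agreementStats(modelTab[[cols[[p]]]][i], refTab[[cols[[p]]]][i],
                         nBoot = nBoot, seed = seed)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(pair = p, segment = s, stringsAsFactors = FALSE), st)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired MAE comparison of each rater against the model
#'
#' For each rater i, the baseline is the mean of the other raters' values;
#' the rater's absolute error |rater_i - baseline| is compared with the
#' model's absolute error |model - baseline| by a two-sided paired t-test.
#'
#' @param raterVals list of (at least 2) equal-length numeric vectors
#' @param modelVals numeric vector of the same length
#' @return \code{data.frame}: \code{rater}, \code{mae_rater},
#'   \code{mae_model}, \code{t_stat}, \code{p_value}, \code{flag}
#' @export
pairedMaeComparison <- function(raterVals, modelVals) {
  nr <- length(raterVals)
  stopifnot(nr >= 2L)
  lens <- c(vapply(raterVals, length, integer(1)), length(modelVals))
  cmAssert(length(unique(lens)) == 1L, "LengthMismatch",
           "all vectors must have equal length")
  rows <- lapply(seq_len(nr), function(i) {
    baseline <- Reduce(`+`, raterVals[-i]) / (nr - 1)
    eR <- abs(raterVals[[i]] - baseline)
    eM <- abs(modelVals - baseline)
    dd <- eR - eM
    flag <- "ok"
    if (stats::sd(dd) == 0) {
      flag <- "DegeneratePairs"
      tStat <- 0
      pVal <- if (mean(dd) == 0) 1 else 0
    } else {
      tt <- stats::t.test(eR, eM, paired = TRUE)
      tStat <- unname(tt$statistic); pVal <- tt$p.value
    }
    data.frame(rater = paste0("R", i), mae_rater = mean(eR),
               mae_model = mean(eM), t_stat = tStat, p_value = pVal,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RMSE from summary statistics
#'
#' Reconstructs the RMSE from the mean difference, the sample SD of the
#' differences and the sample size via the identity
#' \eqn{RMSE^2 = \bar d^2 + s^2 (n-1)/n}, which follows from the definitions
#' of the sample mean and (n-1)-denominator SD. Useful for checking the
#' internal consistency of reported agreement tables.
#'
#' @param meanDiff mean of the paired differences
#' @param sdDiff sample SD (n-1 denominator) of the paired differences
#' @param n number of pairs (>= 2)
#' @return the RMSE
#' @examples
#' summaryRmse(-0.52, 1.57, 100)   # 1.6464
#' @export
summaryRmse <- function(meanDiff, sdDiff, n) {
  cmAssert(length(n) == 1L && is.finite(n) && n >= 2, "InvalidN",
           "n must be a single integer >= 2")
  stopifnot(sdDiff >= 0)
  sqrt(meanDiff^2 + sdDiff^2 * (n - 1) / n)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against pair means with the mean difference
#' and the 95% limits of agreement.
#'
#' @param modelVals,refVals equal-length numeric vectors
#' @param main plot title
#' @param path optional PNG output path; when given the plot is written there
#' @return (invisibly) list with \code{mean_diff}, \code{loa_low},
#'   \code{loa_high}
#' @export
blandAltmanPlot <- function(modelVals, refVals, main = "Bland-Altman",
                            path = NULL) {
  d <- modelVals - refVals
  avg <- (modelVals + refVals) / 2
  md <- mean(d); s <- stats::sd(d)
  loa <- md + c(-1, 1) * 1.96 * s
  draw <- function() {
    graphics::plot(avg, d, pch = 19, col = "grey30",
                   xlab = "Mean of model and reference (deg)",
                   ylab = "Difference model - reference (deg)", main = main)
    graphics::abline(h = md, col = "blue", lwd = 2)
    graphics::abline(h = loa, col = "red", lty = 2, lwd = 2)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(list(mean_diff = md, loa_low = loa[1], loa_high = loa[2]))
}
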
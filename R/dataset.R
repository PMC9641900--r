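#' Generate a synthetic dataset on disk
#'
#' Samples per-case motion profiles and per-view global poses, builds the
#' three-view landmark sets, optionally renders PNG images, and writes the
#' standard landmark CSV plus a JSON manifest carrying the full configuration
#' echo, the split assignment, and each case's ground-truth motion profile.
#' The split is disjoint and seed-stable.
#'
#' @param outDir output directory (created if absent)
#' @param nCases number of cases
#' @param split named fractions summing to 1, e.g.
#'   \code{c(train = 0.8, val = 0.2)}
#' @param seed master RNG seed; every random draw derives from it
#' @param template \code{\link{spineTemplate}}
#' @param params \code{\link{sirmPopulationParams}}-style distribution table
#' @param noise \code{\link{noiseModel}} applied to the written annotations
#'   (the manifest always keeps the exact ground truth; default no noise)
#' @param spacing pixel spacing mm/px of the generated views
#' @param imageSize integer (width, height) px
#' @param render write PNG renders of every view
#' @param renderCfg \code{\link{renderConfig}}
#' @param poseSd SDs of the random global pose: rotation deg, tx mm, ty mm
#' @return (invisibly) the manifest as a list
#' @export
generateDataset <- function(outDir, nCases, split = c(train = 0.8, val = 0.2),
                            seed = 1, template = spineTemplate(),
                            params = sirmPopulationParams(),
                            noise = noiseModel(sigmaMm = 0),
                            spacing = 1.25, imageSize = c(128L, 128L),
                            render = TRUE, renderCfg = renderConfig(),
                            poseSd = c(4, 3, 3)) {
  if (abs(sum(split) - 1) > 1e-9 || any(split < 0) || is.null(names(split)))
    cmStop("InvalidSplit", "split fractions must be named, non-negative and sum to 1")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (render) dir.create(file.path(outDir, "images"), showWarnings = FALSE)

  ids <- if (nCases > 0) sprintf("case%04d", seq_len(nCases)) else character()
  # seed-stable disjoint split
  set.seed(deriveSeed(seed, 101L))
  perm <- sample(nCases)
  counts <- diff(round(cumsum(c(0, split)) * nCases))
  assign <- rep(names(split), counts)
  splitOf <- character(nCases)
  splitOf[perm] <- assign

  cases <- vector("list", nCases)
  caseMeta <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    profile <- sampleMotionProfile(params, seed = deriveSeed(seed, 1000L + i))
    # bounded, seed-stable pose retry: a rare extreme pose draw can push the
    # spine outside a small frame; the motion profile is never resampled
    ct <- NULL
    for (try in 0:19) {
      set.seed(deriveSeed(seed, 2000L + 23L * try + i))
      poses <- lapply(viewLabels(), function(v)
        c(stats::rnorm(1, 0, poseSd[1]), stats::rnorm(1, 0, poseSd[2]),
          stats::rnorm(1, 0, poseSd[3])))
      names(poses) <- viewLabels()
      ct <- tryCatch(buildCase(template, profile, ids[i], poses = poses,
                               spacing = spacing, imageSize = imageSize),
                     OutOfFrame = function(e) NULL)
      if (!is.null(ct)) break
    }
    if (is.null(ct))
      cmStop("OutOfFrame",
             sprintf("case %s does not fit the requested frame", ids[i]))
    if (noise$sigmaMm > 0) {
      set.seed(deriveSeed(seed, 3000L + i))
      views <- lapply(viewLabels(), function(v)
        perturbAnnotations(getView(ct, v), noiseModel(noise$sigmaMm)))
      ct <- caseTriple(ids[i], views[[1]], views[[2]], views[[3]])
    }
    cases[[i]] <- ct
    if (render) {
      for (v in viewLabels()) {
        rv <- renderView(getView(ct, v),
                         modifyList(renderCfg,
                                    list(seed = deriveSeed(seed, 4000L + 3L * i +
                                                             match(v, viewLabels())))))
        writeImagePNG(rv$image, file.path(outDir, "images",
                                          sprintf("%s_%s.png", ids[i], v)))
      }
    }
    caseMeta[[i]] <- list(case_id = ids[i], split = splitOf[i],
                          fn = as.list(profile$fn), ne = as.list(profile$ne),
                          fe = as.list(profile$fe),
                          poses = lapply(poses, as.numeric))
  }
  if (nCases > 0) {
    names(cases) <- ids
    writeLandmarkCSV(cases, file.path(outDir, "landmarks.csv"))
  }
  manifest <- list(
    seed = seed, n_cases = nCases, split = as.list(split),
    pixel_spacing_mm = spacing,
    image_size_px = as.integer(imageSize), rendered = render,
    template = unclass(template), noise_sigma_mm = noise$sigmaMm,
    pose_sd = as.numeric(poseSd),
    render_config = unclass(renderCfg)[c("blurSigmaPx", "noiseSd",
                                         "boneIntensity", "backgroundRange",
                                         "c2HeightMm")],
    params = params, cases = caseMeta)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(manifest)
}

#' Read a generated dataset's manifest
#'
#' @param dir dataset directory
#' @return manifest list
#' @export
readManifest <- function(dir)
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)

#' Load detector samples from a generated dataset
#'
#' @param dir dataset directory written by \code{\link{generateDataset}}
#'   with \code{render = TRUE}
#' @param split which split to load (NULL for all)
#' @return list of samples, each with \code{image}, \code{points} (22 x 2 px),
#'   \code{spacing}, \code{caseId}, \code{view}
#' @export
loadDetectorSamples <- function(dir, split = NULL) {
  man <- readManifest(dir)
  cases <- readLandmarkCSV(file.path(dir, "landmarks.csv"))
  keep <- man$cases$case_id
  if (!is.null(split)) keep <- keep[man$cases$split == split]
  out <- list()
  for (cid in keep) {
    for (v in viewLabels()) {
      img <- readImagePNG(file.path(dir, "images", sprintf("%s_%s.png", cid, v)))
      ann <- getView(cases[[cid]], v)
      out[[sprintf("%s_%s", cid, v)]] <-
        list(image = img, points = ann@points, spacing = ann@pixelSpacing,
             caseId = cid, view = v)
    }
  }
  out
}

#' Ground-truth SIRM table from a manifest
#'
#' @param manifest manifest list (or dataset directory)
#' @return data.frame \code{case_id, segment, sirm_FE_deg, sirm_FN_deg,
#'   sirm_NE_deg}
#' @export
manifestSirmTable <- function(manifest) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  cm <- manifest$cases
  do.call(rbind, lapply(seq_along(cm$case_id), function(i) {
    data.frame(case_id = cm$case_id[i], segment = segmentLabels(),
               sirm_FE_deg = as.numeric(unlist(cm$fe[i, ])),
               sirm_FN_deg = as.numeric(unlist(cm$fn[i, ])),
               sirm_NE_deg = as.numeric(unlist(cm$ne[i, ])),
               stringsAsFactors = FALSE)
  }))
}
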
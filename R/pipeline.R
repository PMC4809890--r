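#' @include classifier.R morphology.R metrics.R
NULL

## ---------------------------------------------------------------------------
## The five-phase pipeline: (1) atlas-prior classification, (2) marker
## watershed adaptation of the CSF prior, (3) reconstruction filtering of
## bright WM, (4) reclassification with the adapted template, (5) restoration
## of isolated CSF/WM pockets. Identical processing for every image; no
## per-subject parameters.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Defaults are the standard settings used for all images: CSF marker from
#' the phase-1 CSF probability at 0.9 with components under 500 mm^3
#' removed, cortical GM marker at 0.7, gradient scales 0.25 mm and the
#' minimum voxel dimension, face connectivity.
#'
#' @slot csfMarkerThreshold CSF posterior threshold (default 0.9).
#' @slot csfMarkerMinVolumeMm3 minimum CSF marker component volume
#'   (default 500 mm^3).
#' @slot gmMarkerThreshold cortical GM posterior threshold (default 0.7).
#' @slot gradientSigmasMm gradient scales in mm; NA means
#'   `c(0.25, min(spacing))` resolved at run time.
#' @slot connectivity 6, 18 or 26 (default 6).
#' @slot classifier a [ClassifierConfig-class].
#' @export
setClass("PipelineConfig",
  representation(csfMarkerThreshold = "numeric",
                 csfMarkerMinVolumeMm3 = "numeric",
                 gmMarkerThreshold = "numeric",
                 gradientSigmasMm = "numeric",
                 connectivity = "integer",
                 classifier = "ClassifierConfig"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@csfMarkerThreshold <= 0 || object@csfMarkerThreshold >= 1)
    msg <- c(msg, "csfMarkerThreshold must be in (0, 1)")
  if (object@gmMarkerThreshold <= 0 || object@gmMarkerThreshold >= 1)
    msg <- c(msg, "gmMarkerThreshold must be in (0, 1)")
  if (object@csfMarkerMinVolumeMm3 <= 0)
    msg <- c(msg, "csfMarkerMinVolumeMm3 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a PipelineConfig
#'
#' @param csfMarkerThreshold,csfMarkerMinVolumeMm3,gmMarkerThreshold,gradientSigmasMm,connectivity,classifier
#'   see [PipelineConfig-class].
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(csfMarkerThreshold = 0.9,
                           csfMarkerMinVolumeMm3 = 500,
                           gmMarkerThreshold = 0.7,
                           gradientSigmasMm = NA_real_,
                           connectivity = 6L,
                           classifier = classifierConfig()) {
  new("PipelineConfig", csfMarkerThreshold = csfMarkerThreshold,
      csfMarkerMinVolumeMm3 = csfMarkerMinVolumeMm3,
      gmMarkerThreshold = gmMarkerThreshold,
      gradientSigmasMm = gradientSigmasMm,
      connectivity = as.integer(connectivity), classifier = classifier)
}

setMethod("show", "PipelineConfig", function(object) {
  sig <- if (anyNA(object@gradientSigmasMm)) "0.25, min(spacing)"
         else paste(object@gradientSigmasMm, collapse = ", ")
  cat(sprintf(paste0("PipelineConfig: CSF marker >= %.2g (components >= %g mm^3), ",
                     "GM marker >= %.2g, gradient sigmas {%s} mm, ",
                     "%d-connectivity\n"),
              object@csfMarkerThreshold, object@csfMarkerMinVolumeMm3,
              object@gmMarkerThreshold, sig, object@connectivity))
})

.resolveSigmas <- function(cfg, spacing) {
  if (anyNA(cfg@gradientSigmasMm)) c(0.25, min(spacing))
  else cfg@gradientSigmasMm
}

#' Build the watershed marker set from the phase-1 classification
#'
#' CSF seed: phase-1 CSF posterior at or above the threshold with
#' components smaller than the minimum physical volume removed. Cortical
#' GM seed: GM posterior at or above its threshold. Background seed: all
#' voxels outside the brain mask. Overlaps are resolved CSF > GM >
#' background (counts logged via message when `verbose`).
#'
#' @param p1 phase-1 [ClassifierResult-class].
#' @param brainMask binary brain mask.
#' @param cfg a [PipelineConfig-class].
#' @param verbose log overlap counts.
#' @return [LabelVolume-class] marker set (1 csf_seed, 2 gm_seed,
#'   3 background_seed; 0 unlabeled).
#' @export
buildMarkers <- function(p1, brainMask, cfg = pipelineConfig(),
                         verbose = FALSE) {
  post <- p1@posteriors
  sp <- voxelSpacing(post)
  msk <- .binData(brainMask)
  csfP <- classMap(post, "csf")
  gmP <- classMap(post, "cortical_gm")
  csfSeed <- csfP >= cfg@csfMarkerThreshold & msk
  csfSeed <- filterSmallComponents(csfSeed, cfg@csfMarkerMinVolumeMm3,
                                   cfg@connectivity, spacing = sp)
  if (!any(csfSeed))
    stop("empty CSF seed after thresholding at ", cfg@csfMarkerThreshold,
         " and removing components under ", cfg@csfMarkerMinVolumeMm3,
         " mm^3; review the marker thresholds (the pipeline cannot adapt",
         " without a CSF seed)")
  gmSeed <- gmP >= cfg@gmMarkerThreshold & msk
  overlap <- sum(gmSeed & csfSeed)
  .msg(verbose, sprintf("markers: %d voxels in both CSF and GM seeds resolved to CSF",
                        overlap))
  gmSeed <- gmSeed & !csfSeed
  bg <- !msk
  markers <- array(0L, dim(csfP))
  markers[bg] <- 3L
  markers[gmSeed] <- 2L
  markers[csfSeed] <- 1L
  LabelVolume(markers, spacing = sp, codeTable = markerCodeTable(),
              affine = voxelAffine(post))
}

#' Phase 2: watershed segmentation of the CSF
#'
#' Builds the multiscale-gradient control image from the T2 image and
#' floods it from the marker set; returns the CSF-labeled region
#' intersected with the brain mask.
#'
#' @param t2 [ScalarVolume-class].
#' @param markers marker [LabelVolume-class] from [buildMarkers()].
#' @param brainMask binary brain mask.
#' @param cfg a [PipelineConfig-class].
#' @return list with `csf` (binary [LabelVolume-class]), `watershed` (full
#'   label partition) and `control` ([ScalarVolume-class]).
#' @export
segmentCsfWatershed <- function(t2, markers, brainMask,
                                cfg = pipelineConfig()) {
  sig <- .resolveSigmas(cfg, voxelSpacing(t2))
  control <- multiscaleGradient(t2, sig)
  ws <- watershedFromMarkers(control, markers, cfg@connectivity)
  msk <- .binData(brainMask)
  csf <- voxelData(ws) == 1L & msk
  list(csf = LabelVolume(array(as.integer(csf), dim(csf)),
                         spacing = voxelSpacing(t2),
                         codeTable = c("1" = "csf"),
                         affine = voxelAffine(t2)),
       watershed = ws, control = control)
}

#' Adapt the template CSF prior with the watershed segmentation
#'
#' The CSF prior becomes the voxelwise maximum of the watershed CSF
#' segmentation (as 0/1) and the original CSF prior; where the per-voxel
#' class sum then exceeds 1, the non-CSF classes are rescaled
#' proportionally so the sum is 1. The CSF prior never decreases.
#'
#' @param priors [ProbabilityMaps-class].
#' @param csfWatershed binary CSF segmentation from phase 2.
#' @return adapted [ProbabilityMaps-class].
#' @export
adaptTemplate <- function(priors, csfWatershed) {
  arr <- voxelData(priors)
  cls <- classNames(priors)
  ci <- match("csf", cls)
  if (is.na(ci)) stop("priors carry no csf class")
  ws <- .binData(csfWatershed)
  csfOld <- arr[, , , ci]
  csfNew <- pmax(csfOld, as.numeric(ws))
  others <- .probSums(arr) - csfOld
  total <- csfNew + others
  over <- total > 1 & others > 0
  sc <- ifelse(over, (1 - csfNew) / others, 1)
  sc[sc < 0] <- 0
  out <- arr
  for (k in seq_along(cls)) {
    if (k == ci) out[, , , k] <- csfNew
    else out[, , , k] <- arr[, , , k] * sc
  }
  ProbabilityMaps(out, classes = cls, spacing = voxelSpacing(priors),
                  affine = voxelAffine(priors))
}

#' Phase 3: reconstruction filtering of bright white matter
#'
#' Marker image: T2 intensities on the phase-1 hard-label CSF voxels, the
#' global in-mask minimum elsewhere; mask image: the T2 image. The
#' grayscale reconstruction by dilation reduces isolated regions brighter
#' than their surroundings (high-signal white matter) to the surrounding
#' level while leaving intensities on seed-connected CSF and class edges
#' containing the seed unchanged. Intensities never increase.
#'
#' @param t2 [ScalarVolume-class].
#' @param p1 phase-1 [ClassifierResult-class].
#' @param brainMask binary brain mask.
#' @param cfg a [PipelineConfig-class].
#' @return filtered [ScalarVolume-class].
#' @export
filterBrightWm <- function(t2, p1, brainMask, cfg = pipelineConfig()) {
  lab1 <- hardLabels(p1@posteriors)
  seed <- voxelData(lab1) == tissueCode("csf")
  if (!any(seed)) {
    warning("phase-1 CSF detection is empty; returning the T2 image unfiltered")
    return(t2)
  }
  msk <- .binData(brainMask)
  tv <- voxelData(t2)
  lo <- min(tv[msk])
  marker <- array(lo, dim(tv))
  marker[seed] <- tv[seed]
  marker <- pmin(marker, tv)   # outside the mask T2 may fall below lo
  reconstructByDilation(ScalarVolume(marker, spacing = voxelSpacing(t2),
                                     affine = voxelAffine(t2)),
                        t2, cfg@connectivity)
}

#' Phase 5: restore isolated CSF and WM pockets
#'
#' Voxels labeled cortical GM in phase 4 but CSF in phase 1, forming
#' connected components that do not touch the phase-4 CSF segmentation,
#' are relabeled CSF (these are the isolated pockets whose bright signal
#' phase 3 flattened). The symmetric rule restores WM pockets (cortical GM
#' in phase 4, WM in phase 1, not touching phase-4 WM). All other labels
#' pass through.
#'
#' @param p1,p4 phase-1 and phase-4 [ClassifierResult-class] on one grid.
#' @param labels [LabelVolume-class] candidate segmentation (phase-4 hard
#'   labels).
#' @param cfg a [PipelineConfig-class].
#' @return list with `labels` (final [LabelVolume-class]) and
#'   `restored` (list of binary masks `csf` and `wm`).
#' @export
restorePockets <- function(p1, p4, labels, cfg = pipelineConfig()) {
  lab1 <- voxelData(hardLabels(p1@posteriors))
  lab4 <- voxelData(labels)
  out <- lab4
  csf <- tissueCode("csf"); gm <- tissueCode("cortical_gm")
  wm <- tissueCode("white_matter")
  offs <- connectivityOffsets(cfg@connectivity)

  restoreOne <- function(targetCode) {
    diffMask <- lab4 == gm & lab1 == targetCode
    restored <- array(FALSE, dim(lab4))
    if (!any(diffMask)) return(restored)
    cc <- .as3d(connectedComponents(diffMask, cfg@connectivity))
    targetSeg <- lab4 == targetCode
    ## components adjacent to the phase-4 segmentation of the target class
    ## are boundary disagreements, not pockets
    adj <- array(FALSE, dim(lab4))
    for (r in seq_len(nrow(offs)))
      adj <- adj | .shiftArray(targetSeg, offs[r, ], FALSE)
    touching <- unique(cc[diffMask & adj])
    ids <- setdiff(unique(cc[diffMask]), c(0L, touching))
    if (length(ids)) restored[cc %in% ids] <- TRUE
    restored
  }

  resCsf <- restoreOne(csf)
  out[resCsf] <- csf
  resWm <- restoreOne(wm)
  out[resWm] <- wm
  list(labels = LabelVolume(out, spacing = voxelSpacing(labels),
                            codeTable = codeTable(labels),
                            affine = voxelAffine(labels)),
       restored = list(csf = resCsf, wm = resWm))
}

#' Result of a full pipeline run
#'
#' Carries every per-phase artifact for audit: phase-1 result, marker set,
#' control image, watershed CSF, adapted priors, filtered image, phase-4
#' result, restoration masks and final labels.
#'
#' @slot finalLabels [LabelVolume-class] eight-class segmentation covering
#'   the brain mask exactly.
#' @slot phase1,phase4 [ClassifierResult-class].
#' @slot markers [LabelVolume-class].
#' @slot control [ScalarVolume-class] watershed control image.
#' @slot csfWatershed [LabelVolume-class] binary phase-2 CSF.
#' @slot adaptedPriors [ProbabilityMaps-class].
#' @slot filteredT2 [ScalarVolume-class] phase-3 output.
#' @slot restored list of binary restoration masks (csf, wm).
#' @slot config [PipelineConfig-class].
#' @slot log named list of per-phase class voxel counts.
#' @export
setClass("MantisResult",
  representation(finalLabels = "LabelVolume", phase1 = "ClassifierResult",
                 phase4 = "ClassifierResult", markers = "LabelVolume",
                 control = "ScalarVolume", csfWatershed = "LabelVolume",
                 adaptedPriors = "ProbabilityMaps",
                 filteredT2 = "ScalarVolume", restored = "list",
                 config = "PipelineConfig", log = "list"))

setMethod("show", "MantisResult", function(object) {
  cat("MantisResult\n"); .showGeom(object@finalLabels)
  counts <- object@log$finalCounts
  if (!is.null(counts)) {
    cat("  final class voxel counts:\n")
    for (nm in names(counts)) cat(sprintf("    %-14s %d\n", nm, counts[[nm]]))
  }
})

.classCounts <- function(lab) {
  tab <- tissueClassTable()
  out <- lapply(as.integer(names(tab)), function(cd) sum(lab == cd))
  names(out) <- unname(tab)
  out
}

#' Run the full five-phase segmentation pipeline
#'
#' Executes phases 1-5 with no per-subject parameter changes and returns
#' every phase artifact. Deterministic for a given configuration: running
#' twice produces bit-identical final labels.
#'
#' @param t2 brain-extracted T2-weighted [ScalarVolume-class].
#' @param brainMask binary brain mask on the same grid.
#' @param priors [ProbabilityMaps-class] over the eight tissue classes, on
#'   the same grid (use [resampleTo()] first if needed).
#' @param cfg a [PipelineConfig-class].
#' @param phase1Posteriors optional externally computed phase-1
#'   [ProbabilityMaps-class] (bypasses the internal classifier for
#'   phase 1).
#' @param verbose log phase progress.
#' @return a [MantisResult-class].
#' @export
runPipeline <- function(t2, brainMask, priors, cfg = pipelineConfig(),
                        phase1Posteriors = NULL, verbose = FALSE) {
  phase <- "phase 1 (initial classification)"
  timings <- list()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res <- tryCatch({
    .msg(verbose, phase)
    t0 <- tic()
    p1 <- if (is.null(phase1Posteriors))
      fitTissueClassifier(t2, brainMask, priors, cfg@classifier)
    else classifierResultFromPosteriors(phase1Posteriors, brainMask)
    timings$phase1 <- lap(t0)

    phase <- "phase 2 (watershed ventricle segmentation)"
    .msg(verbose, phase)
    t0 <- tic()
    markers <- buildMarkers(p1, brainMask, cfg, verbose = verbose)
    ws <- segmentCsfWatershed(t2, markers, brainMask, cfg)
    adapted <- adaptTemplate(priors, ws$csf)
    timings$phase2 <- lap(t0)

    phase <- "phase 3 (reconstruction filtering)"
    .msg(verbose, phase)
    t0 <- tic()
    filtered <- filterBrightWm(t2, p1, brainMask, cfg)
    timings$phase3 <- lap(t0)

    phase <- "phase 4 (reclassification with adapted template)"
    .msg(verbose, phase)
    t0 <- tic()
    p4 <- fitTissueClassifier(filtered, brainMask, adapted, cfg@classifier)
    timings$phase4 <- lap(t0)

    phase <- "phase 5 (pocket restoration)"
    .msg(verbose, phase)
    t0 <- tic()
    lab4 <- hardLabels(p4@posteriors)
    rp <- restorePockets(p1, p4, lab4, cfg)
    timings$phase5 <- lap(t0)

    lab1 <- voxelData(hardLabels(p1@posteriors))
    lg <- list(phase1Counts = .classCounts(lab1),
               phase4Counts = .classCounts(voxelData(lab4)),
               finalCounts = .classCounts(voxelData(rp$labels)),
               restoredCsf = sum(rp$restored$csf),
               restoredWm = sum(rp$restored$wm),
               timingsSec = timings)

    new("MantisResult", finalLabels = rp$labels, phase1 = p1, phase4 = p4,
        markers = markers, control = ws$control, csfWatershed = ws$csf,
        adaptedPriors = adapted, filteredT2 = filtered,
        restored = rp$restored, config = cfg, log = lg)
  }, error = function(e) {
    stop("pipeline failed in ", phase, ": ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' Write all pipeline artifacts to a directory
#'
#' @param result a [MantisResult-class].
#' @param dir output directory; final labels and per-class posteriors at
#'   the top level (c1..c8, mirroring the SPM naming convention), phase
#'   artifacts under `phases/`, and a JSON run manifest.
#' @param t2 optional input [ScalarVolume-class] to copy alongside.
#' @return `dir`, invisibly.
#' @export
writeMantisResult <- function(result, dir, t2 = NULL) {
  dir.create(file.path(dir, "phases"), recursive = TRUE, showWarnings = FALSE)
  writeVolume(result@finalLabels, file.path(dir, "labels.nii.gz"))
  post <- result@phase4@posteriors
  arr <- voxelData(post)
  for (i in seq_len(dim(arr)[4L]))
    writeVolume(ScalarVolume(arr[, , , i], spacing = voxelSpacing(post),
                             affine = voxelAffine(post)),
                file.path(dir, sprintf("c%d_%s.nii.gz", i, classNames(post)[i])))
  ph <- file.path(dir, "phases")
  writeVolume(hardLabels(result@phase1@posteriors),
              file.path(ph, "phase1_labels.nii.gz"))
  writeVolume(result@markers, file.path(ph, "phase2_markers.nii.gz"))
  writeVolume(result@control, file.path(ph, "phase2_control.nii.gz"))
  writeVolume(result@csfWatershed, file.path(ph, "phase2_csf.nii.gz"))
  writeVolume(result@filteredT2, file.path(ph, "phase3_filtered.nii.gz"))
  writeVolume(result@phase1@biasField, file.path(ph, "phase1_bias.nii.gz"))
  writeVolume(result@phase4@biasField, file.path(ph, "phase4_bias.nii.gz"))
  ## mixture state and likelihood trace, one JSON per classification phase
  for (nm in c("phase1", "phase4")) {
    cr <- slot(result, nm)
    if (length(cr@mixture))
      jsonlite::write_json(
        list(weights = cr@mixture$weights, means = cr@mixture$means,
             variances = cr@mixture$variances, classes = cr@mixture$classes,
             logLik = cr@logLik),
        file.path(ph, paste0(nm, "_mixture.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(t2)) writeVolume(t2, file.path(dir, "t2.nii.gz"))
  cfg <- result@config
  manifest <- list(
    config = list(csfMarkerThreshold = cfg@csfMarkerThreshold,
                  csfMarkerMinVolumeMm3 = cfg@csfMarkerMinVolumeMm3,
                  gmMarkerThreshold = cfg@gmMarkerThreshold,
                  gradientSigmasMm = cfg@gradientSigmasMm,
                  connectivity = cfg@connectivity,
                  gaussiansPerClass = cfg@classifier@gaussiansPerClass,
                  biasOrder = cfg@classifier@biasOrder,
                  biasRegularization = cfg@classifier@biasRegularization,
                  seed = cfg@classifier@seed),
    log = result@log,
    package = as.character(utils::packageVersion("mantis")))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
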
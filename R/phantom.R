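#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Deterministic synthetic neonatal T2 phantom: nested-ellipsoid anatomy
## (peripheral CSF rim, cortical GM shell, WM interior, central ventricular
## CSF, deep GM, inferior cerebellum/brainstem, small hippocampus/amygdala
## blobs), T2-like intensity ordering CSF > WM > GM, configurable ventricle
## enlargement relative to the priors, planted bright-WM lesions and
## isolated CSF pockets, smooth multiplicative bias and additive Gaussian
## noise. Everything is reproducible from the seed.
## ---------------------------------------------------------------------------

.defaultIntensities <- function() {
  c(cortical_gm = 100, white_matter = 150, deep_gm = 115, csf = 250,
    brainstem = 130, cerebellum = 108, hippocampus = 92, amygdala = 85)
}

#' Phantom specification
#'
#' The geometry is defined in mm at a 64 mm reference field of view and
#' scaled with the grid, so anisotropic presets (e.g. 0.35 x 0.35 x 2 mm)
#' produce a proportionate brain. `ventricleScale` is a volume enlargement
#' factor (radii scale with its cube root) applied to the ground-truth
#' ventricle while the priors keep scale 1, emulating the enlarged,
#' distorted ventricles of preterm brain injury.
#'
#' @slot dims grid size (default 64^3).
#' @slot spacing mm per axis (default 1 mm isotropic).
#' @slot intensityMeans named per-class mean intensities; must satisfy
#'   CSF > WM > cortical GM.
#' @slot noiseSd additive Gaussian noise SD (default 2).
#' @slot ventricleScale volume enlargement factor >= 1 (default 1).
#' @slot nLesions number of bright WM lesions (default 0).
#' @slot lesionIntensity lesion mean, strictly between WM and CSF means.
#' @slot lesionRadiusMm lesion radius (default 2.5 mm).
#' @slot nPockets number of isolated CSF pockets (default 0).
#' @slot pocketVolumeMm3 pocket volume (default 200 mm^3).
#' @slot biasAmplitude multiplicative bias amplitude as a fraction
#'   (default 0.1; 0 disables).
#' @slot biasSmoothnessMm smoothness of the bias field (default 60 mm,
#'   matching the classifier's stated bias FWHM scale).
#' @slot priorBlurMm Gaussian blur of the one-hot priors (default 1 mm).
#' @slot seed RNG seed fixing all randomness.
#' @export
setClass("PhantomSpec",
  representation(dims = "integer", spacing = "numeric",
                 intensityMeans = "numeric", noiseSd = "numeric",
                 ventricleScale = "numeric", nLesions = "integer",
                 lesionIntensity = "numeric", lesionRadiusMm = "numeric",
                 nPockets = "integer", pocketVolumeMm3 = "numeric",
                 biasAmplitude = "numeric", biasSmoothnessMm = "numeric",
                 priorBlurMm = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  im <- object@intensityMeans
  need <- names(.defaultIntensities())
  if (!all(need %in% names(im))) msg <- c(msg, "intensityMeans must name all 8 classes")
  else {
    if (!(im["csf"] > im["white_matter"] && im["white_matter"] > im["cortical_gm"]))
      msg <- c(msg, "intensity ordering CSF > WM > GM violated")
    if (object@nLesions > 0L &&
        !(object@lesionIntensity > im["white_matter"] &&
          object@lesionIntensity < im["csf"]))
      msg <- c(msg, "lesion intensity must lie strictly between WM and CSF means")
  }
  if (object@ventricleScale < 1) msg <- c(msg, "ventricleScale must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@priorBlurMm < 0) msg <- c(msg, "priorBlurMm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a PhantomSpec
#'
#' @param dims,spacing,intensityMeans,noiseSd,ventricleScale,nLesions,lesionIntensity,lesionRadiusMm,nPockets,pocketVolumeMm3,biasAmplitude,biasSmoothnessMm,priorBlurMm,seed
#'   see [PhantomSpec-class].
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dims = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                        intensityMeans = .defaultIntensities(),
                        noiseSd = 2, ventricleScale = 1, nLesions = 0L,
                        lesionIntensity = 200, lesionRadiusMm = 2.5,
                        nPockets = 0L, pocketVolumeMm3 = 200,
                        biasAmplitude = 0.1, biasSmoothnessMm = 60,
                        priorBlurMm = 1, seed = 1L) {
  new("PhantomSpec", dims = as.integer(dims), spacing = as.numeric(spacing),
      intensityMeans = intensityMeans, noiseSd = noiseSd,
      ventricleScale = ventricleScale, nLesions = as.integer(nLesions),
      lesionIntensity = lesionIntensity, lesionRadiusMm = lesionRadiusMm,
      nPockets = as.integer(nPockets), pocketVolumeMm3 = pocketVolumeMm3,
      biasAmplitude = biasAmplitude, biasSmoothnessMm = biasSmoothnessMm,
      priorBlurMm = priorBlurMm, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %s @ %s mm, ventricle scale %.2g, ",
                     "%d lesions, %d pockets, noise SD %.2g, bias %.0f%%\n"),
              paste(object@dims, collapse = "x"),
              paste(format(object@spacing, digits = 3), collapse = "x"),
              object@ventricleScale, object@nLesions, object@nPockets,
              object@noiseSd, 100 * object@biasAmplitude))
})

#' Phantom bundle: image, truth, mask, priors and manifest
#'
#' @slot t2 [ScalarVolume-class] synthetic T2-weighted image.
#' @slot truth [LabelVolume-class] eight-class ground truth.
#' @slot brainMask [LabelVolume-class] binary mask (truth > 0).
#' @slot priors [ProbabilityMaps-class] built from the scale-1 anatomy.
#' @slot biasField [ScalarVolume-class] the generating bias field.
#' @slot manifest list describing planted objects (ventricle, lesions,
#'   pockets) with coordinates and volumes.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomBundle",
  representation(t2 = "ScalarVolume", truth = "LabelVolume",
                 brainMask = "LabelVolume", priors = "ProbabilityMaps",
                 biasField = "ScalarVolume", manifest = "list",
                 spec = "PhantomSpec"))

setMethod("show", "PhantomBundle", function(object) {
  cat("PhantomBundle\n"); .showGeom(object@t2)
  cat(sprintf("  ventricle: %d voxels (scale %.2g); lesions: %d; pockets: %d\n",
              object@manifest$ventricle$nVoxels, object@spec@ventricleScale,
              length(object@manifest$lesions), length(object@manifest$pockets)))
})

## ellipsoid membership field given mm coordinate arrays
.ellipsoid <- function(X, Y, Z, center, radii) {
  ((X - center[1]) / radii[1])^2 + ((Y - center[2]) / radii[2])^2 +
    ((Z - center[3]) / radii[3])^2 <= 1
}

## internal structure geometry (mm, at 64 mm reference FOV)
.phantomGeometry <- function(sizeFactor) {
  s <- sizeFactor
  list(
    ventricle  = list(center = c(0, 3, 1) * s,    radii = c(7, 7.5, 6) * s),
    deep_gm    = list(center = c(0, -8, -6) * s,  radii = c(6.5, 5.5, 4.5) * s),
    cerebellum = list(center = c(0, -13, -12) * s, radii = c(8, 5.5, 4.5) * s),
    brainstem  = list(center = c(0, -4, -13) * s, radii = c(3.5, 3.5, 6) * s),
    hippocampus = list(centers = list(c(-10, -6, -8) * s, c(10, -6, -8) * s),
                       radii = c(2.5, 4, 2.5) * s),
    amygdala   = list(centers = list(c(-10, 1, -8) * s, c(10, 1, -8) * s),
                      radii = c(2.5, 2.5, 2.5) * s))
}

## face-adjacency test between two masks
.touches <- function(a, b) {
  offs <- connectivityOffsets(6L)
  for (r in seq_len(nrow(offs)))
    if (any(a & .shiftArray(b, offs[r, ], FALSE))) return(TRUE)
  any(a & b)
}

#' Build tissue priors from a ground-truth label volume
#'
#' One-hot class maps are smoothed with a Gaussian of `blurMm` (kernel
#' truncated at 3 sigma, so the prior support is finite) and renormalized
#' per voxel to sum 1 inside the brain mask; outside the mask all priors
#' are 0. `blurMm = 0` returns exact one-hot priors. This emulates the
#' spatial uncertainty of a population template aligned to the subject.
#'
#' @param truth [LabelVolume-class] with codes from [tissueClassTable()].
#' @param blurMm Gaussian blur in mm (>= 0).
#' @param mask optional binary mask; defaults to `truth > 0`.
#' @return a [ProbabilityMaps-class] over the eight tissue classes.
#' @export
makePriors <- function(truth, blurMm = 1, mask = NULL) {
  if (blurMm < 0) stop("blurMm must be >= 0")
  lab <- voxelData(truth)
  d <- dim(lab)
  msk <- if (is.null(mask)) lab > 0L else .binData(mask)
  tab <- tissueClassTable()
  codes <- as.integer(names(tab))
  arr <- array(0, c(d, length(codes)))
  for (i in seq_along(codes)) {
    oneHot <- array(as.numeric(lab == codes[i]), d)
    if (blurMm > 0)
      oneHot <- .as3d(gaussianSmooth(oneHot, blurMm,
                                     spacing = voxelSpacing(truth),
                                     truncate = 3))
    arr[, , , i] <- oneHot
  }
  sums <- .probSums(arr)
  sc <- ifelse(msk & sums > 0, 1 / sums, 0)
  for (i in seq_along(codes)) arr[, , , i] <- arr[, , , i] * sc
  ProbabilityMaps(arr, classes = unname(tab), spacing = voxelSpacing(truth),
                  affine = voxelAffine(truth))
}

## smooth multiplicative bias: unit-mean exp of max-normalized smoothed noise
.makeBias <- function(d, spacing, amplitude, smoothnessMm) {
  if (amplitude <= 0) return(array(1, d))
  raw <- array(rnorm(prod(d)), d)
  sm <- .as3d(gaussianSmooth(raw, smoothnessMm, spacing = spacing,
                             truncate = 3))
  sm <- sm - mean(sm)
  mx <- max(abs(sm))
  if (mx == 0) return(array(1, d))
  exp(sm / mx * log(1 + amplitude))
}

#' Generate a synthetic neonatal T2 phantom
#'
#' Builds the nested-ellipsoid anatomy, plants the requested pathology
#' (bright WM lesions disconnected from CSF; isolated CSF pockets
#' disconnected from all other CSF), applies bias and noise, and builds
#' priors from the scale-1 anatomy (so `ventricleScale > 1` yields priors
#' that understate the true ventricle). Disconnection of planted objects
#' is asserted at generation time; infeasible placements are an error
#' naming the constraint. Fully reproducible from `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomBundle-class].
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  validObject(spec)
  .withSeed(spec@seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
  d <- spec@dims; sp <- spec@spacing
  fov <- d * sp
  sizeFactor <- min(fov) / 64
  tab <- tissueClassTable()
  code <- function(nm) as.integer(names(tab)[match(nm, tab)])

  ## mm coordinates relative to the grid center
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  brainRadii <- c(0.84, 0.88, 0.80) * fov / 2
  norm2 <- (X / brainRadii[1])^2 + (Y / brainRadii[2])^2 + (Z / brainRadii[3])^2
  nrm <- sqrt(norm2)
  mask <- nrm <= 1

  geom <- .phantomGeometry(sizeFactor)

  baseLabels <- function(ventricleScale) {
    lab <- array(0L, d)
    lab[mask] <- code("csf")                     # peripheral rim by default
    lab[nrm <= 0.93] <- code("cortical_gm")
    lab[nrm <= 0.84] <- code("white_matter")
    inner <- lab == code("white_matter") | lab == code("cortical_gm")
    for (nm in c("deep_gm", "cerebellum", "brainstem")) {
      g <- geom[[nm]]
      lab[.ellipsoid(X, Y, Z, g$center, g$radii) & inner] <- code(nm)
    }
    for (nm in c("hippocampus", "amygdala")) {
      g <- geom[[nm]]
      for (ce in g$centers)
        lab[.ellipsoid(X, Y, Z, ce, g$radii) & inner] <- code(nm)
    }
    ## ventricleScale is a volume factor: radii scale with its cube root
    vent <- .ellipsoid(X, Y, Z, geom$ventricle$center,
                       geom$ventricle$radii * ventricleScale^(1 / 3)) & mask
    lab[vent] <- code("csf")
    list(labels = lab, ventricle = vent,
         rim = mask & nrm > 0.93)
  }

  truthParts <- baseLabels(spec@ventricleScale)
  priorParts <- baseLabels(1)
  truth <- truthParts$labels
  truthPrior <- priorParts$labels

  if (.touches(truthParts$ventricle, truthParts$rim))
    stop("infeasible phantom: ventricleScale ", spec@ventricleScale,
         " makes the ventricle touch the peripheral CSF rim on this grid")

  coordsMm <- cbind(X[TRUE], Y[TRUE], Z[TRUE])  # n x 3 (linear order)

  minDistToSet <- function(pointMm, setMask) {
    idx <- which(setMask)
    if (length(idx) == 0L) return(Inf)
    min(cpp_directed_min_dists(matrix(pointMm, 1L, 3L),
                               coordsMm[idx, , drop = FALSE]))
  }

  ## ---- pockets: isolated CSF blobs inside deep (periventricular) WM ----
  pockets <- list()
  if (spec@nPockets > 0L) {
    nVox <- max(1L, as.integer(round(spec@pocketVolumeMm3 / prod(sp))))
    rEq <- (3 * spec@pocketVolumeMm3 / (4 * pi))^(1 / 3)
    eligible <- which(truth == code("white_matter") &
                      truthPrior == code("white_matter") &
                      nrm >= 0.55 & nrm <= 0.78)
    csfMask <- truth == code("csf")
    placed <- list()
    for (p in seq_len(spec@nPockets)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        ci <- sample(eligible, 1L)
        ctr <- coordsMm[ci, ]
        if (minDistToSet(ctr, csfMask) < rEq + 2 * max(sp)) next
        if (length(placed) &&
            min(vapply(placed, function(q) sqrt(sum((q - ctr)^2)), numeric(1))) <
              2 * rEq + 2 * max(sp)) next
        ## nearest-N WM voxels to the center: exact volume control
        wmIdx <- which(truth == code("white_matter") &
                       truthPrior == code("white_matter"))
        dd <- sqrt(colSums((t(coordsMm[wmIdx, , drop = FALSE]) - ctr)^2))
        sel <- wmIdx[order(dd)[seq_len(min(nVox, length(wmIdx)))]]
        if (length(sel) < nVox) next
        if (max(dd[order(dd)[seq_len(nVox)]]) > 2 * rEq) next    # not compact
        ## the selected voxels themselves must stay clear of all CSF
        csfIdx <- which(csfMask)
        gap <- min(cpp_directed_min_dists(coordsMm[sel, , drop = FALSE],
                                          coordsMm[csfIdx, , drop = FALSE]))
        if (gap < 2 * max(sp)) next
        ## the pocket must itself be one face-connected component
        pk <- array(FALSE, d); pk[sel] <- TRUE
        if (max(.as3d(connectedComponents(pk, 6L))) != 1L) next
        truth[sel] <- code("csf")
        truthPrior[sel] <- code("csf")
        csfMask <- truth == code("csf")
        placed <- c(placed, list(ctr))
        pockets[[p]] <- list(centerMm = ctr, voxels = sel,
                             nVoxels = length(sel),
                             volumeMm3 = length(sel) * prod(sp))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible phantom: cannot place isolated CSF pocket ",
                    p, " (", spec@pocketVolumeMm3,
                    " mm^3 disconnected from other CSF) on this grid")
    }
    ## disconnection assertion
    cc <- .as3d(connectedComponents(truth == code("csf"), 6L))
    for (p in seq_along(pockets)) {
      ids <- unique(cc[pockets[[p]]$voxels])
      if (length(ids) != 1L ||
          sum(cc == ids) != pockets[[p]]$nVoxels)
        stop("infeasible phantom: pocket ", p,
             " is not an isolated CSF component")
    }
  }

  ## ---- bright WM lesions (intensity anomalies; labels stay WM) ----
  lesions <- list()
  lesionMask <- array(FALSE, d)
  if (spec@nLesions > 0L) {
    r <- spec@lesionRadiusMm
    csfMask <- truth == code("csf")
    eligible <- which(truth == code("white_matter") & nrm <= 0.75)
    placedC <- list()
    for (l in seq_len(spec@nLesions)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        ci <- sample(eligible, 1L)
        ctr <- coordsMm[ci, ]
        if (minDistToSet(ctr, csfMask) < r + 2 * max(sp)) next
        if (length(placedC) &&
            min(vapply(placedC, function(q) sqrt(sum((q - ctr)^2)), numeric(1))) <
              2 * r + 2 * max(sp)) next
        ball <- ((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2) <= r^2
        sel <- which(ball & truth == code("white_matter"))
        if (length(sel) < 4L) next
        lesionMask[sel] <- TRUE
        placedC <- c(placedC, list(ctr))
        lesions[[l]] <- list(centerMm = ctr, radiusMm = r, voxels = sel,
                             nVoxels = length(sel),
                             volumeMm3 = length(sel) * prod(sp))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible phantom: cannot place bright WM lesion ", l,
                    " disconnected from CSF on this grid")
    }
    if (.touches(lesionMask, truth == code("csf")))
      stop("infeasible phantom: lesion touches CSF")
  }

  ## ---- intensities ----
  means <- spec@intensityMeans
  t2 <- array(0, d)
  for (i in seq_along(tab))
    t2[truth == as.integer(names(tab)[i])] <- means[[tab[i]]]
  t2[lesionMask] <- spec@lesionIntensity
  if (spec@noiseSd > 0)
    t2[mask] <- t2[mask] + rnorm(sum(mask), sd = spec@noiseSd)
  bias <- .makeBias(d, sp, spec@biasAmplitude, spec@biasSmoothnessMm)
  t2 <- t2 * bias
  t2[!mask] <- 0
  t2 <- pmax(t2, 0)

  truthVol <- LabelVolume(truth, spacing = sp, codeTable = tab)
  priors <- makePriors(LabelVolume(truthPrior, spacing = sp, codeTable = tab),
                       blurMm = spec@priorBlurMm, mask = mask)

  manifest <- list(
    ventricle = list(centerMm = geom$ventricle$center,
                     radiiMm = geom$ventricle$radii * spec@ventricleScale^(1 / 3),
                     scale = spec@ventricleScale,
                     voxels = which(truthParts$ventricle),
                     nVoxels = sum(truthParts$ventricle),
                     volumeMm3 = sum(truthParts$ventricle) * prod(sp)),
    ventriclePrior = list(radiiMm = geom$ventricle$radii,
                          nVoxels = sum(priorParts$ventricle)),
    lesions = lesions,
    pockets = pockets,
    brainRadiiMm = brainRadii)

  new("PhantomBundle",
      t2 = ScalarVolume(t2, spacing = sp),
      truth = truthVol,
      brainMask = LabelVolume(array(as.integer(mask), d), spacing = sp,
                              codeTable = c("1" = "brain")),
      priors = priors,
      biasField = ScalarVolume(bias, spacing = sp),
      manifest = manifest, spec = spec)
}

#' Write a phantom bundle to disk
#'
#' @param bundle a [PhantomBundle-class].
#' @param dir output directory (created if needed): t2.nii.gz,
#'   truth.nii.gz, mask.nii.gz, bias.nii.gz, priors/c1..c8 NIfTIs and
#'   manifest.json.
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(bundle@t2, file.path(dir, "t2.nii.gz"))
  writeVolume(bundle@truth, file.path(dir, "truth.nii.gz"))
  writeVolume(bundle@brainMask, file.path(dir, "mask.nii.gz"))
  writeVolume(bundle@biasField, file.path(dir, "bias.nii.gz"))
  pdir <- file.path(dir, "priors")
  dir.create(pdir, showWarnings = FALSE)
  arr <- voxelData(bundle@priors)
  for (i in seq_len(dim(arr)[4L]))
    writeVolume(ScalarVolume(arr[, , , i], spacing = voxelSpacing(bundle@priors),
                             affine = voxelAffine(bundle@priors)),
                file.path(pdir, sprintf("c%d_%s.nii.gz", i,
                                        classNames(bundle@priors)[i])))
  mf <- bundle@manifest
  mf$ventricle$voxels <- NULL   # too large for a manifest
  for (i in seq_along(mf$lesions)) mf$lesions[[i]]$voxels <- NULL
  for (i in seq_along(mf$pockets)) mf$pockets[[i]]$voxels <- NULL
  jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
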
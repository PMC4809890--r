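#' @include nifti.R
NULL

## ---------------------------------------------------------------------------
## User-facing volume I/O, canonical reorientation and resampling.
## ---------------------------------------------------------------------------

## Nearest axis-aligned orientation of an affine: for each voxel axis,
## the dominant world axis and its sign. Returns perm (world axis served
## by each voxel axis) and flips.
.orientationOf <- function(affine) {
  A <- affine[1:3, 1:3]
  if (abs(det(A)) < 1e-12) stop("degenerate affine (determinant ~ 0)")
  perm <- integer(3L); sgn <- integer(3L)
  taken <- logical(3L)
  for (j in 1:3) {
    col <- A[, j]
    ord <- order(abs(col), decreasing = TRUE)
    i <- ord[!taken[ord]][1L]
    taken[i] <- TRUE
    perm[j] <- i
    sgn[j] <- if (col[i] < 0) -1L else 1L
  }
  list(perm = perm, sign = sgn)
}

## Reorder/flip a 3D (or 4D) array + affine so voxel axes align with world
## axes with positive direction. Returns list(data, affine, undo) where undo
## records the transform applied.
.canonicalize <- function(data, affine) {
  o <- .orientationOf(affine)
  d3 <- dim(data)[1:3]
  ## new voxel axis k should be the old axis j with perm[j] == k
  axisOrder <- order(o$perm)         # old axis index for each new axis
  flips <- o$sign[axisOrder] < 0
  nd <- length(dim(data))
  permOrder <- c(axisOrder, if (nd == 4L) 4L)
  out <- aperm(data, permOrder)
  A <- affine
  ## permute columns of the affine to match
  A[1:3, 1:3] <- affine[1:3, axisOrder]
  newd <- d3[axisOrder]
  for (k in 1:3) {
    if (flips[k]) {
      idx <- rep(list(quote(expr = )), nd)
      idx[[k]] <- rev(seq_len(newd[k]))
      out <- do.call(`[`, c(list(out), idx, list(drop = FALSE)))
      ## flipping axis k: col_k -> -col_k, origin += col_k * (n_k - 1)
      A[1:3, 4] <- A[1:3, 4] + A[1:3, k] * (newd[k] - 1)
      A[1:3, k] <- -A[1:3, k]
    }
  }
  list(data = out, affine = A,
       undo = list(axisOrder = axisOrder, flips = flips))
}

## Invert .canonicalize using the recorded undo info.
.decanonicalize <- function(data, affine, undo) {
  nd <- length(dim(data))
  d3 <- dim(data)[1:3]
  A <- affine
  for (k in 1:3) {
    if (undo$flips[k]) {
      idx <- rep(list(quote(expr = )), nd)
      idx[[k]] <- rev(seq_len(d3[k]))
      data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
      A[1:3, 4] <- A[1:3, 4] + A[1:3, k] * (d3[k] - 1)
      A[1:3, k] <- -A[1:3, k]
    }
  }
  inv <- order(undo$axisOrder)       # inverse permutation
  permOrder <- c(undo$axisOrder, if (nd == 4L) 4L)
  data <- aperm(data, order(permOrder))
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, inv]
  list(data = data, affine = A2)
}

#' Load a NIfTI volume
#'
#' Reads a 3D NIfTI-1 volume (.nii or .nii.gz, either endianness). Inputs
#' are reoriented to a canonical axis order on load (nearest axis-aligned
#' orientation with positive steps); the applied transform is recorded in
#' `meta$origOrientation` so [writeVolume()] can restore it.
#'
#' @param path file path.
#' @param kind `"scalar"` or `"label"`. Label files must hold integral
#'   values; a JSON sidecar `<path-sans-ext>.labels.json` is read as code
#'   table when present.
#' @param canonical reorient to canonical axes (default TRUE).
#' @param nan how to treat non-finite voxels in scalar input: `"error"`
#'   (default) or `"zero"` (impute 0).
#' @return a [ScalarVolume-class] or [LabelVolume-class].
#' @export
loadVolume <- function(path, kind = c("scalar", "label"), canonical = TRUE,
                       nan = c("error", "zero")) {
  kind <- match.arg(kind); nan <- match.arg(nan)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- .readNiftiRaw(path)
  undo <- NULL
  if (canonical) {
    cano <- .canonicalize(raw$data, raw$affine)
    raw$data <- cano$data; raw$affine <- cano$affine
    raw$spacing <- sqrt(colSums(raw$affine[1:3, 1:3]^2))
    undo <- cano$undo
  }
  meta <- list(path = path, origOrientation = undo)
  if (kind == "label") {
    if (any(!is.finite(raw$data)))
      stop("label file contains non-finite values: ", path)
    if (max(abs(raw$data - round(raw$data))) > 1e-6)
      stop("label file contains non-integral values: ", path)
    side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
    ct <- NULL
    if (file.exists(side)) {
      j <- jsonlite::read_json(side, simplifyVector = TRUE)
      ct <- stats::setNames(as.character(unlist(j)), names(j))
    }
    LabelVolume(round(raw$data), spacing = raw$spacing, codeTable = ct,
                affine = raw$affine, meta = meta)
  } else {
    if (any(!is.finite(raw$data))) {
      if (nan == "error") stop("scalar volume contains NaN/Inf voxels: ", path)
      raw$data[!is.finite(raw$data)] <- 0
    }
    ScalarVolume(raw$data, spacing = raw$spacing, affine = raw$affine,
                 meta = meta)
  }
}

#' Write a volume as NIfTI-1
#'
#' Scalar volumes are written as float32, label volumes as int32 with a JSON
#' code-table sidecar. If the volume was loaded with canonical reorientation
#' and `restoreOrientation = TRUE`, the original axis order is restored
#' before writing.
#'
#' @param vol a [ScalarVolume-class] or [LabelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param restoreOrientation undo the canonical reorientation recorded at
#'   load time (default TRUE when present).
#' @param datatype NIfTI datatype code override (default 16 float32 for
#'   scalars, 8 int32 for labels; use 64 for float64 round-trips).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, restoreOrientation = TRUE,
                        datatype = NULL) {
  data <- voxelData(vol); affine <- voxelAffine(vol)
  spacing <- voxelSpacing(vol)
  undo <- vol@meta$origOrientation
  if (restoreOrientation && !is.null(undo)) {
    back <- .decanonicalize(data, affine, undo)
    data <- back$data; affine <- back$affine
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  if (is(vol, "LabelVolume")) {
    if (is.null(datatype)) datatype <- 8L
    .writeNiftiRaw(data, spacing, affine, path, datatype)
    side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
    ct <- as.list(codeTable(vol))
    jsonlite::write_json(ct, side, auto_unbox = TRUE, pretty = TRUE)
  } else {
    if (is.null(datatype)) datatype <- 16L
    .writeNiftiRaw(data, spacing, affine, path, datatype)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Resampling
## ---------------------------------------------------------------------------

.trilinear <- function(src, xi, yi, zi) {
  d <- dim(src)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  out <- numeric(length(xi))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fx else fx
    wy <- if (dy == 0) 1 - fy else fy
    wz <- if (dz == 0) 1 - fz else fz
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    w <- wx * wy * wz
    use <- ok & w > 0
    if (any(use)) {
      lin <- 1 + ix[use] + d[1] * (iy[use] + d[2] * iz[use])
      out[use] <- out[use] + w[use] * src[lin]
    }
  }
  out
}

.nearestSample <- function(src, xi, yi, zi) {
  d <- dim(src)
  ix <- round(xi); iy <- round(yi); iz <- round(zi)
  out <- numeric(length(xi))
  ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
  lin <- 1 + ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok])
  out[ok] <- src[lin]
  out
}

## voxel coords (0-based) of the reference grid expressed in the moving grid
.mapGrid <- function(refAffine, refDim, movAffine) {
  if (abs(det(movAffine)) < 1e-12 || abs(det(refAffine)) < 1e-12)
    stop("degenerate affine (determinant ~ 0)")
  M <- solve(movAffine) %*% refAffine
  g <- expand.grid(i = seq_len(refDim[1]) - 1, j = seq_len(refDim[2]) - 1,
                   k = seq_len(refDim[3]) - 1)
  P <- t(M %*% rbind(g$i, g$j, g$k, 1))
  list(x = P[, 1], y = P[, 2], z = P[, 3])
}

#' Resample a volume onto a reference grid
#'
#' Maps the reference voxel centers through both affines and interpolates
#' the moving volume. Label volumes use nearest-neighbor only;
#' probabilities are clipped to [0, 1] and per-voxel class sums capped at 1.
#'
#' @param reference a volume providing the output grid.
#' @param moving a [ScalarVolume-class], [LabelVolume-class] or
#'   [ProbabilityMaps-class] to resample.
#' @param interp `"linear"` or `"nearest"`.
#' @return object of the same class as `moving`, on the reference grid.
#' @export
resampleTo <- function(reference, moving, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  refDim <- dim(voxelData(reference))[1:3]
  refAff <- voxelAffine(reference); refSp <- voxelSpacing(reference)
  co <- .mapGrid(refAff, refDim, voxelAffine(moving))
  if (is(moving, "LabelVolume")) {
    vals <- .nearestSample(voxelData(moving), co$x, co$y, co$z)
    LabelVolume(array(as.integer(round(vals)), refDim), spacing = refSp,
                codeTable = codeTable(moving), affine = refAff)
  } else if (is(moving, "ProbabilityMaps")) {
    arr <- voxelData(moving)
    ncl <- dim(arr)[4L]
    out <- array(0, c(refDim, ncl))
    for (c in seq_len(ncl)) {
      v <- if (interp == "linear") .trilinear(arr[, , , c], co$x, co$y, co$z)
           else .nearestSample(arr[, , , c], co$x, co$y, co$z)
      out[, , , c] <- pmin(pmax(v, 0), 1)
    }
    sums <- .probSums(out)
    over <- sums > 1
    if (any(over)) {
      sc <- ifelse(over, 1 / sums, 1)
      for (c in seq_len(ncl)) out[, , , c] <- out[, , , c] * sc
    }
    ProbabilityMaps(out, classes = classNames(moving), spacing = refSp,
                    affine = refAff)
  } else {
    v <- if (interp == "linear") .trilinear(voxelData(moving), co$x, co$y, co$z)
         else .nearestSample(voxelData(moving), co$x, co$y, co$z)
    ScalarVolume(array(v, refDim), spacing = refSp, affine = refAff)
  }
}
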
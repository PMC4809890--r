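#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Core volume containers. All grids are 3D; geometry is a per-axis spacing
## (mm) plus a 4x4 voxel-to-world affine (0-based voxel indices).
## ---------------------------------------------------------------------------

.validGeometry <- function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L && !(is(object, "ProbabilityMaps") && length(d) == 4L))
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "all three spacings must be positive and finite")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  msg
}

#' ScalarVolume: a real-valued 3D grid with physical geometry
#'
#' Houses the T2-weighted image and derived images (gradient magnitude,
#' bias fields, reconstruction-filtered images).
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric length-3, mm per axis (all positive).
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices, mm).
#' @slot meta list of free-form provenance (original orientation etc.).
#' @export
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric", affine = "matrix",
                 meta = "list"),
  prototype(meta = list()))

setValidity("ScalarVolume", function(object) {
  msg <- .validGeometry(object)
  if (anyNA(object@data)) msg <- c(msg, "data contains NaN/NA")
  if (length(msg)) msg else TRUE
})

#' LabelVolume: an integer-coded segmentation with a code table
#'
#' @slot data 3D integer array of non-negative codes (0 = background).
#' @slot codeTable named character vector mapping code to class name; every
#'   nonzero code present in the data must appear.
#' @slot spacing,affine,meta as in [ScalarVolume-class].
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", affine = "matrix",
                 codeTable = "character", meta = "list"),
  prototype(meta = list()))

setValidity("LabelVolume", function(object) {
  msg <- .validGeometry(object)
  if (!is.integer(object@data)) msg <- c(msg, "label data must be integer")
  else {
    if (anyNA(object@data)) msg <- c(msg, "label data contains NA")
    else if (any(object@data < 0L)) msg <- c(msg, "label codes must be non-negative")
    used <- unique(object@data[object@data != 0L])
    known <- suppressWarnings(as.integer(names(object@codeTable)))
    if (length(used) && !all(used %in% known))
      msg <- c(msg, sprintf("codes not in code table: %s",
                            paste(setdiff(used, known), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ProbabilityMaps: per-class probability volumes on one grid
#'
#' Stored as a 4D array (x, y, z, class). Per-voxel class sums may be at
#' most 1 + 1e-6; the remainder is implicit background.
#'
#' @slot data 4D numeric array in [0, 1].
#' @slot classes ordered character vector of class names (4th dimension).
#' @slot spacing,affine,meta as in [ScalarVolume-class].
#' @export
setClass("ProbabilityMaps",
  representation(data = "array", classes = "character", spacing = "numeric",
                 affine = "matrix", meta = "list"),
  prototype(meta = list()))

setValidity("ProbabilityMaps", function(object) {
  msg <- .validGeometry(object)
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array (x, y, z, class)")
  else if (d[4L] != length(object@classes))
    msg <- c(msg, "4th dimension must match the class list")
  if (anyNA(object@data)) msg <- c(msg, "probabilities contain NA")
  else {
    rng <- range(object@data)
    if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (length(d) == 4L) {
      sums <- .probSums(object@data)
      if (max(sums) > 1 + 1e-6)
        msg <- c(msg, "per-voxel class sums exceed 1 + 1e-6")
    }
  }
  if (length(msg)) msg else TRUE
})

.probSums <- function(arr4) {
  d <- dim(arr4)
  m <- matrix(arr4, ncol = d[4L])
  array(rowSums(m), d[1:3])
}

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

.defaultAffine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

#' Create a ScalarVolume
#'
#' @param data 3D numeric array.
#' @param spacing mm per axis (length 3).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(c(spacing, 1))`.
#' @param meta list of provenance entries.
#' @return a [ScalarVolume-class].
#' @export
ScalarVolume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         meta = list()) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  new("ScalarVolume", data = data, spacing = as.numeric(spacing),
      affine = affine, meta = meta)
}

#' Create a LabelVolume
#'
#' @param data 3D array of non-negative integer codes.
#' @param codeTable named character vector (names are codes as strings). If
#'   missing, codes present in the data are named `"class_<code>"`.
#' @inheritParams ScalarVolume
#' @return a [LabelVolume-class].
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1), codeTable = NULL,
                        affine = NULL, meta = list()) {
  data <- as.array(data)
  if (is.double(data)) {
    if (max(abs(data - round(data))) > 0)
      stop("label data has non-integral values")
    storage.mode(data) <- "integer"
  }
  storage.mode(data) <- "integer"
  if (is.null(codeTable)) {
    used <- sort(unique(data[data != 0L]))
    codeTable <- stats::setNames(paste0("class_", used), used)
  }
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  new("LabelVolume", data = data, spacing = as.numeric(spacing),
      codeTable = codeTable, affine = affine, meta = meta)
}

#' Create ProbabilityMaps
#'
#' @param data 4D array (x, y, z, class) or list of 3D arrays.
#' @param classes character vector of class names.
#' @inheritParams ScalarVolume
#' @return a [ProbabilityMaps-class].
#' @export
ProbabilityMaps <- function(data, classes, spacing = c(1, 1, 1),
                            affine = NULL, meta = list()) {
  if (is.list(data)) {
    d3 <- dim(data[[1L]])
    data <- array(unlist(data, use.names = FALSE), c(d3, length(data)))
  }
  storage.mode(data) <- "double"
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  new("ProbabilityMaps", data = data, classes = as.character(classes),
      spacing = as.numeric(spacing), affine = affine, meta = meta)
}

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @rdname voxelData
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "ProbabilityMaps", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ProbabilityMaps", function(x) x@spacing)

#' @rdname voxelAffine
#' @export
setMethod("voxelAffine", "ScalarVolume", function(x) x@affine)
#' @rdname voxelAffine
#' @export
setMethod("voxelAffine", "LabelVolume", function(x) x@affine)
#' @rdname voxelAffine
#' @export
setMethod("voxelAffine", "ProbabilityMaps", function(x) x@affine)

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ScalarVolume", function(x) prod(x@spacing))
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "LabelVolume", function(x) prod(x@spacing))
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ProbabilityMaps", function(x) prod(x@spacing))

#' @rdname codeTable
#' @export
setMethod("codeTable", "LabelVolume", function(x) x@codeTable)

#' @rdname classNames
#' @export
setMethod("classNames", "ProbabilityMaps", function(x) x@classes)

.showGeom <- function(x) {
  d <- dim(x@data)
  cat(sprintf("  grid: %s  spacing: %s mm\n",
              paste(d[1:3], collapse = " x "),
              paste(format(x@spacing, digits = 4), collapse = " x ")))
}

setMethod("show", "ScalarVolume", function(object) {
  cat("ScalarVolume\n"); .showGeom(object)
  r <- range(object@data)
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", r[1], r[2]))
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume\n"); .showGeom(object)
  used <- sort(unique(as.vector(object@data[object@data != 0L])))
  cat(sprintf("  labels in use: %s\n",
              if (length(used)) paste(used, collapse = ", ") else "(none)"))
})

setMethod("show", "ProbabilityMaps", function(object) {
  cat("ProbabilityMaps\n"); .showGeom(object)
  cat(sprintf("  classes (%d): %s\n", length(object@classes),
              paste(object@classes, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Geometry comparison
## ---------------------------------------------------------------------------

#' Test whether two volumes share grid geometry
#'
#' @param a,b volume objects.
#' @param tol numeric tolerance on spacing/affine entries.
#' @return logical.
#' @export
sameGeometry <- function(a, b, tol = 1e-6) {
  da <- dim(voxelData(a))[1:3]; db <- dim(voxelData(b))[1:3]
  identical(da, db) &&
    max(abs(voxelSpacing(a) - voxelSpacing(b))) <= tol &&
    max(abs(voxelAffine(a) - voxelAffine(b))) <= tol
}

.stopGeometry <- function(a, b, what = "inputs") {
  if (!sameGeometry(a, b))
    stop(sprintf("geometry mismatch: %s must share grid, spacing and affine",
                 what))
  invisible(TRUE)
}

## Extract one class map from ProbabilityMaps as a 3D array.
#' Extract a single class probability map
#'
#' @param p a [ProbabilityMaps-class].
#' @param class class name or index.
#' @return 3D numeric array.
#' @export
classMap <- function(p, class) {
  stopifnot(is(p, "ProbabilityMaps"))
  i <- if (is.character(class)) match(class, p@classes) else as.integer(class)
  if (is.na(i) || i < 1L || i > length(p@classes))
    stop("unknown class: ", class)
  p@data[, , , i, drop = TRUE]
}
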
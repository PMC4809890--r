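#' @include utils.R
NULL

#' Voxel data of a volume
#'
#' @param x a volume object.
#' @return the underlying 3D array (or 4D array for [ProbabilityMaps-class]).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing in mm
#'
#' @param x a volume object.
#' @return numeric length-3 vector of mm per axis.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Voxel-to-world affine (4x4, mm)
#'
#' @param x a volume object.
#' @return 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))

#' Physical volume of one voxel in mm^3
#'
#' @param x a volume object.
#' @return product of the three spacings.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Label code table of a label volume
#'
#' @param x a [LabelVolume-class].
#' @return named character vector mapping code (name) to class name (value).
#' @export
setGeneric("codeTable", function(x) standardGeneric("codeTable"))

#' Class names carried by probability maps
#'
#' @param x a [ProbabilityMaps-class].
#' @return ordered character vector of class names.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
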
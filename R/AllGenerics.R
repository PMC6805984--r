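#' Mask volume in cm^3
#'
#' Member voxel count times the physical voxel volume. An empty mask has
#' volume zero.
#'
#' @param x a [BinaryMask-class].
#' @return volume in cm^3.
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' Extract the nine volumetric imaging parameters from a StructureSet
#'
#' @param x a [StructureSet-class].
#' @param ... passed to methods (`thickness`, the shell thickness in mm).
#' @return a [VolumetricFeatures-class].
#' @export
setGeneric("extractFeatures", function(x, ...) standardGeneric("extractFeatures"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("atvMask", function(x) standardGeneric("atvMask"))

#' @rdname accessors
#' @export
setGeneric("itcMask", function(x) standardGeneric("itcMask"))

#' Accessors for pcrvol objects
#'
#' `gridSpacing`/`gridShape` return the physical spacing (mm) and voxel
#' counts; `voxels` the logical membership array; `atvMask`/`itcMask`
#' the component masks of a [StructureSet-class]; `clinicalTable` and
#' `featureTable` the per-patient data.frames of a
#' [SyntheticCohort-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
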
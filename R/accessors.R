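#' @rdname accessors
#' @export
setMethod("gridSpacing", "ImageGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "BinaryMask", function(x) x@grid@spacing)

#' @rdname accessors
#' @export
setMethod("gridShape", "ImageGrid", function(x) x@shape)

#' @rdname accessors
#' @export
setMethod("gridShape", "BinaryMask", function(x) x@grid@shape)

#' @rdname accessors
#' @export
setMethod("voxels", "BinaryMask", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("atvMask", "StructureSet", function(x) x@atv)

#' @rdname accessors
#' @export
setMethod("itcMask", "StructureSet", function(x) x@itc)
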
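#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("lengthMm", function(x) standardGeneric("lengthMm"))

#' @rdname accessors
#' @export
setGeneric("binaryVolume", function(x) standardGeneric("binaryVolume"))

#' @rdname accessors
#' @export
setGeneric("growthCoefficients", function(x) standardGeneric("growthCoefficients"))
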
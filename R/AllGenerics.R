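#' @title Accessor generics
#' @description Accessors for the core data containers.
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("velocityData", function(x) standardGeneric("velocityData"))
#' @rdname accessors
#' @export
setGeneric("magnitudeData", function(x) standardGeneric("magnitudeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))
#' @rdname accessors
#' @export
setGeneric("cycleDuration", function(x) standardGeneric("cycleDuration"))
#' @rdname accessors
#' @export
setGeneric("venc", function(x) standardGeneric("venc"))
#' @rdname accessors
#' @export
setGeneric("clPoints", function(x) standardGeneric("clPoints"))
#' @rdname accessors
#' @export
setGeneric("clTangents", function(x) standardGeneric("clTangents"))
#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("regionBoundaries", function(x) standardGeneric("regionBoundaries"))
#' @rdname accessors
#' @export
setGeneric("parameterMap", function(x, parameter) standardGeneric("parameterMap"))
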
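#' Accessor generics
#'
#' Small accessor generics shared by the S4 data containers of the package.
#' Each has a method for the classes to which it applies; see the class pages
#' ([StimulusClip-class], [EpochedTrace-class], [FilterPair-class],
#' [PointMosaic-class], [NeuriteScene-class]) for details.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @export
setGeneric("meanIntensity", function(x) standardGeneric("meanIntensity"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))

#' @rdname accessors
#' @export
setGeneric("traceRate", function(x) standardGeneric("traceRate"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("baselineWindow", function(x) standardGeneric("baselineWindow"))

#' @rdname accessors
#' @export
setGeneric("onFilter", function(x) standardGeneric("onFilter"))

#' @rdname accessors
#' @export
setGeneric("offFilter", function(x) standardGeneric("offFilter"))

#' @rdname accessors
#' @export
setGeneric("mosaicPoints", function(x) standardGeneric("mosaicPoints"))

#' @rdname accessors
#' @export
setGeneric("mosaicDensity", function(x) standardGeneric("mosaicDensity"))

#' @rdname accessors
#' @export
setGeneric("puncta", function(x) standardGeneric("puncta"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("effectiveRadius", function(x) standardGeneric("effectiveRadius"))
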
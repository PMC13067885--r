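#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("mlSeries", function(x) standardGeneric("mlSeries"))

#' @rdname accessors
#' @export
setGeneric("apSeries", function(x) standardGeneric("apSeries"))

#' @rdname accessors
#' @export
setGeneric("visualCondition", function(x) standardGeneric("visualCondition"))

#' @rdname accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname accessors
#' @export
setGeneric("hbo", function(x) standardGeneric("hbo"))

#' @rdname accessors
#' @export
setGeneric("hbr", function(x) standardGeneric("hbr"))

#' @rdname accessors
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))

#' @rdname accessors
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))

#' @rdname accessors
#' @export
setGeneric("odValues", function(x) standardGeneric("odValues"))

#' @rdname accessors
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
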
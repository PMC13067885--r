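#' Accessors for fnirsBalance data classes
#'
#' Small accessor generics avoiding direct slot access: sampling rate,
#' series length, channel count, COP axis series, condition and participant
#' labels, hemoglobin matrices, artifact mask and rejected channels,
#' optical-density and intensity arrays, and device wavelengths.
#'
#' @param x a [CopTrial-class], [OpticalRecording-class], [OdSeries-class],
#'   [HemoRecording-class] or [FcMatrix-class] object, as applicable.
#' @return The accessed component (numeric vector, matrix, array or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("samplingRate", "CopTrial", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "OpticalRecording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "OdSeries", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "HemoRecording", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("nSamples", "CopTrial", function(x) length(x@ml))
#' @rdname accessors
#' @export
setMethod("nSamples", "OpticalRecording", function(x) dim(x@intensity)[3])
#' @rdname accessors
#' @export
setMethod("nSamples", "OdSeries", function(x) dim(x@od)[3])
#' @rdname accessors
#' @export
setMethod("nSamples", "HemoRecording", function(x) ncol(x@hbo))

#' @rdname accessors
#' @export
setMethod("nChannels", "OpticalRecording", function(x) dim(x@intensity)[1])
#' @rdname accessors
#' @export
setMethod("nChannels", "OdSeries", function(x) dim(x@od)[1])
#' @rdname accessors
#' @export
setMethod("nChannels", "HemoRecording", function(x) nrow(x@hbo))

#' @rdname accessors
#' @export
setMethod("mlSeries", "CopTrial", function(x) x@ml)
#' @rdname accessors
#' @export
setMethod("apSeries", "CopTrial", function(x) x@ap)
#' @rdname accessors
#' @export
setMethod("visualCondition", "CopTrial", function(x) x@visualCondition)
#' @rdname accessors
#' @export
setMethod("participantId", "CopTrial", function(x) x@participantId)

#' @rdname accessors
#' @export
setMethod("hbo", "HemoRecording", function(x) x@hbo)
#' @rdname accessors
#' @export
setMethod("hbr", "HemoRecording", function(x) x@hbr)
#' @rdname accessors
#' @export
setMethod("artifactMask", "HemoRecording", function(x) x@artifactMask)
#' @rdname accessors
#' @export
setMethod("badChannels", "HemoRecording", function(x) x@badChannels)

#' @rdname accessors
#' @export
setMethod("odValues", "OdSeries", function(x) x@od)
#' @rdname accessors
#' @export
setMethod("intensityValues", "OpticalRecording", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("wavelengths", "OpticalRecording", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "OdSeries", function(x) x@wavelengths)

#' @describeIn FcMatrix extract the Fisher-z matrix.
#' @param x an `FcMatrix`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "FcMatrix", function(x, ...) x@z)

setMethod("show", "CopTrial", function(object) {
  cat(sprintf(
    "CopTrial: %s, %s eyes, trial %d\n  %d samples at %g Hz (%.1f s)\n",
    object@participantId, object@visualCondition, object@trialIndex,
    length(object@ml), object@samplingRate,
    length(object@ml) / object@samplingRate
  ))
})

setMethod("show", "OpticalRecording", function(object) {
  d <- dim(object@intensity)
  cat(sprintf(
    "OpticalRecording: %d channels x %g/%g nm x %d samples at %g Hz\n",
    d[1], object@wavelengths[1], object@wavelengths[2], d[3],
    object@samplingRate
  ))
})

setMethod("show", "OdSeries", function(object) {
  d <- dim(object@od)
  cat(sprintf(
    "OdSeries: %d channels x 2 wavelengths x %d samples at %g Hz\n",
    d[1], d[3], object@samplingRate
  ))
})

setMethod("show", "HemoRecording", function(object) {
  cat(sprintf(
    "HemoRecording: %d channels x %d samples at %g Hz\n",
    nrow(object@hbo), ncol(object@hbo), object@samplingRate
  ))
  cat(sprintf(
    "  artifact samples: %.1f%%; bad channels: %s\n",
    100 * mean(object@artifactMask),
    if (length(object@badChannels))
      paste(object@badChannels, collapse = ", ") else "none"
  ))
})

setMethod("show", "FcMatrix", function(object) {
  z <- object@z
  ut <- z[upper.tri(z)]
  cat(sprintf(
    "FcMatrix: %d x %d Fisher-z connectivity\n  mean z %.3f, %d/%d positive edges\n",
    nrow(z), ncol(z), mean(ut), sum(ut > 0), length(ut)
  ))
})
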
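#' @import methods
NULL

#' CopTrial: a single center-of-pressure trial
#'
#' Holds one force-platform center-of-pressure (COP) trajectory for a single
#' standing trial: the medio-lateral (ML, x-axis) and anterior-posterior
#' (AP, y-axis) displacement series in millimetres, the sampling rate, and
#' the trial labels needed to place it inside a 2 (group) x 2 (visual
#' condition) design.
#'
#' @slot ml numeric vector of ML displacement (mm).
#' @slot ap numeric vector of AP displacement (mm), same length as `ml`.
#' @slot samplingRate sampling frequency in Hz.
#' @slot visualCondition `"open"` or `"closed"`.
#' @slot trialIndex integer trial number within the condition.
#' @slot participantId participant identifier.
#'
#' @seealso [copTrial()], [copMetrics()], [filterCop()]
#' @export
setClass("CopTrial",
  representation(
    ml = "numeric",
    ap = "numeric",
    samplingRate = "numeric",
    visualCondition = "character",
    trialIndex = "integer",
    participantId = "character"
  ),
  prototype(
    samplingRate = 1000,
    visualCondition = "open",
    trialIndex = 1L,
    participantId = "P01"
  )
)

setValidity("CopTrial", function(object) {
  msg <- character()
  if (length(object@ml) != length(object@ap))
    msg <- c(msg, "ml and ap series must have equal length")
  if (length(object@ml) < 2)
    msg <- c(msg, "COP series must contain at least 2 samples")
  if (!all(is.finite(object@ml)) || !all(is.finite(object@ap)))
    msg <- c(msg, "COP series must be finite")
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!object@visualCondition %in% c("open", "closed"))
    msg <- c(msg, "visualCondition must be 'open' or 'closed'")
  if (length(msg)) msg else TRUE
})

#' OpticalRecording: raw two-wavelength fNIRS intensities
#'
#' Raw optical intensity series for a multichannel continuous-wave fNIRS
#' recording: one series per channel and wavelength, in arbitrary device
#' units. Channels are rows of a `channel x wavelength x time` array.
#'
#' @slot intensity numeric array `[channel, wavelength, time]`, strictly
#'   positive.
#' @slot wavelengths the two wavelengths in nm (default 730, 850).
#' @slot samplingRate sampling frequency in Hz (default 11).
#' @slot sdDistance source-detector separation in cm, one value per channel
#'   (default 3).
#'
#' @seealso [intensityToOd()], [preprocessRecording()],
#'   [generateFnirsRecording()]
#' @export
setClass("OpticalRecording",
  representation(
    intensity = "array",
    wavelengths = "numeric",
    samplingRate = "numeric",
    sdDistance = "numeric"
  ),
  prototype(
    wavelengths = c(730, 850),
    samplingRate = 11
  )
)

setValidity("OpticalRecording", function(object) {
  msg <- character()
  d <- dim(object@intensity)
  if (length(d) != 3)
    msg <- c(msg, "intensity must be a channel x wavelength x time array")
  else {
    if (d[2] != 2) msg <- c(msg, "exactly two wavelengths are required")
    if (length(object@sdDistance) != d[1])
      msg <- c(msg, "sdDistance must give one separation per channel")
  }
  if (length(object@wavelengths) != 2)
    msg <- c(msg, "wavelengths must have length 2")
  if (!all(object@intensity > 0))
    msg <- c(msg, "all intensities must be strictly positive")
  if (object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (length(msg)) msg else TRUE
})

#' OdSeries: change in optical density
#'
#' Base-10 optical-density change relative to the temporal mean intensity,
#' per channel and wavelength. Produced by [intensityToOd()]; dimensionless.
#'
#' @slot od numeric array `[channel, wavelength, time]`.
#' @slot wavelengths the two wavelengths in nm.
#' @slot samplingRate sampling frequency in Hz.
#' @slot sdDistance source-detector separation in cm per channel.
#'
#' @seealso [scrubMotionArtifacts()], [bandpassFilter()], [odToHemoglobin()]
#' @export
setClass("OdSeries",
  representation(
    od = "array",
    wavelengths = "numeric",
    samplingRate = "numeric",
    sdDistance = "numeric"
  )
)

setValidity("OdSeries", function(object) {
  msg <- character()
  d <- dim(object@od)
  if (length(d) != 3 || d[2] != 2)
    msg <- c(msg, "od must be a channel x 2-wavelength x time array")
  if (!all(is.finite(object@od)))
    msg <- c(msg, "od values must be finite")
  if (length(msg)) msg else TRUE
})

#' HemoRecording: hemoglobin concentration changes
#'
#' Per-channel oxy- and deoxyhemoglobin concentration change series in
#' micromolar, together with the motion-artifact mask and the set of
#' channels rejected during scrubbing. After [preprocessRecording()] every
#' channel's HbO series has zero temporal mean.
#'
#' @slot hbo numeric matrix `[channel, time]` of HbO changes (uM).
#' @slot hbr numeric matrix `[channel, time]` of HbR changes (uM).
#' @slot samplingRate sampling frequency in Hz.
#' @slot artifactMask logical matrix `[channel, time]`; `TRUE` marks samples
#'   replaced by interpolation during motion scrubbing.
#' @slot badChannels integer indices of channels excluded from downstream
#'   region averaging.
#'
#' @seealso [preprocessRecording()], [roiAverage()]
#' @export
setClass("HemoRecording",
  representation(
    hbo = "matrix",
    hbr = "matrix",
    samplingRate = "numeric",
    artifactMask = "matrix",
    badChannels = "integer"
  )
)

setValidity("HemoRecording", function(object) {
  msg <- character()
  if (!identical(dim(object@hbo), dim(object@hbr)))
    msg <- c(msg, "hbo and hbr must have identical dimensions")
  if (!identical(dim(object@hbo), dim(object@artifactMask)))
    msg <- c(msg, "artifactMask must match the hbo dimensions")
  if (!all(is.finite(object@hbo)) || !all(is.finite(object@hbr)))
    msg <- c(msg, "hemoglobin series must be finite")
  if (length(object@badChannels) &&
      (min(object@badChannels) < 1 ||
       max(object@badChannels) > nrow(object@hbo)))
    msg <- c(msg, "badChannels out of range")
  if (length(msg)) msg else TRUE
})

#' FcMatrix: Fisher-z functional-connectivity matrix
#'
#' Symmetric region-of-interest connectivity matrix of Fisher z-transformed
#' Pearson correlations with negative correlations zeroed before the
#' transform; the diagonal is 0 by convention.
#'
#' @slot z numeric ROI x ROI matrix of Fisher-z values.
#'
#' @seealso [connectivityMatrix()], [networkMetrics()],
#'   [thresholdProportional()]
#' @export
setClass("FcMatrix", representation(z = "matrix"))

setValidity("FcMatrix", function(object) {
  z <- object@z
  msg <- character()
  if (nrow(z) != ncol(z)) msg <- c(msg, "matrix must be square")
  if (!all(is.finite(z))) msg <- c(msg, "entries must be finite")
  if (any(z < 0)) msg <- c(msg, "entries must be non-negative")
  if (any(abs(z - t(z)) > 1e-12)) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(z)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})
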
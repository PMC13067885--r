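#' Modified Beer-Lambert law coefficients
#'
#' Extinction coefficients of oxy- and deoxyhemoglobin at the two device
#' wavelengths, in 1/(mM*cm), and the differential pathlength factor (DPF)
#' per wavelength. Defaults use the widely tabulated molar extinction
#' spectra of hemoglobin at 730 and 850 nm and the conventional adult DPF
#' of 6.0; both are configurable.
#'
#' @param extinction 2x2 matrix, rows = wavelengths (in the recording's
#'   order), columns = `c("HbO", "HbR")`, units 1/(mM*cm).
#' @param dpf numeric length-2 differential pathlength factor per
#'   wavelength.
#' @return list with elements `extinction` and `dpf`.
#' @examples
#' mbllCoefficients()
#' @export
mbllCoefficients <- function(
    extinction = matrix(
      c(
        0.390, 1.102, # 730 nm: HbO, HbR
        1.058, 0.691 # 850 nm: HbO, HbR
      ),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("730", "850"), c("HbO", "HbR"))
    ),
    dpf = c(6.0, 6.0)) {
  if (!identical(dim(extinction), c(2L, 2L)))
    stop("extinction must be a 2 x 2 matrix", call. = FALSE)
  if (length(dpf) != 2 || any(dpf <= 0))
    stop("dpf must be two positive values", call. = FALSE)
  if (abs(det(extinction * dpf)) < 1e-10)
    stop("extinction * DPF system is singular", call. = FALSE)
  list(extinction = extinction, dpf = dpf)
}

#' Convert raw intensities to optical-density change
#'
#' `dOD(t) = -log10(I(t) / mean(I))` per channel and wavelength. Scaling a
#' channel's intensities by any constant leaves the result unchanged.
#'
#' @param rec an [OpticalRecording-class].
#' @return an [OdSeries-class].
#' @export
intensityToOd <- function(rec) {
  stopifnot(is(rec, "OpticalRecording"))
  ii <- rec@intensity
  bad <- which(apply(ii <= 0, 1, any))
  if (length(bad))
    stop(
      "non-positive intensity in channel(s) ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  od <- ii
  for (ch in seq_len(dim(ii)[1])) {
    for (w in 1:2) {
      x <- ii[ch, w, ]
      od[ch, w, ] <- -log10(x / mean(x))
    }
  }
  new("OdSeries",
    od = od, wavelengths = rec@wavelengths,
    samplingRate = rec@samplingRate, sdDistance = rec@sdDistance
  )
}

# Sliding peak-to-peak range over a window of `w` samples; returns a vector
# of length n - w + 1 (one value per window start).
.rollingRange <- function(x, w) {
  n <- length(x)
  nw <- n - w + 1
  mx <- x[seq_len(nw)]
  mn <- mx
  for (k in 1:(w - 1)) {
    seg <- x[(1 + k):(nw + k)]
    mx <- pmax(mx, seg)
    mn <- pmin(mn, seg)
  }
  mx - mn
}

#' Flag and interpolate motion artifacts in optical-density series
#'
#' A sample is flagged when the peak-to-peak signal change within any
#' window of `windowS` seconds containing it exceeds `sdFactor` times the
#' channel's standard deviation (per wavelength). Flagged segments are
#' replaced by linear interpolation from surrounding clean samples, keeping
#' the series uniformly sampled for filtering and correlation. Channels
#' whose flagged fraction reaches `badChannelFraction` are reported as bad.
#'
#' @param od an [OdSeries-class].
#' @param windowS detection window length in seconds (default 0.5).
#' @param sdFactor threshold in channel-SD multiples (default 10).
#' @param badChannelFraction flagged-sample fraction at or above which a
#'   channel is declared bad (default 0.5).
#' @return list with elements `od` (scrubbed [OdSeries-class]), `mask`
#'   (logical channel x time matrix) and `badChannels` (integer vector).
#' @export
scrubMotionArtifacts <- function(od, windowS = 0.5, sdFactor = 10,
                                 badChannelFraction = 0.5) {
  stopifnot(is(od, "OdSeries"))
  fs <- od@samplingRate
  n <- dim(od@od)[3]
  w <- max(2L, round(windowS * fs))
  if (w >= n) stop("window longer than the recording", call. = FALSE)
  nch <- dim(od@od)[1]
  mask <- matrix(FALSE, nch, n)
  out <- od@od
  for (ch in seq_len(nch)) {
    for (wl in 1:2) {
      x <- od@od[ch, wl, ]
      thr <- sdFactor * stats::sd(x)
      if (!is.finite(thr) || thr == 0) next
      rng <- .rollingRange(x, w)
      starts <- which(rng > thr)
      if (!length(starts)) next
      for (s in starts) mask[ch, s:(s + w - 1)] <- TRUE
    }
  }
  badChannels <- which(rowMeans(mask) >= badChannelFraction)
  for (ch in seq_len(nch)) {
    flagged <- mask[ch, ]
    if (!any(flagged) || all(flagged)) next
    good <- which(!flagged)
    for (wl in 1:2) {
      x <- out[ch, wl, ]
      x[flagged] <- stats::approx(good, x[good], xout = which(flagged),
        rule = 2
      )$y
      out[ch, wl, ] <- x
    }
  }
  od@od <- out
  list(od = od, mask = mask, badChannels = as.integer(badChannels))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward band-pass for hemodynamic series; the default
#' 0.01-0.1 Hz band isolates slow hemodynamic fluctuations while rejecting
#' respiratory (~0.3 Hz), cardiac (~1 Hz) and Mayer-wave components as well
#' as drift/DC.
#'
#' @param x numeric vector, or matrix with one series per row.
#' @param samplingRate sampling frequency in Hz.
#' @param lowHz,highHz band edges in Hz; `highHz` must be below Nyquist.
#' @param order filter order before the forward-backward pass (default 3).
#' @return filtered object of the same shape.
#' @export
bandpassFilter <- function(x, samplingRate, lowHz = 0.01, highHz = 0.1,
                           order = 3) {
  nyq <- samplingRate / 2
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq))
    stop("need 0 < lowHz < highHz < Nyquist (", nyq, " Hz)", call. = FALSE)
  # cascade of separate high- and low-pass sections: a single narrowband
  # band-pass of order 2*order is numerically ill-conditioned (poles
  # clustered near z = 1), the cascade is not
  hp <- .butterDesign(order, lowHz / nyq, "high")
  lp <- .butterDesign(order, highHz / nyq, "low")
  f <- function(v) .zeroPhase(lp, .zeroPhase(hp, v))
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

# Band-pass an OdSeries in place.
.bandpassOd <- function(od, lowHz, highHz, order) {
  for (wl in 1:2) {
    od@od[, wl, ] <- bandpassFilter(
      od@od[, wl, , drop = TRUE], od@samplingRate, lowHz, highHz, order
    )
  }
  od
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and time point, the 2x2 linear system
#' `dOD_lambda = d * DPF(lambda) * (eHbO(lambda) dHbO + eHbR(lambda) dHbR)`
#' for the concentration changes, returned in micromolar. Concentrations
#' scale as 1/d: doubling the source-detector distance halves the recovered
#' concentrations for fixed optical density.
#'
#' @param od an [OdSeries-class].
#' @param coeffs coefficients from [mbllCoefficients()].
#' @return list with `hbo` and `hbr` channel x time matrices (uM).
#' @export
odToHemoglobin <- function(od, coeffs = mbllCoefficients()) {
  stopifnot(is(od, "OdSeries"))
  nch <- dim(od@od)[1]
  n <- dim(od@od)[3]
  hboM <- matrix(0, nch, n)
  hbrM <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    # E maps mM concentrations to OD; invert and convert to uM
    e <- coeffs$extinction * coeffs$dpf * od@sdDistance[ch]
    conc <- solve(e, rbind(od@od[ch, 1, ], od@od[ch, 2, ])) * 1000
    hboM[ch, ] <- conc[1, ]
    hbrM[ch, ] <- conc[2, ]
  }
  list(hbo = hboM, hbr = hbrM)
}

#' Forward modified Beer-Lambert model
#'
#' Synthesizes optical-density changes from known concentration changes;
#' the exact inverse of [odToHemoglobin()] (used by the synthetic generator
#' and for roundtrip verification).
#'
#' @param hbo,hbr channel x time matrices of concentration changes (uM).
#' @param coeffs coefficients from [mbllCoefficients()].
#' @param sdDistance source-detector separation in cm (scalar or per
#'   channel).
#' @return array `[channel, wavelength, time]` of optical-density changes.
#' @export
hemoglobinToOd <- function(hbo, hbr, coeffs = mbllCoefficients(),
                           sdDistance = 3) {
  nch <- nrow(hbo)
  n <- ncol(hbo)
  d <- rep_len(sdDistance, nch)
  od <- array(0, dim = c(nch, 2, n))
  for (ch in seq_len(nch)) {
    e <- coeffs$extinction * coeffs$dpf * d[ch]
    od[ch, , ] <- e %*% rbind(hbo[ch, ], hbr[ch, ]) / 1000
  }
  od
}

#' Full fNIRS preprocessing chain
#'
#' Raw intensities to analysis-ready hemoglobin series:
#' optical-density conversion, motion-artifact scrubbing, zero-phase
#' 0.01-0.1 Hz band-pass, modified Beer-Lambert inversion, and final
#' per-channel mean subtraction (global trend normalization). Entirely
#' deterministic.
#'
#' @param rec an [OpticalRecording-class].
#' @param coeffs coefficients from [mbllCoefficients()].
#' @param lowHz,highHz,filterOrder band-pass settings.
#' @param windowS,sdFactor,badChannelFraction scrubbing settings, see
#'   [scrubMotionArtifacts()].
#' @return a [HemoRecording-class]; each channel's HbO and HbR series has
#'   zero temporal mean.
#' @examples
#' tpl <- generateNetworkTemplate("smallworld", seed = 1)
#' rec <- generateFnirsRecording(tpl, duration = 60, seed = 1)
#' hemo <- preprocessRecording(rec)
#' range(rowMeans(hbo(hemo)))
#' @export
preprocessRecording <- function(rec, coeffs = mbllCoefficients(),
                                lowHz = 0.01, highHz = 0.1, filterOrder = 3,
                                windowS = 0.5, sdFactor = 10,
                                badChannelFraction = 0.5) {
  od <- intensityToOd(rec)
  scrubbed <- scrubMotionArtifacts(od, windowS, sdFactor, badChannelFraction)
  odf <- .bandpassOd(scrubbed$od, lowHz, highHz, filterOrder)
  conc <- odToHemoglobin(odf, coeffs)
  hboM <- conc$hbo - rowMeans(conc$hbo)
  hbrM <- conc$hbr - rowMeans(conc$hbr)
  new("HemoRecording",
    hbo = hboM, hbr = hbrM, samplingRate = rec@samplingRate,
    artifactMask = scrubbed$mask, badChannels = scrubbed$badChannels
  )
}

#' Read / write optical recordings as long CSV
#'
#' Long format with columns `time_s`, `channel`, `wavelength_nm`,
#' `intensity`.
#'
#' @param rec an [OpticalRecording-class].
#' @param path file path.
#' @return `readOpticalRecordingCsv` returns an [OpticalRecording-class];
#'   `writeOpticalRecordingCsv` returns `path` invisibly.
#' @export
writeOpticalRecordingCsv <- function(rec, path) {
  d <- dim(rec@intensity)
  tt <- (seq_len(d[3]) - 1) / rec@samplingRate
  long <- data.frame(
    time_s = rep(tt, each = d[1] * 2),
    channel = rep(seq_len(d[1]), times = 2 * d[3]),
    wavelength_nm = rep(rep(rec@wavelengths, each = d[1]), times = d[3]),
    intensity = as.vector(rec@intensity)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOpticalRecordingCsv
#' @param sdDistance source-detector separation in cm assigned on read.
#' @export
readOpticalRecordingCsv <- function(path, sdDistance = 3) {
  d <- utils::read.csv(path)
  need <- c("time_s", "channel", "wavelength_nm", "intensity")
  if (!all(need %in% names(d)))
    stop(
      "fNIRS CSV must have columns time_s, channel, wavelength_nm, intensity",
      call. = FALSE
    )
  tt <- sort(unique(d$time_s))
  wl <- sort(unique(d$wavelength_nm))
  ch <- sort(unique(d$channel))
  if (length(wl) != 2) stop("exactly two wavelengths expected", call. = FALSE)
  arr <- array(NA_real_, dim = c(length(ch), 2, length(tt)))
  d <- d[order(d$time_s, d$wavelength_nm, d$channel), ]
  arr[] <- d$intensity # channel fastest, then wavelength, then time
  fs <- 1 / stats::median(diff(tt))
  new("OpticalRecording",
    intensity = arr, wavelengths = wl, samplingRate = fs,
    sdDistance = rep_len(sdDistance, length(ch))
  )
}
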
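#' Physiological noise specification for synthetic fNIRS signals
#'
#' Oscillatory components at the canonical physiological frequencies
#' (Mayer waves ~0.1 Hz, respiration ~0.3 Hz, cardiac ~1.0 Hz), a slow
#' linear drift with a per-channel random slope, and occasional motion
#' spikes. Amplitudes are in micromolar on the HbO scale; spike amplitude
#' is in multiples of the channel's optical-density SD.
#'
#' @param oscillations data.frame with columns `freq` (Hz) and `amplitude`
#'   (uM); frequencies must lie below the recording Nyquist (5.5 Hz at
#'   11 Hz sampling).
#' @param driftSd SD of the per-channel linear drift slope (uM per
#'   minute).
#' @param spikeRate motion-spike rate in events per minute per channel.
#' @param spikeAmplitude spike height in channel-OD-SD multiples.
#' @param channelNoiseSd SD of independent white channel noise (uM).
#' @return validated list of class `NoiseSpec`.
#' @export
noiseSpec <- function(
    oscillations = data.frame(
      freq = c(0.1, 0.3, 1.0),
      amplitude = c(0.2, 0.1, 0.1)
    ),
    driftSd = 0.3, spikeRate = 0.5, spikeAmplitude = 8,
    channelNoiseSd = 0.15) {
  if (any(oscillations$amplitude < 0) || driftSd < 0 || spikeRate < 0 ||
      spikeAmplitude < 0 || channelNoiseSd < 0)
    stop("noise amplitudes and rates must be >= 0", call. = FALSE)
  if (any(oscillations$freq >= 5.5))
    stop("oscillation frequencies must be below the 5.5 Hz Nyquist",
      call. = FALSE
    )
  out <- list(
    oscillations = oscillations, driftSd = driftSd,
    spikeRate = spikeRate, spikeAmplitude = spikeAmplitude,
    channelNoiseSd = channelNoiseSd
  )
  class(out) <- "NoiseSpec"
  out
}

#' Silent noise specification
#'
#' Convenience: all oscillation, drift, spike and channel-noise amplitudes
#' zero.
#'
#' @return a `NoiseSpec` with every component disabled.
#' @export
quietNoiseSpec <- function() {
  noiseSpec(
    oscillations = data.frame(freq = numeric(), amplitude = numeric()),
    driftSd = 0, spikeRate = 0, spikeAmplitude = 0, channelNoiseSd = 0
  )
}

#' Generate a synthetic two-wavelength fNIRS recording
#'
#' Draws latent ROI signals with covariance `I + coupling * A` induced by
#' the template adjacency `A` (verified positive definite), assigns each
#' channel its ROI's latent signal plus independent channel noise,
#' physiological oscillations and drift, derives HbR as a scaled mirror of
#' HbO, converts to optical density through the forward modified
#' Beer-Lambert model, optionally injects motion spikes, and exponentiates
#' to raw intensities — so the full preprocessing chain can be exercised
#' end to end. The latent signals are low-pass-filtered noise
#' (`latentCutoffHz`), mirroring the concentration of spontaneous
#' hemodynamic fluctuations at low frequencies; the mixing is applied
#' after filtering, so the pairwise correlation structure holds across the
#' whole spectrum. The clean per-channel HbO and the latent ROI signals
#' are attached as attribute `"truth"`.
#'
#' @param template a `NetworkTemplate` from [generateNetworkTemplate()].
#' @param noise a `NoiseSpec` (default [noiseSpec()]).
#' @param channelMap channel map from [defaultChannelMap()]; its ROIs (in
#'   [roiOrder()]) must match the template's node count.
#' @param duration recording length in seconds (default 300).
#' @param samplingRate sampling frequency in Hz (default 11).
#' @param seed integer seed.
#' @param latentSd SD of the latent ROI HbO fluctuation (uM, default 0.5).
#' @param latentCutoffHz low-pass cutoff shaping the latent (and global)
#'   signal spectrum (Hz, default 0.2).
#' @param globalSd SD of a slow systemic component shared by every ROI
#'   (uM, default 0.2). Emulates global superficial/systemic physiology,
#'   which in real fNIRS shifts all pairwise correlations positive.
#' @param hbrRatio HbR change per unit HbO change (default -1/3).
#' @param coeffs forward-model coefficients from [mbllCoefficients()].
#' @param sdDistance source-detector separation in cm (default 3).
#' @param baselineIntensity mean raw intensity in device units.
#' @return an [OpticalRecording-class] with attribute `"truth"`: a list
#'   with `latent` (ROI x time), `hboClean` (channel x time) and
#'   `adjacency`.
#' @export
generateFnirsRecording <- function(template, noise = noiseSpec(),
                                   channelMap = defaultChannelMap(),
                                   duration = 300, samplingRate = 11,
                                   seed = 1, latentSd = 0.5,
                                   latentCutoffHz = 0.2,
                                   globalSd = 0.2,
                                   hbrRatio = -1 / 3,
                                   coeffs = mbllCoefficients(),
                                   sdDistance = 3,
                                   baselineIntensity = 1000) {
  checkPositiveScalar(duration, "duration")
  rois <- .roiOrder[.roiOrder %in% unique(channelMap$roi)]
  if (length(rois) != template$nNodes)
    stop("channel map ROIs must match the template's node count",
      call. = FALSE
    )
  n <- round(duration * samplingRate)
  nch <- nrow(channelMap)
  w <- if (!is.null(template$weighted)) template$weighted else
    template$adjacency
  sigma <- diag(template$nNodes) + template$coupling * w
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("implied latent covariance is not positive definite; ",
      "reduce coupling",
      call. = FALSE
    )
  cholS <- chol(sigma)
  tt <- (seq_len(n) - 1) / samplingRate

  slowNoise <- function(m) {
    # unit-SD low-pass noise emulating the slow hemodynamic spectrum
    z <- matrix(stats::rnorm(m * n), m, n)
    if (latentCutoffHz > 0 && latentCutoffHz < samplingRate / 2) {
      bf <- .butterDesign(2, latentCutoffHz / (samplingRate / 2), "low")
      z <- t(apply(z, 1, function(v) .zeroPhase(bf, v)))
      z <- z / apply(z, 1, stats::sd)
    }
    z
  }
  rec <- withSeed(seed, {
    latent <- latentSd * crossprod(cholS, slowNoise(template$nNodes))
    if (globalSd > 0) {
      latent <- sweep(latent, 2, globalSd * slowNoise(1)[1, ], "+")
    }
    rownames(latent) <- rois

    # systemic oscillations (Mayer, respiration, cardiac) are coherent
    # across the scalp: one phase per component per recording
    oscPhases <- stats::runif(nrow(noise$oscillations), 0, 2 * pi)
    hboClean <- matrix(0, nch, n)
    hboM <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      r <- channelMap$roi[channelMap$channel == ch]
      base <- latent[r, ]
      hboClean[ch, ] <- base
      x <- base + noise$channelNoiseSd * stats::rnorm(n)
      if (nrow(noise$oscillations)) {
        for (o in seq_len(nrow(noise$oscillations))) {
          x <- x + noise$oscillations$amplitude[o] *
            sin(2 * pi * noise$oscillations$freq[o] * tt + oscPhases[o])
        }
      }
      if (noise$driftSd > 0)
        x <- x + stats::rnorm(1, 0, noise$driftSd) * tt / 60
      hboM[ch, ] <- x
    }
    hbrM <- hbrRatio * hboM
    od <- hemoglobinToOd(hboM, hbrM, coeffs, sdDistance)
    if (noise$spikeRate > 0 && noise$spikeAmplitude > 0) {
      spikeLen <- max(1L, round(0.3 * samplingRate))
      for (ch in seq_len(nch)) {
        nSpk <- stats::rpois(1, noise$spikeRate * duration / 60)
        if (nSpk == 0) next
        starts <- sample.int(max(1, n - spikeLen), nSpk, replace = TRUE)
        for (s in starts) {
          idx <- s:min(n, s + spikeLen - 1)
          sgn <- sample(c(-1, 1), 1)
          for (wl in 1:2) {
            amp <- noise$spikeAmplitude * stats::sd(od[ch, wl, ])
            od[ch, wl, idx] <- od[ch, wl, idx] + sgn * amp
          }
        }
      }
    }
    intensity <- baselineIntensity * 10^(-od)
    out <- new("OpticalRecording",
      intensity = intensity, wavelengths = c(730, 850),
      samplingRate = samplingRate,
      sdDistance = rep_len(sdDistance, nch)
    )
    attr(out, "truth") <- list(
      latent = latent, hboClean = hboClean,
      adjacency = template$adjacency
    )
    out
  })
  rec
}
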
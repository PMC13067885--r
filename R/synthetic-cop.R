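#' Parameters of the synthetic COP process
#'
#' The synthetic center-of-pressure trajectory is a discretized
#' two-dimensional mean-reverting (Ornstein-Uhlenbeck) random walk,
#' `x <- x - restoringRate * x * dt + diffusion * sqrt(dt) * eps`,
#' one independent process per axis. Mean reversion keeps 30 s trials
#' stationary, mirroring the bounded nature of quiet-standing sway; the
#' stationary per-axis SD is `diffusion / sqrt(2 * restoringRate)`. The
#' default diffusions (5 mm/sqrt(s) ML, 8 mm/sqrt(s) AP with unit restoring
#' rate) give stationary SDs of about 3.5 and 5.7 mm, the magnitude of RMS
#' sway typically reported for older adults.
#'
#' @param restoringRate mean-reversion rate in 1/s, recycled to both axes.
#' @param diffusion diffusion coefficient in mm/sqrt(s), `c(ML, AP)`.
#' @param samplingRate sampling frequency in Hz (default 1000).
#' @param duration trial length in seconds (default 30).
#' @return validated parameter list.
#' @export
copGenParams <- function(restoringRate = c(1, 1), diffusion = c(5, 8),
                         samplingRate = 1000, duration = 30) {
  restoringRate <- rep_len(restoringRate, 2)
  diffusion <- rep_len(diffusion, 2)
  if (any(diffusion < 0)) stop("diffusion must be >= 0", call. = FALSE)
  if (any(restoringRate <= 0))
    stop("restoringRate must be > 0", call. = FALSE)
  checkPositiveScalar(samplingRate, "samplingRate")
  checkPositiveScalar(duration, "duration")
  list(
    restoringRate = restoringRate, diffusion = diffusion,
    samplingRate = samplingRate, duration = duration
  )
}

# One axis of the Euler-discretized OU process, started at the origin.
.ouSeries <- function(n, theta, sigma, dt) {
  if (sigma == 0) return(numeric(n))
  innov <- sigma * sqrt(dt) * stats::rnorm(n)
  as.numeric(stats::filter(innov, 1 - theta * dt, method = "recursive"))
}

#' Generate one synthetic COP trial
#'
#' Draws a two-axis mean-reverting random-walk trajectory reproducibly
#' from a seed. With zero diffusion the trajectory is constant at the
#' origin (sway area and velocity are 0).
#'
#' @param params from [copGenParams()].
#' @param seed integer seed.
#' @param visualCondition,trialIndex,participantId trial labels.
#' @return a [CopTrial-class].
#' @examples
#' tr <- generateCopTrial(copGenParams(duration = 2), seed = 7)
#' copMetrics(tr)
#' @export
generateCopTrial <- function(params = copGenParams(), seed = 1,
                             visualCondition = "open", trialIndex = 1L,
                             participantId = "P01") {
  n <- round(params$duration * params$samplingRate)
  dt <- 1 / params$samplingRate
  xy <- withSeed(seed, list(
    ml = .ouSeries(n, params$restoringRate[1], params$diffusion[1], dt),
    ap = .ouSeries(n, params$restoringRate[2], params$diffusion[2], dt)
  ))
  copTrial(xy$ml, xy$ap,
    samplingRate = params$samplingRate,
    visualCondition = visualCondition, trialIndex = trialIndex,
    participantId = participantId
  )
}
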
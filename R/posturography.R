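#' Construct a CopTrial
#'
#' @param ml,ap numeric displacement series in mm (medio-lateral and
#'   anterior-posterior axes).
#' @param samplingRate sampling frequency in Hz.
#' @param visualCondition `"open"` or `"closed"`.
#' @param trialIndex trial number within the condition.
#' @param participantId participant identifier.
#' @return a [CopTrial-class] object.
#' @examples
#' tr <- copTrial(sin(1:100 / 10), cos(1:100 / 10), samplingRate = 100)
#' copMetrics(tr, filter = FALSE)
#' @export
copTrial <- function(ml, ap, samplingRate = 1000, visualCondition = "open",
                     trialIndex = 1L, participantId = "P01") {
  new("CopTrial",
    ml = as.numeric(ml), ap = as.numeric(ap),
    samplingRate = samplingRate, visualCondition = visualCondition,
    trialIndex = as.integer(trialIndex), participantId = participantId
  )
}

#' Zero-phase Butterworth low-pass filtering of a COP trial
#'
#' Smooths both displacement axes with a low-pass Butterworth filter applied
#' forward and backward (zero phase lag). The default 10 Hz cutoff keeps the
#' postural-sway band while removing measurement noise.
#'
#' @param trial a [CopTrial-class].
#' @param cutoffHz low-pass cutoff in Hz; must be below the Nyquist
#'   frequency.
#' @param order filter order before the forward-backward pass (default 4).
#' @return the filtered [CopTrial-class], same length.
#' @export
filterCop <- function(trial, cutoffHz = 10, order = 4) {
  stopifnot(is(trial, "CopTrial"))
  fs <- trial@samplingRate
  if (cutoffHz >= fs / 2)
    stop("cutoffHz must be below the Nyquist frequency ", fs / 2, call. = FALSE)
  checkPositiveScalar(cutoffHz, "cutoffHz")
  bf <- .butterDesign(order, cutoffHz / (fs / 2), "low")
  trial@ml <- .zeroPhase(bf, trial@ml)
  trial@ap <- .zeroPhase(bf, trial@ap)
  validObject(trial)
  trial
}

#' RMS displacement of a COP trial
#'
#' Root-mean-square displacement about the trial mean, per axis and
#' resultant: `ML_RMS = sqrt(mean((ml - mean(ml))^2))`, AP analogously, and
#' `RMS = sqrt(ML_RMS^2 + AP_RMS^2)`.
#'
#' @param trial a [CopTrial-class] (normally already filtered).
#' @return named numeric vector `c(RMS, ML_RMS, AP_RMS)` in mm.
#' @export
copRms <- function(trial) {
  stopifnot(is(trial, "CopTrial"))
  mlr <- sqrt(mean((trial@ml - mean(trial@ml))^2))
  apr <- sqrt(mean((trial@ap - mean(trial@ap))^2))
  c(RMS = sqrt(mlr^2 + apr^2), ML_RMS = mlr, AP_RMS = apr)
}

#' Mean velocity of a COP trial
#'
#' Path length per unit time. The resultant velocity sums Euclidean step
#' lengths; per-axis velocities sum absolute increments. Time base is
#' `T = (n - 1) / samplingRate`, so a constant-speed path yields its exact
#' speed.
#'
#' @param trial a [CopTrial-class].
#' @return named numeric vector `c(V, ML_V, AP_V)` in mm/s.
#' @export
copVelocity <- function(trial) {
  stopifnot(is(trial, "CopTrial"))
  n <- length(trial@ml)
  if (n < 2) stop("at least 2 samples required", call. = FALSE)
  dml <- diff(trial@ml)
  dap <- diff(trial@ap)
  tt <- (n - 1) / trial@samplingRate
  c(
    V = sum(sqrt(dml^2 + dap^2)) / tt,
    ML_V = sum(abs(dml)) / tt,
    AP_V = sum(abs(dap)) / tt
  )
}

# 0.95 quantile of chi-square with 2 df; scales the covariance ellipse.
.ellipseQuantile <- 5.991465

#' 95% confidence-ellipse sway area
#'
#' Area of the 95% covariance-based confidence ellipse of the (ML, AP)
#' point cloud: `AREA = pi * q * sqrt(det(S))` with `S` the 2x2 sample
#' covariance and `q = 5.991465`, the 0.95 quantile of the chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param trial a [CopTrial-class].
#' @return sway area in mm^2. A degenerate (collinear or constant) point
#'   cloud returns 0 with a warning.
#' @export
copSwayArea <- function(trial) {
  stopifnot(is(trial, "CopTrial"))
  s <- stats::cov(cbind(trial@ml, trial@ap))
  dt <- det(s)
  if (!is.finite(dt) || dt <= 0) {
    warning("degenerate COP covariance; sway area set to 0", call. = FALSE)
    return(0)
  }
  pi * .ellipseQuantile * sqrt(dt)
}

#' All seven balance indices for one trial
#'
#' Convenience wrapper computing sway area, mean velocities and RMS
#' displacements on an (optionally low-pass filtered) trial.
#'
#' @param trial a [CopTrial-class].
#' @param filter apply [filterCop()] first (default `TRUE`).
#' @param cutoffHz,order passed to [filterCop()].
#' @return named numeric vector
#'   `c(AREA, ML_V, AP_V, V, ML_RMS, AP_RMS, RMS)`.
#' @export
copMetrics <- function(trial, filter = TRUE, cutoffHz = 10, order = 4) {
  if (filter) trial <- filterCop(trial, cutoffHz, order)
  v <- copVelocity(trial)
  r <- copRms(trial)
  c(
    AREA = copSwayArea(trial),
    ML_V = unname(v["ML_V"]), AP_V = unname(v["AP_V"]), V = unname(v["V"]),
    ML_RMS = unname(r["ML_RMS"]), AP_RMS = unname(r["AP_RMS"]),
    RMS = unname(r["RMS"])
  )
}

#' Average balance indices across trials
#'
#' Arithmetic mean of each index over the repeated trials of one
#' participant-condition cell. Note the per-trial identity
#' `RMS^2 = ML_RMS^2 + AP_RMS^2` need not hold after averaging.
#'
#' @param metricsList non-empty list of vectors as returned by
#'   [copMetrics()].
#' @return named numeric vector of the same layout.
#' @export
aggregateTrials <- function(metricsList) {
  if (!length(metricsList)) stop("empty metrics list", call. = FALSE)
  m <- do.call(rbind, metricsList)
  colMeans(m)
}

#' Read / write COP trials as CSV
#'
#' Plain CSV with columns `time_s`, `ml_mm`, `ap_mm`.
#'
#' @param trial a [CopTrial-class].
#' @param path file path.
#' @param ... labels passed to [copTrial()] when reading.
#' @return `readCopTrialCsv` returns a [CopTrial-class];
#'   `writeCopTrialCsv` returns `path` invisibly.
#' @export
writeCopTrialCsv <- function(trial, path) {
  n <- length(trial@ml)
  utils::write.csv(
    data.frame(
      time_s = (seq_len(n) - 1) / trial@samplingRate,
      ml_mm = trial@ml, ap_mm = trial@ap
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeCopTrialCsv
#' @export
readCopTrialCsv <- function(path, ...) {
  d <- utils::read.csv(path)
  need <- c("time_s", "ml_mm", "ap_mm")
  if (!all(need %in% names(d)))
    stop("COP CSV must have columns time_s, ml_mm, ap_mm", call. = FALSE)
  fs <- 1 / stats::median(diff(d$time_s))
  copTrial(d$ml_mm, d$ap_mm, samplingRate = fs, ...)
}
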
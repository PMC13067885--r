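# Fixed ROI ordering used for every connectivity matrix and nodal output.
.roiOrder <- c(
  "L_PFC", "R_PFC", "L_S1", "R_S1", "L_M1", "R_M1",
  "L_PMC", "R_PMC", "L_V", "R_V"
)

# Expected channel counts per ROI for the shipped 48-channel montage.
.roiCounts <- c(
  L_PFC = 10L, R_PFC = 9L, L_S1 = 3L, R_S1 = 3L, L_M1 = 2L, R_M1 = 2L,
  L_PMC = 5L, R_PMC = 5L, L_V = 5L, R_V = 4L
)

#' Canonical ROI ordering
#'
#' The fixed order of the ten cortical regions of interest used throughout:
#' left/right prefrontal (PFC), primary somatosensory (S1), primary motor
#' (M1), premotor and supplementary motor (PMC), and visual (V) cortex.
#'
#' @return character vector of 10 ROI labels.
#' @export
roiOrder <- function() .roiOrder

#' Channel-to-ROI map of the 48-channel montage
#'
#' Loads the shipped montage table assigning each of the 48 measurement
#' channels to one of the 10 ROIs, and validates it: 48 channels, each
#' mapped once, with per-ROI channel counts (10, 9, 3, 3, 2, 2, 5, 5, 5, 4)
#' in the canonical [roiOrder()].
#'
#' @param path optional path to an alternative map CSV with columns
#'   `channel`, `hemisphere`, `region`, `roi`.
#' @return data.frame with columns `channel`, `hemisphere`, `region`,
#'   `roi`.
#' @examples
#' map <- defaultChannelMap()
#' table(map$roi)[roiOrder()]
#' @export
defaultChannelMap <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "channel_roi_map.csv",
      package = "fnirsBalance", mustWork = TRUE
    )
    strict <- TRUE
  } else {
    strict <- FALSE
  }
  map <- utils::read.csv(path)
  need <- c("channel", "hemisphere", "region", "roi")
  if (!all(need %in% names(map)))
    stop("channel map needs columns channel, hemisphere, region, roi",
      call. = FALSE
    )
  if (anyDuplicated(map$channel))
    stop("each channel must be mapped exactly once", call. = FALSE)
  if (strict) {
    if (!identical(sort(map$channel), 1:48))
      stop("default map must cover channels 1..48", call. = FALSE)
    counts <- table(factor(map$roi, levels = .roiOrder))
    if (!all(as.integer(counts) == as.integer(.roiCounts[.roiOrder])))
      stop("default map ROI counts are corrupted", call. = FALSE)
  }
  map
}

#' Average channels into ROI time series
#'
#' Each ROI series is the arithmetic mean of the HbO series of the usable
#' channels assigned to it; channels listed in `badChannels(hemo)` are
#' excluded before averaging. Rows follow the canonical [roiOrder()].
#'
#' @param hemo a [HemoRecording-class].
#' @param map channel map from [defaultChannelMap()].
#' @return numeric ROI x time matrix with ROI row names.
#' @export
roiAverage <- function(hemo, map = defaultChannelMap()) {
  stopifnot(is(hemo, "HemoRecording"))
  rois <- unique(map$roi)
  rois <- .roiOrder[.roiOrder %in% rois]
  out <- matrix(0, length(rois), ncol(hemo@hbo),
    dimnames = list(rois, NULL)
  )
  for (r in rois) {
    chans <- map$channel[map$roi == r]
    chans <- setdiff(chans, hemo@badChannels)
    if (!length(chans))
      stop("ROI ", r, " has no usable channels", call. = FALSE)
    out[r, ] <- colMeans(hemo@hbo[chans, , drop = FALSE])
  }
  out
}

#' Fisher-z functional-connectivity matrix
#'
#' Pearson correlation between every pair of ROI series; negative
#' correlations are set to 0, then values are Fisher z-transformed
#' (`atanh`, with r clipped at 0.999999 so near-duplicate series stay
#' finite). The diagonal is 0 by convention.
#'
#' @param roi ROI x time matrix as returned by [roiAverage()].
#' @return an [FcMatrix-class].
#' @export
connectivityMatrix <- function(roi) {
  if (!is.matrix(roi) || ncol(roi) < 3)
    stop("need an ROI x time matrix with at least 3 time points",
      call. = FALSE
    )
  sds <- apply(roi, 1, stats::sd)
  if (any(sds == 0)) {
    nm <- rownames(roi)[which(sds == 0)]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant ROI series: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(roi))
  r[r < 0] <- 0
  r <- pmin(r, 0.999999)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  new("FcMatrix", z = z)
}

#' Write an FcMatrix as labelled CSV
#'
#' @param fc an [FcMatrix-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeFcMatrixCsv <- function(fc, path) {
  utils::write.csv(as.matrix(fc), path, row.names = TRUE)
  invisible(path)
}
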
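#' Design of a synthetic two-group, two-condition cohort
#'
#' Describes the 2 (group: MCI, CN) x 2 (visual condition: eyes open, eyes
#' closed) x 3 (trial) cohort the generator emulates, with known
#' ground-truth effect structure. Per-cell effect multipliers act on the
#' COP diffusion coefficient (sway magnitude) and on the latent network's
#' randomization (rewiring extent of the small-world template). The
#' defaults reproduce the qualitative orderings of the study conditions:
#' sway largest and network most randomized in MCI with eyes closed.
#' Setting all multipliers to 1 yields a null cohort.
#'
#' @param nPerGroup participants per group (default 34).
#' @param groups,conditions factor levels (defaults `c("MCI", "CN")`,
#'   `c("open", "closed")`).
#' @param trialsPerCondition COP trials per participant and condition
#'   (default 3).
#' @param diffusionMultipliers named numeric, one multiplier per
#'   `group.condition` cell applied to the COP diffusion.
#' @param randomizationMultipliers named numeric per cell; multiplies the
#'   base rewiring probability of the network template (capped at 1).
#' @param copParams base COP process parameters from [copGenParams()].
#' @param noise fNIRS noise from [noiseSpec()].
#' @param coupling latent network coupling strength (default 0.4).
#' @param baseRewireProb small-world template rewiring probability before
#'   cell multipliers (default 0.1).
#' @param fnirsDuration per-condition fNIRS recording length in s
#'   (default 300).
#' @param participantSdLog SD of the log-normal participant trait
#'   multiplier on diffusion (between-subject variability, default 0.15).
#' @param conditionSdLog SD of the log-normal state multiplier drawn per
#'   participant-condition (default 0.08).
#' @param masterSeed integer master seed; all unit seeds derive from it.
#' @return validated list of class `CohortDesign`.
#' @export
cohortDesign <- function(nPerGroup = 34, groups = c("MCI", "CN"),
                         conditions = c("open", "closed"),
                         trialsPerCondition = 3,
                         diffusionMultipliers = c(
                           MCI.open = 1.05, MCI.closed = 1.5,
                           CN.open = 1.0, CN.closed = 1.15
                         ),
                         randomizationMultipliers = c(
                           MCI.open = 1.5, MCI.closed = 6,
                           CN.open = 1.0, CN.closed = 2.5
                         ),
                         copParams = copGenParams(),
                         noise = noiseSpec(),
                         coupling = 0.4, baseRewireProb = 0.1,
                         fnirsDuration = 300,
                         participantSdLog = 0.15, conditionSdLog = 0.08,
                         masterSeed = 1) {
  if (nPerGroup < 1 || trialsPerCondition < 1)
    stop("counts must be positive", call. = FALSE)
  cells <- as.vector(outer(groups, conditions, paste, sep = "."))
  for (nm in c("diffusionMultipliers", "randomizationMultipliers")) {
    m <- get(nm)
    if (!all(cells %in% names(m)))
      stop(nm, " must name every group.condition cell", call. = FALSE)
    if (any(m < 0)) stop(nm, " must be >= 0", call. = FALSE)
  }
  out <- list(
    nPerGroup = nPerGroup, groups = groups, conditions = conditions,
    trialsPerCondition = trialsPerCondition,
    diffusionMultipliers = diffusionMultipliers,
    randomizationMultipliers = randomizationMultipliers,
    copParams = copParams, noise = noise, coupling = coupling,
    baseRewireProb = baseRewireProb, fnirsDuration = fnirsDuration,
    participantSdLog = participantSdLog, conditionSdLog = conditionSdLog,
    masterSeed = masterSeed
  )
  class(out) <- "CohortDesign"
  out
}

#' Null-cohort convenience design
#'
#' A [cohortDesign()] with every cell multiplier set to 1 (no true
#' group-by-condition effects), for type-I-error calibration.
#'
#' @param ... overrides passed to [cohortDesign()].
#' @return a `CohortDesign`.
#' @export
nullCohortDesign <- function(...) {
  flat <- c(
    MCI.open = 1, MCI.closed = 1, CN.open = 1, CN.closed = 1
  )
  cohortDesign(
    diffusionMultipliers = flat, randomizationMultipliers = flat, ...
  )
}

#' Generate a synthetic cohort dataset
#'
#' Produces, per participant and condition, the requested COP trials and
#' one synthetic fNIRS recording, applying the design's per-cell effect
#' multipliers. Participant traits, condition states, templates and every
#' trial stream use seeds derived from the master seed, so identical
#' designs yield bitwise-identical datasets.
#'
#' @param design a `CohortDesign`.
#' @param include which modalities to generate: subset of
#'   `c("cop", "fnirs")` (default both; generating only `"cop"` is much
#'   faster for behavioral-only simulations).
#' @param channelMap channel map for the fNIRS forward model.
#' @return list of class `CohortDataset` with elements `design`,
#'   `participants` (data.frame id, group) and `data`, a nested list
#'   `data[[participantId]][[condition]]` with `cop` (list of
#'   [CopTrial-class]) and `fnirs` ([OpticalRecording-class] or `NULL`).
#' @examples
#' ds <- generateCohort(
#'   nullCohortDesign(nPerGroup = 2,
#'     copParams = copGenParams(duration = 2, samplingRate = 100)),
#'   include = "cop"
#' )
#' length(ds$data) # 4 participants
#' @export
generateCohort <- function(design, include = c("cop", "fnirs"),
                           channelMap = defaultChannelMap()) {
  stopifnot(inherits(design, "CohortDesign"))
  include <- match.arg(include, several.ok = TRUE)
  nTot <- design$nPerGroup * length(design$groups)
  ids <- sprintf("P%03d", seq_len(nTot))
  grp <- rep(design$groups, each = design$nPerGroup)
  participants <- data.frame(id = ids, group = grp)
  data <- vector("list", nTot)
  names(data) <- ids
  for (p in seq_len(nTot)) {
    trait <- withSeed(
      deriveSeed(design$masterSeed, p, 900),
      exp(stats::rnorm(1, 0, design$participantSdLog))
    )
    perCond <- list()
    for (ci in seq_along(design$conditions)) {
      cond <- design$conditions[ci]
      cell <- paste(grp[p], cond, sep = ".")
      state <- withSeed(
        deriveSeed(design$masterSeed, p, ci, 901),
        exp(stats::rnorm(1, 0, design$conditionSdLog))
      )
      entry <- list(cop = NULL, fnirs = NULL)
      if ("cop" %in% include) {
        mult <- design$diffusionMultipliers[[cell]] * trait * state
        pars <- design$copParams
        pars$diffusion <- pars$diffusion * mult
        entry$cop <- lapply(seq_len(design$trialsPerCondition), function(tr) {
          generateCopTrial(pars,
            seed = deriveSeed(design$masterSeed, p, ci, tr),
            visualCondition = cond, trialIndex = tr,
            participantId = ids[p]
          )
        })
      }
      if ("fnirs" %in% include) {
        rw <- min(1, design$baseRewireProb *
          design$randomizationMultipliers[[cell]])
        tpl <- generateNetworkTemplate(
          kind = "smallworld", rewireProb = rw,
          coupling = design$coupling,
          seed = deriveSeed(design$masterSeed, p, ci, 902)
        )
        entry$fnirs <- generateFnirsRecording(
          tpl,
          noise = design$noise, channelMap = channelMap,
          duration = design$fnirsDuration,
          seed = deriveSeed(design$masterSeed, p, ci, 903)
        )
        entry$template <- tpl
      }
      perCond[[cond]] <- entry
    }
    data[[p]] <- perCond
  }
  out <- list(design = design, participants = participants, data = data)
  class(out) <- "CohortDataset"
  out
}

#' @export
print.CohortDataset <- function(x, ...) {
  cat(sprintf(
    "CohortDataset: %d participants (%s), conditions %s, %d COP trials/condition\n",
    nrow(x$participants),
    paste(table(x$participants$group), collapse = "/"),
    paste(x$design$conditions, collapse = ", "),
    x$design$trialsPerCondition
  ))
  invisible(x)
}

#' Balance indices for every participant-condition cell of a cohort
#'
#' Runs [copMetrics()] on each trial and [aggregateTrials()] within each
#' participant-condition cell.
#'
#' @param dataset a `CohortDataset` generated with `"cop"` included.
#' @param filter,cutoffHz passed to [copMetrics()].
#' @return long data.frame: participant, group, condition, metric, value.
#' @export
cohortCopTable <- function(dataset, filter = TRUE, cutoffHz = 10) {
  rows <- list()
  for (p in seq_len(nrow(dataset$participants))) {
    id <- dataset$participants$id[p]
    for (cond in dataset$design$conditions) {
      trials <- dataset$data[[id]][[cond]]$cop
      if (is.null(trials)) stop("cohort has no COP data", call. = FALSE)
      agg <- aggregateTrials(lapply(trials, copMetrics,
        filter = filter, cutoffHz = cutoffHz
      ))
      rows[[length(rows) + 1]] <- data.frame(
        participant = id, group = dataset$participants$group[p],
        condition = cond, metric = names(agg), value = unname(agg)
      )
    }
  }
  do.call(rbind, rows)
}
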
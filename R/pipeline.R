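#' Configuration of an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read a
#'   manifest of CSV inputs).
#' @param design a `CohortDesign` for synthetic mode.
#' @param manifest in files mode, path to a CSV with columns
#'   `participant`, `group`, `condition`, `cop_files`
#'   (semicolon-separated trial CSV paths) and `fnirs_file`.
#' @param channelMap channel map (default [defaultChannelMap()]).
#' @param grid sparsity thresholds from [sparsityGrid()].
#' @param nRand null networks per threshold (default 100).
#' @param seed integer seed for network null ensembles.
#' @param cutoffHz COP low-pass cutoff.
#' @param preprocessArgs list of overrides for [preprocessRecording()].
#' @param adaptGridMin raise the grid minimum to the cohort's minimum
#'   connected sparsity when the configured minimum is too low (default
#'   `TRUE`).
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(mode = c("synthetic", "files"),
                      design = cohortDesign(), manifest = NULL,
                      channelMap = defaultChannelMap(),
                      grid = sparsityGrid(), nRand = 100, seed = 1,
                      cutoffHz = 10, preprocessArgs = list(),
                      adaptGridMin = TRUE) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(manifest) || !file.exists(manifest))
      stop("files mode needs an existing manifest CSV", call. = FALSE)
  }
  out <- list(
    mode = mode, design = design, manifest = manifest,
    channelMap = channelMap, grid = grid, nRand = nRand, seed = seed,
    cutoffHz = cutoffHz, preprocessArgs = preprocessArgs,
    adaptGridMin = adaptGridMin
  )
  class(out) <- "RunConfig"
  out
}

# Load file-mode inputs into the same nested structure generateCohort uses.
.loadFilesCohort <- function(config) {
  man <- utils::read.csv(config$manifest)
  need <- c("participant", "group", "condition", "cop_files", "fnirs_file")
  if (!all(need %in% names(man)))
    stop("manifest needs columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  ids <- unique(man$participant)
  participants <- unique(man[, c("participant", "group")])
  names(participants) <- c("id", "group")
  data <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    copPaths <- strsplit(row$cop_files, ";")[[1]]
    entry <- list(
      cop = lapply(seq_along(copPaths), function(k) {
        readCopTrialCsv(trimws(copPaths[k]),
          visualCondition = row$condition, trialIndex = k,
          participantId = row$participant
        )
      }),
      fnirs = readOpticalRecordingCsv(row$fnirs_file)
    )
    data[[row$participant]][[row$condition]] <- entry
  }
  list(
    design = NULL, participants = participants[match(ids, participants$id), ],
    data = data,
    conditions = unique(man$condition)
  )
}

#' Run the full balance/brain-network pipeline
#'
#' Orchestrates generation (or file ingestion), posturography, fNIRS
#' preprocessing, ROI connectivity, graph-metric AUCs over the sparsity
#' sweep, and the statistical layer (mixed ANOVA per metric with partial
#' eta squared, simple effects where the interaction is significant,
#' Bonferroni across the three global network metrics and FDR across the
#' ten nodal-efficiency ROIs, and brain-behavior correlations of sway area
#' and AP-RMS with sigma and R_S1 nodal efficiency per group and
#' condition). Deterministic for a fixed config.
#'
#' @param config a `RunConfig`.
#' @param verbose print stage progress (default `FALSE`).
#' @return list of class `ReportBundle`: `copTable`, `aucTable`,
#'   `anovaCop`, `anovaNetwork`, `simpleEffects`, `correlations`,
#'   `manifest`.
#' @export
runPipeline <- function(config = runConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  if (config$mode == "synthetic") {
    say("generating synthetic cohort")
    dataset <- generateCohort(config$design, channelMap = config$channelMap)
    conditions <- config$design$conditions
  } else {
    say("loading file inputs")
    dataset <- .loadFilesCohort(config)
    conditions <- dataset$conditions
  }
  participants <- dataset$participants

  say("posturography")
  copRows <- list()
  for (p in seq_len(nrow(participants))) {
    id <- participants$id[p]
    for (cond in conditions) {
      trials <- dataset$data[[id]][[cond]]$cop
      agg <- aggregateTrials(
        lapply(trials, copMetrics, cutoffHz = config$cutoffHz)
      )
      copRows[[length(copRows) + 1]] <- data.frame(
        participant = id, group = participants$group[p],
        condition = cond, metric = names(agg), value = unname(agg)
      )
    }
  }
  copTable <- do.call(rbind, copRows)

  say("fNIRS preprocessing and connectivity")
  fcIndex <- list()
  fcList <- list()
  for (p in seq_len(nrow(participants))) {
    id <- participants$id[p]
    for (cond in conditions) {
      rec <- dataset$data[[id]][[cond]]$fnirs
      hemo <- do.call(preprocessRecording,
        c(list(rec = rec), config$preprocessArgs)
      )
      fc <- connectivityMatrix(roiAverage(hemo, config$channelMap))
      fcList[[length(fcList) + 1]] <- fc
      fcIndex[[length(fcIndex) + 1]] <- data.frame(
        participant = id, group = participants$group[p], condition = cond
      )
    }
  }
  fcIndex <- do.call(rbind, fcIndex)

  say("network topology")
  grid <- config$grid
  sMin <- max(vapply(seq_along(fcList), function(i) {
    tryCatch(minConnectedSparsity(fcList[[i]]), error = function(e) {
      stop(
        "connectivity stage failed for participant ",
        fcIndex$participant[i], " (", fcIndex$condition[i], "): ",
        conditionMessage(e),
        call. = FALSE
      )
    })
  }, numeric(1)))
  if (config$adaptGridMin && sMin > grid[1] + 1e-9) {
    step <- if (length(grid) > 1) grid[2] - grid[1] else 0.01
    if (sMin > max(grid)) {
      warning(
        "minimum connected sparsity ", signif(sMin, 4),
        " exceeds the configured sweep; evaluating at that single ",
        "threshold",
        call. = FALSE
      )
      grid <- sparsityGrid(sMin, sMin, step)
    } else {
      grid <- sparsityGrid(sMin, max(grid), step)
    }
  }
  aucRows <- list()
  for (i in seq_along(fcList)) {
    ms <- networkMetrics(fcList[[i]],
      grid = grid, nRand = config$nRand,
      seed = deriveSeed(config$seed, i)
    )
    glob <- data.frame(
      fcIndex[i, ], metric = c("sigma", "eg", "eloc"), roi = NA,
      value = c(ms$sigmaAuc, ms$egAuc, ms$elocAuc), row.names = NULL
    )
    nod <- data.frame(
      fcIndex[i, ], metric = "ne", roi = names(ms$neAuc),
      value = unname(ms$neAuc), row.names = NULL
    )
    aucRows[[length(aucRows) + 1]] <- rbind(glob, nod)
  }
  aucTable <- do.call(rbind, aucRows)
  rownames(aucTable) <- NULL

  say("statistics")
  runAnova <- function(tab) {
    d <- data.frame(
      participant = tab$participant, group = tab$group,
      condition = tab$condition, value = tab$value
    )
    mixedAnova2x2(d)
  }
  anovaCop <- do.call(rbind, lapply(
    split(copTable, copTable$metric),
    function(tab) cbind(metric = tab$metric[1], runAnova(tab))
  ))
  rownames(anovaCop) <- NULL

  globalTabs <- split(
    aucTable[aucTable$metric != "ne", ],
    aucTable$metric[aucTable$metric != "ne"]
  )
  nodalTabs <- split(
    aucTable[aucTable$metric == "ne", ],
    aucTable$roi[aucTable$metric == "ne"]
  )
  anovaNetwork <- rbind(
    do.call(rbind, lapply(names(globalTabs), function(m) {
      cbind(metric = m, roi = NA, runAnova(globalTabs[[m]]))
    })),
    do.call(rbind, lapply(names(nodalTabs), function(r) {
      cbind(metric = "ne", roi = r, runAnova(nodalTabs[[r]]))
    }))
  )
  rownames(anovaNetwork) <- NULL
  # multiplicity control: Bonferroni (m = 3) over global metrics, FDR over
  # the 10 ROIs of nodal efficiency, per effect
  anovaNetwork$pAdj <- NA_real_
  for (eff in unique(anovaNetwork$effect)) {
    gi <- which(anovaNetwork$metric != "ne" & anovaNetwork$effect == eff)
    anovaNetwork$pAdj[gi] <- bonferroniAdjust(anovaNetwork$p[gi], m = 3)
    ni <- which(anovaNetwork$metric == "ne" & anovaNetwork$effect == eff)
    anovaNetwork$pAdj[ni] <- fdrBH(anovaNetwork$p[ni])
  }

  se <- list()
  seSource <- rbind(
    cbind(copTable, roi = NA)[cbind(copTable, roi = NA)$metric == "AREA", ],
    aucTable[aucTable$metric == "sigma", c(names(fcIndex), "metric", "roi", "value")]
  )
  for (m in unique(seSource$metric)) {
    tab <- seSource[seSource$metric == m, ]
    at <- runAnova(tab)
    if (at$p[at$effect == "interaction"] < 0.05) {
      se[[length(se) + 1]] <- cbind(
        metric = m,
        simpleEffects(data.frame(
          participant = tab$participant, group = tab$group,
          condition = tab$condition, value = tab$value
        ))
      )
    }
  }
  seTable <- if (length(se)) do.call(rbind, se) else
    data.frame(
      metric = character(), family = character(), level = character(),
      estimate = numeric(), t = numeric(), df = numeric(),
      p = numeric(), pAdj = numeric()
    )

  corRows <- list()
  wide <- function(tab, m, r = NA) {
    sel <- tab$metric == m
    if (!is.na(r)) sel <- sel & !is.na(tab$roi) & tab$roi == r
    tab[sel, c("participant", "group", "condition", "value")]
  }
  behav <- list(AREA = wide(copTable, "AREA"),
    AP_RMS = wide(copTable, "AP_RMS")
  )
  brain <- list(sigma = wide(aucTable, "sigma"),
    ne_R_S1 = wide(aucTable, "ne", "R_S1")
  )
  for (bm in names(behav)) {
    for (nm in names(brain)) {
      for (g in unique(participants$group)) {
        for (cond in conditions) {
          x <- behav[[bm]]
          y <- brain[[nm]]
          x <- x[x$group == g & x$condition == cond, ]
          y <- y[y$group == g & y$condition == cond, ]
          y <- y[match(x$participant, y$participant), ]
          ct <- pearsonCorrTest(x$value, y$value)
          corRows[[length(corRows) + 1]] <- data.frame(
            behavioral = bm, network = nm, group = g, condition = cond,
            r = ct$r, n = ct$n, p = ct$p
          )
        }
      }
    }
  }
  correlations <- do.call(rbind, corRows)

  manifest <- list(
    seed = config$seed, nRand = config$nRand,
    grid = list(min = grid[1], max = grid[length(grid)],
      n = length(grid)
    ),
    minConnectedSparsity = sMin,
    mode = config$mode,
    nParticipants = nrow(participants),
    packageVersion = as.character(utils::packageVersion("fnirsBalance")),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    configJson = jsonlite::toJSON(
      list(
        mode = config$mode, nRand = config$nRand, seed = config$seed,
        grid = grid, cutoffHz = config$cutoffHz,
        masterSeed = if (!is.null(config$design))
          config$design$masterSeed else NA
      ),
      auto_unbox = TRUE, digits = NA
    )
  )

  out <- list(
    copTable = copTable, aucTable = aucTable, anovaCop = anovaCop,
    anovaNetwork = anovaNetwork, simpleEffects = seTable,
    correlations = correlations, manifest = manifest
  )
  class(out) <- "ReportBundle"
  out
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat(sprintf(
    "ReportBundle: %d participants, %d COP rows, %d AUC rows\n",
    x$manifest$nParticipants, nrow(x$copTable), nrow(x$aucTable)
  ))
  cat("ANOVA (network):\n")
  print(x$anovaNetwork[x$anovaNetwork$metric != "ne", ])
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes each table as CSV and the run manifest as JSON. Files are
#' written to a temporary name and renamed, so re-runs replace outputs
#' atomically. File names: `cop_metrics.csv`, `network_auc.csv`,
#' `anova_cop.csv`, `anova_network.csv`, `simple_effects.csv`,
#' `correlations.csv`, `manifest.json`.
#'
#' @param bundle a `ReportBundle`.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
writeReport <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ReportBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    cop_metrics.csv = bundle$copTable,
    network_auc.csv = bundle$aucTable,
    anova_cop.csv = bundle$anovaCop,
    anova_network.csv = bundle$anovaNetwork,
    simple_effects.csv = bundle$simpleEffects,
    correlations.csv = bundle$correlations
  )
  paths <- character()
  for (nm in names(tables)) {
    path <- file.path(dir, nm)
    tmp <- paste0(path, ".tmp")
    utils::write.csv(tables[[nm]], tmp, row.names = FALSE)
    file.rename(tmp, path)
    paths <- c(paths, path)
  }
  mpath <- file.path(dir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(bundle$manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, mpath)
  invisible(c(paths, mpath))
}
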
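#' Group summary for summary-statistics tests
#'
#' @param mean,sd,n group mean, standard deviation and size.
#' @return validated list.
#' @export
sampleSummary <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  list(mean = mean, sd = sd, n = n)
}

#' Two-sample t test from group summaries
#'
#' Independent-samples t test computed from per-group mean, SD and n.
#' The default pooled-variance form uses
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`; `welch = TRUE` gives the unequal-variance form with
#' Satterthwaite df.
#'
#' @param a,b group summaries from [sampleSummary()].
#' @param welch use the Welch form (default `FALSE`, pooled).
#' @return list `t`, `df`, `p` (two-sided).
#' @examples
#' pooledTTest(sampleSummary(67.26, 2.77, 34), sampleSummary(66.82, 3.30, 34))
#' @export
pooledTTest <- function(a, b, welch = FALSE) {
  se1 <- a$sd^2 / a$n
  se2 <- b$sd^2 / b$n
  if (welch) {
    se <- sqrt(se1 + se2)
    df <- (se1 + se2)^2 / (se1^2 / (a$n - 1) + se2^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 == 0) {
      if (a$mean != b$mean)
        stop("zero pooled variance with unequal means", call. = FALSE)
      return(list(t = 0, df = a$n + b$n - 2, p = 1))
    }
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  tval <- (a$mean - b$mean) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction (the default), i.e.
#' `chi^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @param correct apply the Yates continuity correction (default
#'   `FALSE`).
#' @return list `chisq`, `df`, `p`.
#' @examples
#' chisqTest2x2(matrix(c(12, 6, 22, 28), 2)) # sex distribution example
#' @export
chisqTest2x2 <- function(tbl, correct = FALSE) {
  tbl <- as.matrix(tbl)
  if (!identical(dim(tbl), c(2L, 2L)) || any(tbl < 0))
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    stop("zero marginal total", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tbl, correct = correct))
  list(
    chisq = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value
  )
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from each group's centre; the
#' default mean-centred variant matches the common default of mainstream
#' statistics software, `center = "median"` gives the Brown-Forsythe
#' variant.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor).
#' @param center `"mean"` (default) or `"median"`.
#' @return list `W` (the F statistic), `df1`, `df2`, `p`. With all
#'   deviations zero the statistic is undefined and returned as `NaN`.
#' @export
leveneHomogeneity <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  cfun <- if (center == "mean") mean else stats::median
  dev <- abs(values - stats::ave(values, groups, FUN = cfun))
  if (all(dev == 0))
    return(list(W = NaN, df1 = nlevels(groups) - 1,
      df2 = length(values) - nlevels(groups), p = NaN
    ))
  fit <- stats::anova(stats::lm(dev ~ groups))
  list(
    W = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
    p = fit$`Pr(>F)`[1]
  )
}

# Validate and normalize long-format mixed-design data.
.checkMixedData <- function(data) {
  need <- c("participant", "group", "condition", "value")
  if (!all(need %in% names(data)))
    stop("data needs columns participant, group, condition, value",
      call. = FALSE
    )
  data$participant <- factor(data$participant)
  data$group <- factor(data$group, levels = unique(as.character(data$group)))
  data$condition <- factor(data$condition,
    levels = unique(as.character(data$condition))
  )
  if (nlevels(data$group) != 2 || nlevels(data$condition) != 2)
    stop("exactly two groups and two conditions are required", call. = FALSE)
  counts <- table(data$participant, data$condition)
  bad <- rownames(counts)[apply(counts != 1, 1, any)]
  if (length(bad))
    stop(
      "participant(s) without exactly one value per condition: ",
      paste(bad, collapse = ", "), call. = FALSE
    )
  data
}

#' 2x2 mixed-design ANOVA with partial eta squared
#'
#' Classical sums-of-squares partition for one between-subjects factor
#' (group) and one within-subjects factor (condition): the group effect is
#' tested against subjects-within-group, condition and the interaction
#' against condition-by-subjects-within-group, each with df (1, n - 2).
#' Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`; for df1 = 1 this equals
#' `F / (F + df2)`.
#'
#' @param data long data.frame with columns `participant`, `group`,
#'   `condition`, `value`; every participant observed once per condition.
#' @return data.frame of class `AnovaTable` with one row per effect
#'   (`condition`, `group`, `interaction`): `F`, `df1`, `df2`, `p`,
#'   `etaSqP`.
#' @export
mixedAnova2x2 <- function(data) {
  data <- .checkMixedData(data)
  fit <- stats::aov(
    value ~ group * condition + Error(participant), data = data
  )
  s <- summary(fit)
  between <- as.data.frame(s[["Error: participant"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  rn <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    if (!length(i)) stop("effect not found: ", name, call. = FALSE)
    tab[i, ]
  }
  ssG <- rn(between, "group")["Sum Sq"][[1]]
  ssSubj <- rn(between, "Residuals")["Sum Sq"][[1]]
  ssC <- rn(within, "condition")["Sum Sq"][[1]]
  ssI <- rn(within, "group:condition")["Sum Sq"][[1]]
  ssW <- rn(within, "Residuals")["Sum Sq"][[1]]
  dfSubj <- rn(between, "Residuals")["Df"][[1]]
  dfW <- rn(within, "Residuals")["Df"][[1]]
  ssTot <- ssG + ssSubj + ssC + ssI + ssW
  mk <- function(effect, ss, ssErr, dfErr) {
    # a stratum that is numerically empty (e.g. no within-subject
    # variation at all) has no testable effect
    if (ss + ssErr < 1e-10 * max(ssTot, 1)) {
      return(data.frame(
        effect = effect, F = 0, df1 = 1, df2 = dfErr, p = 1, etaSqP = 0
      ))
    }
    ff <- (ss / 1) / (ssErr / dfErr)
    data.frame(
      effect = effect, F = ff, df1 = 1, df2 = dfErr,
      p = stats::pf(ff, 1, dfErr, lower.tail = FALSE),
      etaSqP = ss / (ss + ssErr)
    )
  }
  out <- rbind(
    mk("condition", ssC, ssW, dfW),
    mk("group", ssG, ssSubj, dfSubj),
    mk("interaction", ssI, ssW, dfW)
  )
  rownames(out) <- NULL
  class(out) <- c("AnovaTable", "data.frame")
  out
}

#' Partial eta squared from F with one numerator df
#'
#' The identity `etaSqP = F * df1 / (F * df1 + df2)`; with df1 = 1 this is
#' `F / (F + df2)`.
#'
#' @param f F statistic.
#' @param df2 denominator degrees of freedom.
#' @param df1 numerator degrees of freedom (default 1).
#' @return partial eta squared.
#' @examples
#' etaSquaredFromF(30.294, 66) # 0.315
#' @export
etaSquaredFromF <- function(f, df2, df1 = 1) {
  f * df1 / (f * df1 + df2)
}

#' Simple-effects analysis for a 2x2 mixed design
#'
#' Follows up a significant interaction: an independent-groups contrast at
#' each condition (pooled two-sample t) and a paired contrast across
#' conditions within each group; two-sided p values with Bonferroni
#' adjustment within each two-test family.
#'
#' @param data long data.frame as for [mixedAnova2x2()].
#' @return data.frame with columns `family` (`between`/`within`), `level`,
#'   `estimate` (mean difference), `t`, `df`, `p`, `pAdj`.
#' @export
simpleEffects <- function(data) {
  data <- .checkMixedData(data)
  gl <- levels(data$group)
  cl <- levels(data$condition)
  rows <- list()
  for (cond in cl) {
    sub <- data[data$condition == cond, ]
    x <- sub$value[sub$group == gl[1]]
    y <- sub$value[sub$group == gl[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("fewer than 2 observations in a cell", call. = FALSE)
    tt <- stats::t.test(x, y, var.equal = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      family = "between", level = cond,
      estimate = mean(x) - mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
    )
  }
  for (g in gl) {
    sub <- data[data$group == g, ]
    sub <- sub[order(sub$participant), ]
    x <- sub$value[sub$condition == cl[1]]
    y <- sub$value[sub$condition == cl[2]]
    if (length(x) < 2)
      stop("fewer than 2 observations in a cell", call. = FALSE)
    tt <- stats::t.test(x, y, paired = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      family = "within", level = g,
      estimate = mean(x) - mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
    )
  }
  out <- do.call(rbind, rows)
  out$pAdj <- pmin(1, 2 * out$p) # Bonferroni within each two-test family
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values controlling the false-discovery rate;
#' monotone and capped at 1.
#'
#' @param p numeric p values in \[0, 1\].
#' @return adjusted p values, same order.
#' @export
fdrBH <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("p values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for a stated family size `m` (at least the number of
#' tests supplied).
#'
#' @param p numeric p values.
#' @param m family size (default `length(p)`).
#' @return adjusted p values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < length(p))
    stop("family size m must be >= number of tests", call. = FALSE)
  pmin(1, m * p)
}

#' Pearson correlation with two-sided t-based p value
#'
#' Sample Pearson correlation; the p value comes from
#' `t = r sqrt((n - 2) / (1 - r^2))` with n - 2 df.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return list `r`, `n`, `p`.
#' @export
pearsonCorrTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need two equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector", call. = FALSE)
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), n = length(x), p = res$p.value)
}
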
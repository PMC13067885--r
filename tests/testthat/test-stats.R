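test_that("pooled t is antisymmetric and degenerate cases behave", {
  a <- sampleSummary(10, 2, 20)
  b <- sampleSummary(11, 3, 25)
  r1 <- pooledTTest(a, b)
  r2 <- pooledTTest(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$df, 43)

  same <- pooledTTest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  z1 <- sampleSummary(5, 0, 10)
  z2 <- sampleSummary(6, 0, 10)
  expect_error(pooledTTest(z1, z2), "zero pooled variance")
  expect_equal(pooledTTest(z1, z1)$t, 0)

  # Welch equals pooled for equal group sizes and SDs
  w <- pooledTTest(a, sampleSummary(11, 2, 20), welch = TRUE)
  p <- pooledTTest(a, sampleSummary(11, 2, 20))
  expect_equal(w$t, p$t)
  expect_equal(w$df, p$df)
})

test_that("chi-square matches the expected-count oracle without correction", {
  for (s in 1:10) {
    set.seed(s)
    tbl <- matrix(sample(5:40, 4), 2)
    res <- chisqTest2x2(tbl)
    e <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
    expect_equal(res$chisq, sum((tbl - e)^2 / e), tolerance = 1e-12)
    expect_equal(res$df, 1)
    # invariance under row and column swaps
    expect_equal(chisqTest2x2(tbl[2:1, ])$chisq, res$chisq)
    expect_equal(chisqTest2x2(tbl[, 2:1])$chisq, res$chisq)
  }
  expect_equal(chisqTest2x2(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  prop <- matrix(c(10, 20, 30, 60), 2) # proportional rows
  expect_equal(chisqTest2x2(prop)$chisq, 0, tolerance = 1e-12)
  expect_error(chisqTest2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
    "marginal"
  )
})

test_that("Levene's statistic equals a one-way ANOVA on absolute deviations", {
  vals <- c(1, 2, 3, 0, 4, 8)
  grp <- rep(c("a", "b"), each = 3)
  res <- leveneHomogeneity(vals, grp)
  dev <- abs(vals - ave(vals, grp))
  ref <- anova(lm(dev ~ factor(grp)))
  expect_equal(res$W, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-12)

  same <- leveneHomogeneity(c(1, 2, 3, 11, 12, 13), grp)
  expect_equal(same$W, 0, tolerance = 1e-12) # location invariance

  degenerate <- leveneHomogeneity(c(1, 1, 1, 2, 2, 2), grp)
  expect_true(is.nan(degenerate$W))
})

test_that("mixed ANOVA matches independent contrast-based oracles", {
  set.seed(12)
  for (rep in 1:5) {
    d <- expand.grid(
      participant = sprintf("S%02d", 1:20), condition = c("open", "closed")
    )
    d$group <- ifelse(as.integer(sub("S", "", d$participant)) <= 10,
      "MCI", "CN"
    )
    d$value <- rnorm(nrow(d)) +
      2 * (d$group == "MCI") + 0.5 * (d$condition == "closed") +
      rnorm(20)[as.integer(factor(d$participant))]
    at <- mixedAnova2x2(d)
    oracle <- oracleMixedF(d)
    expect_equal(at$F[at$effect == "interaction"],
      unname(oracle["interaction"]),
      tolerance = 1e-8
    )
    expect_equal(at$F[at$effect == "group"], unname(oracle["group"]),
      tolerance = 1e-8
    )
    expect_equal(at$F[at$effect == "condition"],
      unname(oracle["condition"]),
      tolerance = 1e-8
    )
    expect_true(all(at$df1 == 1))
    expect_true(all(at$df2 == 18))
    # partial eta squared identity for df1 = 1
    expect_equal(at$etaSqP, at$F / (at$F + at$df2), tolerance = 1e-12)
  }
})

test_that("mixed ANOVA handles flat data and rejects incomplete designs", {
  d <- expand.grid(
    participant = sprintf("S%02d", 1:8), condition = c("open", "closed")
  )
  d$group <- rep(c("MCI", "CN"), each = 4)
  set.seed(5)
  pv <- rnorm(8)
  d$value <- pv[as.integer(factor(d$participant))] # identical across conditions
  at <- mixedAnova2x2(d)
  expect_equal(at$F[at$effect == "condition"], 0, tolerance = 1e-12)
  expect_equal(at$F[at$effect == "interaction"], 0, tolerance = 1e-12)

  expect_error(mixedAnova2x2(d[-1, ]), "S01")
})

test_that("simple effects equal stand-alone t tests with Bonferroni factor 2", {
  set.seed(31)
  d <- expand.grid(
    participant = sprintf("S%02d", 1:16), condition = c("open", "closed")
  )
  d$group <- rep(c("MCI", "CN"), each = 8)
  d$value <- rnorm(nrow(d)) + 1.5 * (d$group == "MCI" & d$condition == "closed")
  se <- simpleEffects(d)
  expect_equal(nrow(se), 4)
  expect_true(all(se$pAdj >= se$p))
  expect_true(all(se$pAdj <= 1))

  bet <- se[se$family == "between" & se$level == "closed", ]
  x <- d$value[d$condition == "closed" & d$group == "MCI"]
  y <- d$value[d$condition == "closed" & d$group == "CN"]
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(bet$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(bet$pAdj, min(1, 2 * ref$p.value), tolerance = 1e-12)

  wit <- se[se$family == "within" & se$level == "MCI", ]
  sub <- d[d$group == "MCI", ]
  sub <- sub[order(sub$participant), ]
  refw <- t.test(sub$value[sub$condition == "open"],
    sub$value[sub$condition == "closed"],
    paired = TRUE
  )
  expect_equal(wit$t, unname(refw$statistic), tolerance = 1e-12)
})

test_that("injected within-subject shifts surface only in within contrasts", {
  set.seed(77)
  d <- expand.grid(
    participant = sprintf("S%02d", 1:24), condition = c("open", "closed")
  )
  d$group <- rep(c("MCI", "CN"), each = 12)
  d$value <- rnorm(nrow(d), sd = 0.5) + 3 * (d$condition == "closed")
  se <- simpleEffects(d)
  expect_true(all(se$pAdj[se$family == "within"] < 0.05))
  expect_true(all(se$pAdj[se$family == "between"] > 0.05))
})

test_that("identical groups give an adjusted between-group p of 1", {
  d <- expand.grid(
    participant = sprintf("S%02d", 1:8), condition = c("open", "closed")
  )
  d$group <- rep(c("MCI", "CN"), each = 4)
  set.seed(2)
  base <- rnorm(4)
  d$value <- rep(rep(base, 2), 2) + 0.3 * (d$condition == "closed") +
    rnorm(nrow(d), sd = 0.01)
  d$value[d$condition == "closed"] <- d$value[d$condition == "open"] +
    0.3 + rnorm(8, sd = 0.01)
  se <- simpleEffects(d)
  expect_equal(se$pAdj[se$family == "between"], c(1, 1))
})

test_that("FDR follows the step-up rule and stays below Bonferroni", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrBH(rep(0.2, 5)), rep(0.2, 5))
  for (s in 1:10) {
    set.seed(s)
    p <- runif(10)
    adj <- fdrBH(p)
    expect_equal(adj, oracleFdrBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= bonferroniAdjust(p) + 1e-12))
  }
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
})

test_that("Bonferroni multiplies by the family size and caps at 1", {
  expect_equal(bonferroniAdjust(0.01, m = 3), 0.03)
  expect_equal(bonferroniAdjust(0.5, m = 3), 1)
  expect_error(bonferroniAdjust(c(0.1, 0.2), m = 1), "family size")
})

test_that("correlation test matches the t-distribution closed form", {
  x <- 1:20
  expect_equal(pearsonCorrTest(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrTest(x, -x)$r, -1)

  pair <- vectorsWithSampleR(34, -0.384, seed = 5)
  res <- pearsonCorrTest(pair$x, pair$y)
  expect_equal(res$r, -0.384, tolerance = 1e-12)
  tref <- -0.384 * sqrt(32 / (1 - 0.384^2))
  expect_equal(res$p, 2 * pt(tref, 32), tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.025)

  expect_error(pearsonCorrTest(rep(1, 10), rnorm(10)), "constant")
})
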
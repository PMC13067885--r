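test_that("zero-phase low-pass preserves the sway band and kills noise", {
  fs <- 1000
  tt <- seq(0, 5, by = 1 / fs)
  const <- copTrial(rep(3.5, length(tt)), rep(-1.2, length(tt)),
    samplingRate = fs
  )
  f <- filterCop(const)
  expect_lt(max(abs(mlSeries(f) - 3.5)), 1e-9)
  expect_lt(max(abs(apSeries(f) + 1.2)), 1e-9)

  slow <- sin(2 * pi * 1 * tt)
  fast <- sin(2 * pi * 100 * tt)
  tr <- filterCop(copTrial(slow, fast, samplingRate = fs))
  mid <- 1000:4000
  expect_gt(max(abs(mlSeries(tr)[mid])), 0.99) # 1 Hz retained within 1%
  expect_lt(max(abs(apSeries(tr)[mid])), 0.01) # 100 Hz attenuated > 99%

  expect_error(filterCop(const, cutoffHz = 600), "Nyquist")
  expect_equal(nSamples(f), length(tt))
})

test_that("RMS displacement follows its closed form and is translation invariant", {
  ml <- rep(c(1, -1), 50)
  ap <- rep(0.7, 100)
  tr <- smallCopTrial(ml, ap)
  r <- copRms(tr)
  expect_equal(unname(r["ML_RMS"]), 1)
  expect_equal(unname(r["AP_RMS"]), 0)
  expect_equal(unname(r["RMS"]), 1)

  shifted <- smallCopTrial(ml + 10, ap + 10)
  expect_equal(copRms(shifted), r)

  const <- smallCopTrial(rep(2, 10), rep(3, 10))
  expect_equal(unname(copRms(const)), c(0, 0, 0))
})

test_that("mean velocity is exact for uniform motion and obeys the triangle bound", {
  # 301 samples at 10 Hz, ML advancing 2 mm per step: 600 mm over 30 s
  ml <- 2 * (0:300)
  ap <- rep(1, 301)
  tr <- copTrial(ml, ap, samplingRate = 10)
  v <- copVelocity(tr)
  expect_equal(unname(v["V"]), 20)
  expect_equal(unname(v["ML_V"]), 20)
  expect_equal(unname(v["AP_V"]), 0)

  for (s in 1:10) {
    set.seed(s)
    tr <- smallCopTrial(rnorm(200), rnorm(200))
    v <- copVelocity(tr)
    expect_lte(max(v["ML_V"], v["AP_V"]), v["V"] + 1e-12)
    expect_lte(v["V"], v["ML_V"] + v["AP_V"] + 1e-12)
  }

  const <- smallCopTrial(rep(0, 50), rep(0, 50))
  expect_equal(unname(copVelocity(const)), c(0, 0, 0))
})

test_that("sway area matches the 95% covariance ellipse closed form", {
  # point cloud with exact sample covariance diag(4, 1)
  set.seed(7)
  n <- 500
  x <- rnorm(n)
  y <- residuals(lm(rnorm(n) ~ x))
  x <- (x - mean(x)) / sd(x) * 2
  y <- (y - mean(y)) / sd(y)
  tr <- smallCopTrial(x, y)
  expect_equal(copSwayArea(tr), pi * 5.991465 * 2, tolerance = 1e-9)

  # rotation invariance
  th <- 0.83
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  expect_equal(copSwayArea(smallCopTrial(xr, yr)), copSwayArea(tr),
    tolerance = 1e-9
  )
  # translation invariance
  expect_equal(copSwayArea(smallCopTrial(x + 5, y - 3)), copSwayArea(tr),
    tolerance = 1e-9
  )

  expect_warning(
    a0 <- copSwayArea(smallCopTrial(rep(1, 10), rep(2, 10))),
    "degenerate"
  )
  expect_equal(a0, 0)
})

test_that("balance indices scale correctly and keep the per-trial RMS identity", {
  set.seed(11)
  tr <- smallCopTrial(cumsum(rnorm(300)), cumsum(rnorm(300)))
  m1 <- copMetrics(tr, filter = FALSE)
  c2 <- smallCopTrial(3 * mlSeries(tr), 3 * apSeries(tr))
  m2 <- copMetrics(c2, filter = FALSE)
  expect_equal(m2["RMS"], 3 * m1["RMS"], tolerance = 1e-10)
  expect_equal(m2["V"], 3 * m1["V"], tolerance = 1e-10)
  expect_equal(m2["AREA"], 9 * m1["AREA"], tolerance = 1e-10)
  expect_true(all(m1 >= 0))
  expect_equal(m1[["RMS"]]^2, m1[["ML_RMS"]]^2 + m1[["AP_RMS"]]^2,
    tolerance = 1e-12
  )
})

test_that("trial aggregation is the arithmetic mean of each index", {
  set.seed(3)
  trials <- lapply(1:3, function(i) {
    copMetrics(smallCopTrial(rnorm(200), rnorm(200)), filter = FALSE)
  })
  agg <- aggregateTrials(trials)
  expect_equal(agg, colMeans(do.call(rbind, trials)))
  expect_equal(aggregateTrials(trials[1]), trials[[1]])
  fake <- lapply(c(1, 2, 3), function(a) c(AREA = a))
  expect_equal(unname(aggregateTrials(fake)), 2)
  expect_error(aggregateTrials(list()), "empty")
})

test_that("COP trials survive a CSV roundtrip", {
  tr <- generateCopTrial(copGenParams(duration = 1, samplingRate = 200),
    seed = 5
  )
  path <- tempfile(fileext = ".csv")
  writeCopTrialCsv(tr, path)
  back <- readCopTrialCsv(path)
  expect_equal(mlSeries(back), mlSeries(tr), tolerance = 1e-9)
  expect_equal(apSeries(back), apSeries(tr), tolerance = 1e-9)
  expect_equal(samplingRate(back), 200, tolerance = 1e-6)
  unlink(path)
})
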
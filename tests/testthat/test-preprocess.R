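# small synthetic OpticalRecording built by hand
makeRecording <- function(intensity, fs = 11) {
  new("OpticalRecording",
    intensity = intensity, wavelengths = c(730, 850),
    samplingRate = fs, sdDistance = rep(3, dim(intensity)[1])
  )
}

test_that("optical-density conversion is ratio-based and scale invariant", {
  n <- 1000
  ii <- array(0, dim = c(2, 2, n))
  ii[1, , ] <- 100
  ii[2, 1, ] <- 50 * exp(0.01 * sin(seq_len(n) / 50))
  ii[2, 2, ] <- 80
  od <- intensityToOd(makeRecording(ii))
  expect_lt(max(abs(odValues(od)[1, , ])), 1e-12) # constant -> zero

  ii2 <- ii
  ii2[2, 1, ] <- ii[2, 1, ] * 37.5 # per-channel scaling drops out
  od2 <- intensityToOd(makeRecording(ii2))
  expect_equal(odValues(od2), odValues(od), tolerance = 1e-12)

  # one halved sample on a long flat baseline appears as ~log10(2)
  ii3 <- array(100, dim = c(1, 2, n))
  ii3[1, 1, 500] <- 50
  od3 <- intensityToOd(makeRecording(ii3))
  expect_equal(odValues(od3)[1, 1, 500], log10(2), tolerance = 2e-3)

  ii4 <- ii
  ii4[1, 1, 3] <- 0
  expect_error(intensityToOd(makeRecording(ii4)), "positive")
})

test_that("motion scrubbing flags injected steps and reports dead channels", {
  n <- 660
  fs <- 11
  tt <- (seq_len(n) - 1) / fs
  odArr <- array(0, dim = c(3, 2, n))
  for (w in 1:2) {
    odArr[1, w, ] <- 0.01 * sin(2 * pi * 0.05 * tt) # smooth: no flags
    odArr[2, w, ] <- 0.01 * sin(2 * pi * 0.05 * tt)
    odArr[3, w, ] <- 0.002 * sin(2 * pi * 0.05 * tt)
  }
  sdCh2 <- sd(odArr[2, 1, ])
  odArr[2, , 300:302] <- odArr[2, , 300:302] + 10 * sdCh2
  # channel 3: large alternating jumps everywhere
  for (w in 1:2) {
    odArr[3, w, ] <- odArr[3, w, ] + rep(c(0, 1), length.out = n) * 0.5
  }
  od <- new("OdSeries",
    od = odArr, wavelengths = c(730, 850), samplingRate = fs,
    sdDistance = rep(3, 3)
  )
  res <- scrubMotionArtifacts(od, sdFactor = 5, badChannelFraction = 0.5)
  expect_false(any(res$mask[1, ]))
  expect_true(all(res$mask[2, 300:302]))
  # flagged segment interpolated toward the smooth neighbourhood
  expect_lt(max(abs(res$od@od[2, 1, 300:302])), 5 * sdCh2)
  # every window of the square-wave channel trips a tight threshold, so
  # the whole channel is flagged and reported bad at a 100% fraction
  res2 <- scrubMotionArtifacts(od, sdFactor = 1, badChannelFraction = 1)
  expect_true(all(res2$mask[3, ]))
  expect_true(3 %in% res2$badChannels)
})

test_that("band-pass keeps mid-band tones, rejects fast tones and DC", {
  fs <- 11
  tt <- seq(0, 600, by = 1 / fs)
  mid <- 3000:3600
  y1 <- bandpassFilter(sin(2 * pi * 0.05 * tt), fs)
  expect_gt(max(abs(y1[mid])), 0.95) # within 5%
  y2 <- bandpassFilter(sin(2 * pi * 1.0 * tt), fs)
  expect_lt(max(abs(y2[mid])), 0.05) # >= 95% attenuated
  y3 <- bandpassFilter(rep(4, length(tt)), fs)
  expect_lt(mean(abs(y3)), 1e-6) # DC rejected
  expect_error(bandpassFilter(y1, fs, highHz = 6), "Nyquist")
})

test_that("the Beer-Lambert forward model and inversion compose to identity", {
  n <- 200
  set.seed(4)
  hboTrue <- matrix(rep(c(1.0, -0.4), each = n), 2, n, byrow = TRUE) +
    0.2 * matrix(rnorm(2 * n), 2, n)
  hbrTrue <- matrix(rep(c(-0.3, 0.2), each = n), 2, n, byrow = TRUE)
  od <- hemoglobinToOd(hboTrue, hbrTrue, sdDistance = 3)
  ods <- new("OdSeries",
    od = od, wavelengths = c(730, 850), samplingRate = 11,
    sdDistance = rep(3, 2)
  )
  conc <- odToHemoglobin(ods)
  expect_equal(conc$hbo, hboTrue, tolerance = 1e-9)
  expect_equal(conc$hbr, hbrTrue, tolerance = 1e-9)

  # linearity in 1/d: same OD at doubled separation halves concentration
  ods2 <- new("OdSeries",
    od = od, wavelengths = c(730, 850), samplingRate = 11,
    sdDistance = rep(6, 2)
  )
  conc2 <- odToHemoglobin(ods2)
  expect_equal(conc2$hbo, hboTrue / 2, tolerance = 1e-9)

  expect_error(
    mbllCoefficients(extinction = matrix(c(1, 1, 1, 1), 2)),
    "singular"
  )
})

test_that("the preprocessing chain is deterministic, mean-free and scale invariant", {
  tpl <- generateNetworkTemplate("smallworld", seed = 8)
  rec <- generateFnirsRecording(tpl, duration = 60, seed = 8)
  h1 <- preprocessRecording(rec)
  h2 <- preprocessRecording(rec)
  expect_identical(hbo(h1), hbo(h2))
  expect_lt(max(abs(rowMeans(hbo(h1)))), 1e-9)
  expect_lt(max(abs(rowMeans(hbr(h1)))), 1e-9)

  scaled <- rec
  scaled@intensity <- rec@intensity * 3.7
  h3 <- preprocessRecording(scaled)
  expect_equal(hbo(h3), hbo(h1), tolerance = 1e-3)
})

test_that("channels sharing a latent ROI signal are more correlated than strangers", {
  map <- defaultChannelMap()
  within <- c()
  across <- c()
  for (s in 1:5) {
    tpl <- generateNetworkTemplate("smallworld", coupling = 0, seed = s)
    rec <- generateFnirsRecording(tpl,
      noise = noiseSpec(spikeRate = 0), duration = 120, seed = 10 + s,
      globalSd = 0
    )
    h <- hbo(preprocessRecording(rec))
    r <- cor(t(h))
    roi <- map$roi[order(map$channel)]
    same <- outer(roi, roi, "==") & upper.tri(r)
    within <- c(within, mean(r[same]))
    across <- c(across, mean(r[!same & upper.tri(r)]))
  }
  expect_gt(mean(within), mean(across) + 0.2)
})

test_that("optical recordings survive a long-CSV roundtrip", {
  tpl <- generateNetworkTemplate("smallworld", seed = 2)
  rec <- generateFnirsRecording(tpl, duration = 5, seed = 2)
  path <- tempfile(fileext = ".csv")
  writeOpticalRecordingCsv(rec, path)
  back <- readOpticalRecordingCsv(path)
  expect_equal(intensityValues(back), unname(intensityValues(rec)),
    tolerance = 1e-9
  )
  expect_equal(samplingRate(back), 11, tolerance = 1e-6)
  unlink(path)
})
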
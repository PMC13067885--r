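test_that("the shipped montage matches the published channel counts", {
  map <- defaultChannelMap()
  expect_equal(nrow(map), 48)
  expect_equal(sort(map$channel), 1:48)
  counts <- as.integer(table(factor(map$roi, levels = roiOrder())))
  expect_equal(counts, c(10L, 9L, 3L, 3L, 2L, 2L, 5L, 5L, 5L, 4L))
  expect_equal(sum(counts), 48L)
})

makeHemo <- function(hboM, bad = integer(0)) {
  new("HemoRecording",
    hbo = hboM, hbr = -hboM / 3, samplingRate = 11,
    artifactMask = matrix(FALSE, nrow(hboM), ncol(hboM)),
    badChannels = as.integer(bad)
  )
}

test_that("ROI averaging is the arithmetic mean of usable member channels", {
  map <- data.frame(
    channel = 1:4, hemisphere = c("L", "L", "R", "R"),
    region = "PFC", roi = c("L_PFC", "L_PFC", "R_PFC", "R_PFC")
  )
  hboM <- rbind(c(1, 1), c(3, 3), c(2, 4), c(2, 4))
  roi <- roiAverage(makeHemo(hboM), map)
  expect_equal(unname(roi["L_PFC", ]), c(2, 2))
  expect_equal(unname(roi["R_PFC", ]), c(2, 4))

  # bad channel excluded before averaging
  roi2 <- roiAverage(makeHemo(hboM, bad = 2), map)
  expect_equal(unname(roi2["L_PFC", ]), c(1, 1))

  expect_error(roiAverage(makeHemo(hboM, bad = c(1, 2)), map), "L_PFC")
})

test_that("connectivity matrix applies Pearson, negative zeroing and Fisher z", {
  n <- 200
  pair <- vectorsWithSampleR(n, 0.5, seed = 21)
  neg <- vectorsWithSampleR(n, -0.3, seed = 22)
  set.seed(23)
  roi <- rbind(
    pair$x, pair$y, neg$x, neg$y,
    matrix(rnorm(6 * n), 6, n)
  )
  rownames(roi) <- roiOrder()
  fc <- connectivityMatrix(roi)
  z <- as.matrix(fc)
  expect_equal(z[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(z[3, 4], 0) # negative correlation zeroed
  expect_true(isSymmetric(z))
  expect_true(all(z >= 0))
  expect_true(all(diag(z) == 0))

  # Pearson invariance to per-ROI affine rescaling
  roi2 <- roi * 3.2 + 17
  expect_equal(as.matrix(connectivityMatrix(roi2)), z, tolerance = 1e-9)

  roiBad <- roi
  roiBad[5, ] <- 2
  expect_error(connectivityMatrix(roiBad), "L_M1")
})

test_that("near-duplicate series stay finite through the z transform", {
  set.seed(9)
  x <- rnorm(100)
  roi <- rbind(x, x, matrix(rnorm(8 * 100), 8, 100))
  rownames(roi) <- roiOrder()
  z <- as.matrix(connectivityMatrix(roi))
  expect_true(is.finite(z[1, 2]))
  expect_equal(z[1, 2], atanh(0.999999), tolerance = 1e-9)
})

test_that("independent white-noise ROIs give near-zero z on average", {
  vals <- sapply(1:20, function(s) {
    set.seed(s)
    roi <- matrix(rnorm(10 * 330), 10, 330)
    rownames(roi) <- roiOrder()
    z <- as.matrix(connectivityMatrix(roi))
    mean(z[upper.tri(z)])
  })
  expect_lt(mean(abs(vals)), 0.2)
})
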
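# GRF, COP, peak-pressure images, spatiotemporal parameters, balance
# preprocessing.

test_that("GRF follows the sensor-area formula with linearity", {
  g <- buildGeometry()                       # A = 2.5e-5 m^2
  fr <- array(0, dim = c(1, 10, 10))
  expect_equal(grfSeries(fr, g), 0)
  fr[1, 5, 5] <- 100
  expect_equal(grfSeries(fr, g), 2.5)        # 1000 * 2.5e-5 * 100
  expect_equal(grfSeries(fr * 2, g), 5)
  set.seed(12)
  for (i in 1:20) {
    a <- array(runif(5 * 8 * 8, 0, 500), dim = c(5, 8, 8))
    b <- array(runif(5 * 8 * 8, 0, 500), dim = c(5, 8, 8))
    expect_equal(grfSeries(a + b, g), grfSeries(a, g) + grfSeries(b, g))
    k <- runif(1, 0.1, 10)
    expect_equal(grfSeries(a * k, g), k * grfSeries(a, g))
  }
})

test_that("COP is the pressure-weighted centroid in cm", {
  g <- buildGeometry()                       # s = 0.5 cm
  fr <- array(0, dim = c(1, 10, 10))
  fr[1, 3, 5] <- 80; fr[1, 3, 7] <- 80       # x = 4 and 6 (0-based)
  cop <- copSeries(fr, g)
  expect_equal(cop$ml, 5 * 0.5)
  expect_equal(cop$ap, 2 * 0.5)
  sq <- array(0, dim = c(1, 11, 11)); sq[1, 3:9, 3:9] <- 120
  cop <- copSeries(sq, g)
  expect_equal(cop$ml, 5 * 0.5)              # geometric center (0-based 5)
  expect_equal(cop$ap, 5 * 0.5)
})

test_that("COP centering and translation equivariance hold exactly", {
  g <- buildGeometry()
  set.seed(3)
  for (i in 1:20) {
    a <- array(0, dim = c(6, 20, 20))
    a[, 4:12, 6:14] <- runif(6 * 9 * 9, 10, 400)
    cc <- copSeries(a, g, centered = TRUE)
    expect_lt(abs(mean(cc$ml)), 1e-9)
    expect_lt(abs(mean(cc$ap)), 1e-9)
    dy <- sample(0:5, 1); dx <- sample(0:4, 1)
    b <- array(0, dim = dim(a))
    b[, (4 + dy):(12 + dy), (6 + dx):(14 + dx)] <- a[, 4:12, 6:14]
    c0 <- copSeries(a, g); c1 <- copSeries(b, g)
    expect_equal(c1$ap, c0$ap + 0.5 * dy)
    expect_equal(c1$ml, c0$ml + 0.5 * dx)
  }
  # zero-total frames are dropped; all-zero input errors
  z <- array(0, dim = c(3, 5, 5)); z[2, 2, 2] <- 50
  expect_equal(copSeries(z, g)$frame, 2L)
  expect_error(copSeries(array(0, c(2, 5, 5)), g), "zero total")
})

test_that("peak-pressure image equals the per-pixel maximum", {
  a <- array(runif(8 * 12 * 9, 0, 600), dim = c(8, 12, 9))
  pk <- peakPressureImage(a)
  for (t in 1:8) expect_true(all(pk >= a[t, , ]))
  brute <- matrix(0, 12, 9)
  for (i in 1:12) for (j in 1:9) brute[i, j] <- max(a[, i, j])
  expect_equal(pk, brute)
  one <- array(runif(20), dim = c(1, 4, 5))
  expect_equal(peakPressureImage(one), one[1, , ])
})

test_that("spatiotemporal parameters follow box arithmetic", {
  g <- buildGeometry()                        # pitch 0.5 cm, 100 Hz
  steps <- data.frame(
    StartFrame = c(100, 150), EndFrame = c(160, 215),
    Ymin = c(100, 170), Ymax = c(150, 220),
    Xmin = c(100, 120), Xmax = c(120, 140),
    RotationAngle = c(-8, 8), Side = c("Right", "Left"))
  gp <- spatiotemporalParameters(steps, g)
  expect_equal(gp$stepLengthCm[2], 70 * 0.5)  # centroid delta-y 70 px
  expect_equal(gp$stepWidthCm[2], 20 * 0.5)
  expect_equal(gp$stepTimeS[2], 0.5)
  expect_equal(gp$cadence[2], 120)
  expect_equal(gp$speedMs[2], 0.35 / 0.5)
  expect_equal(gp$stanceTimeS, c(0.61, 0.66))
  expect_equal(gp$toeOutDeg, c(8, 8))         # side-signed outward rotation
  expect_true(all(is.na(gp[1, c("stepLengthCm", "stepTimeS", "cadence")])))
  one <- spatiotemporalParameters(steps[1, ], g)
  expect_equal(nrow(one), 1L)
  expect_false(is.na(one$stanceTimeS))
})

test_that("balance preprocessing crops, pads, rotates and trims correctly", {
  g <- test_geometry()
  sim <- simulateBalanceTrial(test_feet(), g, durationS = 11, seed = 4,
                              extraFrames = 30L)
  out <- preprocessBalance(sim$trial, outputFrames = 1000L)
  expect_equal(dim(out), c(1000L, 180L, 180L))
  # trailing frames are kept and pressures inside the ROI box are conserved
  fr <- trialFrames(sim$trial, nFrames(sim$trial) - 999:0)
  act <- apply(fr, c(2, 3), max) >= 10
  ry <- range(which(rowSums(act) > 0)); rx <- range(which(colSums(act) > 0))
  expect_equal(sum(out), sum(fr[, ry[1]:ry[2], rx[1]:rx[2]]))
  expect_equal(sum(out[1000, , ] > 0), sum(fr[1000, , ] > 0))
  # static stance: every retained frame equals the first
  still <- simulateBalanceTrial(test_feet(), g, durationS = 3, seed = 5,
                                swayAmplitude = 0)
  o2 <- preprocessBalance(still$trial, outputFrames = 200L)
  for (k in c(50L, 200L)) expect_identical(o2[k, , ], o2[1, , ])
  # short trials pad with a warning; oversized activity errors
  expect_warning(o3 <- preprocessBalance(still$trial, outputFrames = 400L),
                 "zero-padding")
  expect_equal(dim(o3)[1], 400L)
  expect_true(all(o3[1:100, , ] == 0))
})

test_that("balance auto-orientation puts the long axis vertical, heels down", {
  g <- test_geometry()
  sim <- simulateBalanceTrial(test_feet(), g, durationS = 3, seed = 6,
                              swayAmplitude = 0)
  out <- preprocessBalance(sim$trial, outputFrames = 100L)
  act <- apply(out, c(2, 3), max) >= 10
  ry <- range(which(rowSums(act) > 0)); rx <- range(which(colSums(act) > 0))
  expect_gte(diff(ry), diff(rx))             # feet long axis vertical
  pk <- apply(out, c(2, 3), max)
  heel_row <- which(pk == max(pk), arr.ind = TRUE)[1, 1]
  expect_gt(heel_row, 90)                    # heel (pressure max) in lower half
})
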
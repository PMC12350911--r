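# Synthetic walkway simulator: templates, trials, artifacts.

test_that("foot templates roll heel to toe and mirror between sides", {
  g <- test_geometry()
  fpR <- test_feet(); fpL <- test_feet(); fpL$side <- "Left"
  tR <- makeFootTemplate(fpR, g, stanceFrames = 40L)
  tL <- makeFootTemplate(fpL, g, stanceFrames = 40L)
  expect_equal(dim(tR), c(40L, 50L, 18L))
  # left is the exact column mirror of right
  expect_identical(tL, tR[, , 18:1])
  # early frames heel-dominant, late frames toe-dominant (toe at row 1)
  half <- 25L
  early <- tR[2, , ]; late <- tR[39, , ]
  expect_gt(sum(early[(half + 1):50, ]), sum(early[1:half, ]))
  expect_gt(sum(late[1:half, ]), sum(late[(half + 1):50, ]))
  # every frame has contact
  expect_true(all(apply(tR, 1, max) > 0))
})

test_that("constant weighting gives identical frames; oversized feet error", {
  g <- test_geometry()
  fp <- footParams(25, 9, archDepth = 0, weighting = "constant")
  tt <- makeFootTemplate(fp, g, stanceFrames = 10L)
  for (k in 2:10) expect_identical(tt[k, , ], tt[1, , ])
  expect_error(makeFootTemplate(footParams(soleLengthCm = 500), g),
               "invalid params")
})

test_that("template GRF matches the closed-form sensor-area sum", {
  g <- test_geometry()
  tt <- makeFootTemplate(test_feet(), g, stanceFrames = 12L)
  grf <- grfSeries(tt, g)
  for (k in c(1L, 6L, 12L))
    expect_equal(grf[k], 1000 * sensorArea(g) * sum(tt[k, , ]))
})

test_that("walking trials are deterministic and schema-valid", {
  g <- test_geometry()
  s1 <- simulateWalkingTrial(test_gait(), test_feet(), g, durationS = 6,
                             seed = 9)
  s2 <- simulateWalkingTrial(test_gait(), test_feet(), g, durationS = 6,
                             seed = 9)
  expect_identical(trialFrames(s1$trial), trialFrames(s2$trial))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateWalkingTrial(test_gait(), test_feet(), g, durationS = 6,
                             seed = 10)
  expect_false(identical(trialFrames(s1$trial), trialFrames(s3$trial)))
  expect_equal(nFrames(s1$trial), 600L)
  expect_true(validObject(s1$trial))
  tr <- s1$truth
  full <- tr$Incomplete == 0
  expect_true(all(tr$Ymin[full] >= 0 & tr$Ymax[full] <= gridHeight(g) - 1))
  expect_true(all(tr$Xmin[full] >= 0 & tr$Xmax[full] <= gridWidth(g) - 1))
})

test_that("scheduled footfalls are kinematically self-consistent", {
  g <- test_geometry()
  zero_j <- list(timingSdFrames = 0, posSdPx = 0, pressureSd = 0, scaleSd = 0,
                 stanceSdFrames = 0, edgeDropP = 0)
  gait <- gaitParams(1.2, 60, 12)
  sim <- simulateWalkingTrial(gait, test_feet(), g, durationS = 10, seed = 1,
                              jitter = zero_j)
  tr <- sim$truth
  interval <- 60 / gait$cadence * sampleRate(g)
  steplen_px <- gait$stepLengthCm / sensorPitch(g)
  for (p in unique(tr$PassID)) {
    rows <- tr[tr$PassID == p & tr$Standing == 0, ]
    if (nrow(rows) < 2) next
    expect_true(all(abs(diff(rows$StartFrame) - interval) <= 1))
    expect_true(all(abs(abs(diff(rows$CenterY)) - steplen_px) <= 1))
    expect_true(all(abs(abs(diff(rows$CenterX)) -
                        gait$stepWidthCm / sensorPitch(g)) <= 1))
  }
  # sides alternate within a pass; orientation alternates across passes
  expect_true(all(tapply(tr$Side, tr$PassID,
                         function(s) all(s[-1] != s[-length(s)]))))
  ori <- tapply(tr$Orientation, tr$PassID, unique)
  expect_true(all(abs(diff(as.integer(ori))) == 1))
})

test_that("balance trials have the requested stance, length and sway", {
  g <- test_geometry()
  sim <- simulateBalanceTrial(test_feet(), g, durationS = 4, stance = "both",
                              seed = 2, extraFrames = 7L)
  expect_equal(nFrames(sim$trial), 407L)
  expect_equal(nrow(sim$truth), 2L)
  expect_setequal(sim$truth$Side, c("Left", "Right"))
  one <- simulateBalanceTrial(test_feet(), g, durationS = 2, stance = "left",
                              seed = 2)
  expect_equal(nrow(one$truth), 1L)
  expect_equal(one$truth$Side, "Left")
  # zero sway implies constant frames
  still <- simulateBalanceTrial(test_feet(), g, durationS = 2, seed = 3,
                                swayAmplitude = 0)
  fr <- trialFrames(still$trial)
  for (k in c(50L, 120L, 200L))
    expect_identical(fr[k, , ], fr[1, , ])
})

test_that("artifact injection: identity, dead tile, ghosting beyond lift-off", {
  g <- test_geometry()
  sim <- simulateWalkingTrial(test_gait(), test_feet(), g, durationS = 6,
                              seed = 5)
  id <- injectArtifacts(sim, noiseSpec(), seed = 1)
  expect_identical(trialFrames(id$trial), trialFrames(sim$trial))
  expect_identical(id$truth$Artifact, sim$truth$Artifact)

  dead <- injectArtifacts(sim, noiseSpec(deadTile = c(2, 1)), seed = 1)
  fr <- trialFrames(dead$trial)
  n <- g@sensorsPerTileSide
  expect_true(all(fr[, n + seq_len(n), seq_len(n)] == 0))

  gh <- injectArtifacts(sim, noiseSpec(ghostRate = 1, ghostFrames = 25,
                                       ghostSensors = 10), seed = 1)
  tr <- gh$truth
  expect_true(all(tr$Artifact[tr$EndFrame < nFrames(sim$trial) - 26] == 1))
  fr <- trialFrames(gh$trial)
  i <- which(tr$Artifact == 1)[1]
  post <- fr[tr$EndFrame[i] + 1 + 1:25,
             (tr$Ymin[i]:tr$Ymax[i]) + 1, (tr$Xmin[i]:tr$Xmax[i]) + 1,
             drop = FALSE]
  # held sensors stay active for the whole ghost window past truth lift-off
  expect_true(all(apply(post >= g@activationKpa, 1, sum) > 0))
})
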
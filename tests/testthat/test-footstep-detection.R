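# Frame-level detection, tracking and pass assignment.

test_that("empty and trivial frames detect correctly", {
  g <- test_geometry()
  fo <- detectFrameObjects(matrix(0, 60, 40), g)
  expect_equal(nrow(fo$boxes), 0L)
  fr <- matrix(0, 60, 40); fr[20:29, 10:15] <- 100
  fo <- detectFrameObjects(fr, g, frameIndex = 7L)
  expect_equal(nrow(fo$boxes), 1L)
  expect_equal(fo$frame, 7L)
  # morphology net growth: dilation 4 then erosion 2 adds ~2 px per side
  expect_lte(abs(fo$boxes$ymin - 17), 1)
  expect_lte(abs(fo$boxes$ymax - 31), 1)
})

test_that("centroid merging combines near objects transitively", {
  g <- test_geometry()
  fr <- matrix(0, 80, 80)
  fr[10:14, 10:14] <- 100          # centroid (12, 12)
  fr[10:14, 23:27] <- 100          # centroid (12, 25): 13 px away -> merged
  fo <- detectFrameObjects(fr, g)
  expect_equal(nrow(fo$boxes), 1L)
  fr2 <- matrix(0, 80, 80)
  fr2[10:14, 10:14] <- 100
  fr2[10:14, 53:57] <- 100         # 43 px away -> separate
  fo2 <- detectFrameObjects(fr2, g)
  expect_equal(nrow(fo2$boxes), 2L)
})

test_that("detection equals the brute-force oracle on random frames", {
  g <- test_geometry()
  params <- detectionParams()
  set.seed(99)
  for (i in 1:120) {
    fr <- random_frame(sample(20:64, 1), sample(20:64, 1))
    got <- detectFrameObjects(fr, g, params)$boxes
    want <- naive_detect(fr, g, params)
    expect_equal(nrow(got), length(want), info = paste("trial", i))
    if (!length(want)) next
    key <- function(b) sprintf("%d,%d,%d,%d,%d", b$ymin, b$ymax, b$xmin,
                               b$xmax, b$npx)
    expect_setequal(vapply(seq_len(nrow(got)), function(k) key(got[k, ]),
                           character(1)),
                    vapply(want, key, character(1)))
  }
})

test_that("stationary blobs produce single tracks with exact spans", {
  g <- test_geometry()
  frames <- array(0L, dim = c(100, 120, 60))
  frames[11:81, 30:45, 20:28] <- 150L
  trial <- rawTrial(frames, buildGeometry(1, 2, 60))
  tracks <- trackFootsteps(detectTrialObjects(trial))
  expect_equal(length(tracks), 1L)
  expect_equal(range(tracks[[1]]$frames), c(10, 80))
  steps <- extractFootsteps(trial, tracks)
  expect_equal(unname(steps[[1]]@box["StartFrame"]), 10L)
  expect_equal(unname(steps[[1]]@box["EndFrame"]), 80L)
  # box measured on the morphologically processed mask: raw extent +~2 px
  expect_true(abs(steps[[1]]@box["Ymin"] - 27L) <= 2L)
  expect_true(abs(steps[[1]]@box["Ymax"] - 46L) <= 2L)
})

test_that("simultaneous well-separated blobs keep distinct identities", {
  frames <- array(0L, dim = c(60, 120, 60))
  frames[6:55, 10:25, 10:19] <- 150L
  frames[11:50, 80:95, 40:49] <- 200L
  trial <- rawTrial(frames, buildGeometry(1, 2, 60))
  tracks <- trackFootsteps(detectTrialObjects(trial))
  expect_equal(length(tracks), 2L)
  steps <- extractFootsteps(trial, tracks)
  b <- box_df(steps)
  b <- b[order(b$Ymin), ]
  expect_equal(b$StartFrame, c(5L, 10L))
  expect_equal(b$EndFrame, c(54L, 49L))
  # tensors are spatially disjoint: each keeps only its own pressure
  expect_true(all(steps[[1]]@tensor %in% c(0, 150)))
  expect_true(all(steps[[2]]@tensor %in% c(0, 200)))
})

test_that("extracted boxes stay within the grid domain", {
  g <- test_geometry()
  sim <- simulateWalkingTrial(test_gait(), test_feet(), g, durationS = 8,
                              seed = 21, startOffsetPx = 10)
  steps <- extractFootsteps(sim$trial,
                            trackFootsteps(detectTrialObjects(sim$trial)))
  b <- box_df(steps)
  expect_true(all(b$Ymin >= 0 & b$Ymax <= gridHeight(g) - 1))
  expect_true(all(b$Xmin >= 0 & b$Xmax <= gridWidth(g) - 1))
  expect_true(all(b$StartFrame <= b$EndFrame))
})

test_that("pass assignment splits on silent gaps and direction changes", {
  steps <- data.frame(
    StartFrame = c(10, 60, 110, 400, 450, 800),
    EndFrame = c(70, 120, 170, 460, 510, 860),
    Orientation = c(1, 1, 1, 0, 0, 0))
  expect_equal(assignPasses(steps, gapFrames = 100), c(0, 0, 0, 1, 1, 2))
  # orientation flip forces a new pass even without a gap
  steps2 <- data.frame(StartFrame = c(10, 60), EndFrame = c(70, 120),
                       Orientation = c(1, 0))
  expect_equal(assignPasses(steps2), c(0, 1))
  expect_equal(assignPasses(steps2[0, ]), integer(0))
})
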
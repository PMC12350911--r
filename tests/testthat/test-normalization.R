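# Alignment, padding, temporal/spatial/amplitude normalization, pipelines.

template_step <- function(archDepth = 0.7, stance = 30L, side = "Right",
                          g = test_geometry()) {
  fp <- test_feet(archDepth); fp$side <- side
  tmpl <- makeFootTemplate(fp, g, stance)
  new("Footstep", tensor = tmpl,
      box = c(StartFrame = 0L, EndFrame = stance - 1L, Ymin = 0L,
              Ymax = dim(tmpl)[2] - 1L, Xmin = 0L, Xmax = dim(tmpl)[3] - 1L),
      trackId = 1L)
}

test_that("alignment recovers applied rotations and composes", {
  g <- test_geometry()
  st <- template_step()
  up <- principalAxisAlign(st, orientation = 0, g)
  base_angle <- up$angle                     # intrinsic axis of the shape
  for (th in c(-25, -12, 7, 20)) {
    rot <- gaitmat:::rotate_stack_nn(st@tensor, th)
    al <- principalAxisAlign(rot, orientation = 0, g)
    expect_lt(abs(al$angle - (base_angle + th)), 1.0)
    # aligning a rotated copy reproduces aligning the original (same dims,
    # nearly the same mass)
    expect_lt(abs(sum(al$tensor > 0) - sum(up$tensor > 0)) /
              sum(up$tensor > 0), 0.06)
  }
  # isotropic cloud: angle falls back to 0 with a warning
  iso <- array(0, dim = c(3, 21, 21))
  iso[, 5:17, 5:17] <- 100
  expect_warning(a0 <- principalAxisAlign(iso, 0, g), "isotropic")
  expect_equal(a0$angle, 0)
})

test_that("orientation flip gives a toe-up canonical pose", {
  g <- test_geometry()
  st <- template_step()                     # canonical: toe at low rows
  al0 <- principalAxisAlign(st, orientation = 0, g)
  flipped <- st
  flipped@tensor <- gaitmat:::rot180_stack(st@tensor)
  al1 <- principalAxisAlign(flipped, orientation = 1, g)
  m0 <- peakPressureImage(al0$tensor); m1 <- peakPressureImage(al1$tensor)
  # heel carries the global pressure maximum and must end up in the lower half
  expect_gt(which.max(apply(m0, 1, max)), nrow(m0) / 2)
  expect_gt(which.max(apply(m1, 1, max)), nrow(m1) / 2)
})

test_that("padding centers the content and conserves pressure exactly", {
  tens <- array(0, dim = c(4, 10, 10))
  tens[, 2:9, 3:8] <- 55
  out <- padAndCenter(tens, 75, 40)
  expect_equal(dim(out), c(4L, 75L, 40L))
  expect_equal(apply(out, 1, sum), apply(tens, 1, sum))
  nz <- which(apply(out > 0, c(2, 3), any), arr.ind = TRUE)
  cen <- colMeans(apply(nz, 2, range))
  expect_lt(abs(cen[1] - 38), 1.1)          # (75+1)/2
  expect_lt(abs(cen[2] - 20.5), 1.1)        # (40+1)/2
  # identity when already at target size
  full <- padAndCenter(tens, 10, 10)
  expect_identical(full, tens)
  expect_error(padAndCenter(array(1, c(2, 80, 10)), 75, 40), "overflow")
})

test_that("temporal resampling copies frames under the enumerated mapping", {
  tens <- array(seq_len(3 * 2 * 2), dim = c(3, 2, 2))
  out <- normalizeTime(tens, 101L)
  src <- rep(NA_integer_, 101)
  for (i in 0:100) src[i + 1] <- if (i <= 25) 1L else if (i <= 75) 2L else 3L
  for (i in 1:101) expect_identical(out[i, , ], tens[src[i], , ])
  # identity at matching length; constant input stays constant
  t101 <- array(rnorm(101 * 4), dim = c(101, 2, 2))
  expect_identical(normalizeTime(t101, 101L), t101)
  const <- array(rep(matrix(1:4, 2), each = 1), dim = c(1, 2, 2))
  rep5 <- normalizeTime(const, 5L)
  for (i in 1:5) expect_identical(rep5[i, , ], const[1, , ])
})

test_that("every output frame is an exact input frame for T_in 1..10", {
  for (tin in 1:10) {
    tens <- array(0, dim = c(tin, 3, 3))
    for (t in seq_len(tin)) tens[t, , ] <- t * 10
    out <- normalizeTime(tens, 101L)
    # endpoint mapping and exact-copy property
    expect_equal(out[1, 1, 1], 10)
    expect_equal(out[101, 1, 1], tin * 10)
    expect_true(all(out[, 1, 1] %in% (seq_len(tin) * 10)))
    # monotone non-decreasing source index
    expect_true(all(diff(out[, 1, 1]) >= 0))
  }
})

test_that("sole dimensions count active pixels along the aligned axes", {
  g <- test_geometry()
  tens <- array(0, dim = c(2, 70, 30))
  tens[, 5:59, 6:23] <- 100                 # solid 55 x 18
  expect_equal(unname(soleDimensions(tens, g)), c(55, 18))
  single <- array(0, dim = c(1, 10, 10)); single[1, 4, 4] <- 50
  expect_equal(unname(soleDimensions(single, g)), c(1, 1))
  # C-shaped mask: compare against direct per-axis counting
  cmask <- array(0, dim = c(1, 20, 20))
  cmask[1, 3:17, 3:6] <- 100; cmask[1, 3:6, 3:17] <- 100
  cmask[1, 14:17, 3:17] <- 100
  m <- cmask[1, , ] >= 10
  expect_equal(unname(soleDimensions(cmask, g)),
               c(max(colSums(m)), max(rowSums(m))))
  expect_error(soleDimensions(array(0, c(1, 5, 5)), g), "no active")
})

test_that("sole resizing reaches the target dimensions by nearest neighbour", {
  g <- test_geometry()
  tens <- array(0, dim = c(3, 40, 16))
  tens[, 3:37, 3:14] <- 200                 # 35 x 12 solid sole
  sd0 <- soleDimensions(tens, g)
  out <- resizeSole(tens, c(70, 25), sd0)
  sd1 <- soleDimensions(out, g)
  expect_lte(abs(sd1[1] - 70), 1)
  expect_lte(abs(sd1[2] - 25), 1)
  # nearest neighbour copies values: per-frame max preserved
  expect_equal(apply(out, 1, max), apply(tens, 1, max))
  # identity scale when already at target
  t2 <- array(0, dim = c(2, 70, 25)); t2[, , ] <- 80
  expect_identical(resizeSole(t2, c(70, 25), soleDimensions(t2, g)), t2)
})

test_that("amplitude modes rescale as specified", {
  tens <- array(0, dim = c(2, 4, 4))
  tens[1, 1:2, 1:2] <- 25                   # frame total 100
  tens[2, 1:2, 1:4] <- 25                   # frame total 200
  res <- normalizeAmplitude(tens, "mean-pressure")
  expect_equal(res$meanPressure, 150)
  expect_equal(apply(res$tensor, 1, sum), c(100, 200) / 150)
  const <- array(50, dim = c(3, 2, 2))      # constant per-frame totals
  nm <- normalizeAmplitude(const, "mean-pressure")
  expect_equal(apply(nm$tensor, 1, sum), rep(1, 3))
  mm <- normalizeAmplitude(tens * 3, "min-max")
  expect_equal(max(mm$tensor), 1)
  expect_equal(min(mm$tensor), 0)
  bm <- normalizeAmplitude(tens, "body-mass", bodyMass = 80)
  expect_equal(bm$tensor, tens / 80)
  expect_error(normalizeAmplitude(array(0, c(1, 2, 2)), "mean-pressure"),
               "all-zero")
  expect_error(normalizeAmplitude(tens, "body-mass"), "body_mass")
})

test_that("preset pipelines produce the published shapes and properties", {
  g <- test_geometry()
  st <- template_step(stance = 37L)
  n1 <- runPipeline(st, pipelinePreset(1), orientation = 0, geometry = g)
  expect_equal(dim(n1$tensor), c(101L, 75L, 40L))
  # every retained frame total appears among the rotated-input frame totals
  al <- principalAxisAlign(st, 0, g)
  in_totals <- round(apply(al$tensor, 1, sum), 9)
  out_totals <- round(apply(n1$tensor, 1, sum), 9)
  expect_true(all(out_totals %in% in_totals))
  expect_false(is.na(n1$RotationAngle))
  expect_true(n1$FootLength >= 1 && n1$FootLength <= 75)
  expect_true(n1$FootWidth >= 1 && n1$FootWidth <= 40)

  n2 <- runPipeline(st, pipelinePreset(2), orientation = 0, geometry = g)
  expect_equal(dim(n2$tensor), c(101L, 75L, 40L))
  # unit mean total pressure after amplitude normalization
  expect_equal(mean(apply(n2$tensor, 1, sum)), 1, tolerance = 1e-9)
  # sole dims on the (amplitude-normalized) output: rescale to kPa first
  sd2 <- soleDimensions(n2$tensor * n2$MeanPressure, g)
  expect_lte(abs(sd2[1] - 70), 1)
  expect_lte(abs(sd2[2] - 25), 1)
})

test_that("empty configs are the identity and bad orders are config errors", {
  g <- test_geometry()
  st <- template_step(stance = 5L)
  ident <- runPipeline(st, pipelineConfig(), orientation = 0, geometry = g)
  expect_identical(ident$tensor, st@tensor)
  expect_error(pipelineConfig(list(op = "resize", L = 70, W = 25)),
               "config error")
  expect_error(pipelineConfig(list(op = "warp")), "config error")
  expect_error(pipelineConfig(list(op = "rotate"),
                              list(op = "resize", L = 70, W = 25),
                              list(op = "pad", H = 60, W = 20)),
               "config error")
})
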
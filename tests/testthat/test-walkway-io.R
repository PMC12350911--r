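# Container round trips and metadata schema validation.

test_that("npz-style containers round-trip bit-exactly", {
  set.seed(1)
  for (i in 1:5) {
    d <- sample(2:9, 3)
    a <- array(sample(0:1500, prod(d), replace = TRUE), dim = d)
    storage.mode(a) <- sample(c("integer", "double"), 1)
    p <- tempfile(fileext = ".npz")
    writeTensor(a, p)
    b <- gaitmat:::read_npz(p, "arr_0")$arr_0
    expect_equal(unname(b), unname(a), tolerance = 0)
    unlink(p)
  }
  # floats with fractional values
  a <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  p <- tempfile(fileext = ".npz")
  writeTensor(a, p)
  expect_identical(gaitmat:::read_npz(p, "arr_0")$arr_0, a)
  unlink(p)
})

test_that("mat-style containers round-trip bit-exactly", {
  set.seed(2)
  for (compress in c(TRUE, FALSE)) {
    a <- array(sample(0:1500, 120, replace = TRUE), dim = c(4, 5, 6))
    p <- tempfile(fileext = ".mat")
    gaitmat:::write_mat(p, list(arr_0 = a), compress = compress)
    b <- gaitmat:::read_mat(p, "arr_0")$arr_0
    expect_equal(unname(b), unname(a), tolerance = 0)
    unlink(p)
  }
  a <- array(rnorm(60), dim = c(3, 4, 5))
  p <- tempfile(fileext = ".mat")
  writeTensor(a, p)
  expect_identical(gaitmat:::read_mat(p, "arr_0")$arr_0, a)
  unlink(p)
})

test_that("trials round-trip through both containers with tags and shape checks", {
  g <- buildGeometry(1, 2, 10)
  a <- array(sample(seq(0, 100, by = 10), 200 * 20 * 10, replace = TRUE),
             dim = c(200, 20, 10))
  tr <- rawTrial(a, g, participantID = "001", footwear = "BF", task = "W1")
  for (ext in c("npz", "mat")) {
    p <- tempfile(fileext = paste0(".", ext))
    writeTrial(tr, p)
    back <- readTrial(p, g, participantID = "001", footwear = "BF",
                      task = "W1")
    expect_equal(nFrames(back), 200L)
    expect_equal(trialFrames(back), trialFrames(tr), tolerance = 0)
    unlink(p)
  }
})

test_that("lazy npz trials stream frames identical to eager reads", {
  g <- buildGeometry(1, 1, 16)
  a <- array(sample(seq(0, 1510, by = 10), 50 * 16 * 16, replace = TRUE),
             dim = c(50, 16, 16))
  p <- tempfile(fileext = ".npz")
  writeTensor(a, p)
  lz <- readTrial(p, g, lazy = TRUE)
  expect_gt(length(lz@source), 0L)
  expect_equal(nFrames(lz), 50L)
  idx <- c(1L, 7L, 50L)
  expect_equal(trialFrames(lz, idx), a[idx, , , drop = FALSE] * 1.0)
  unlink(p)
})

test_that("missing keys and malformed shapes raise format/shape errors", {
  g <- buildGeometry(1, 1, 8)
  p <- tempfile(fileext = ".npz")
  gaitmat:::write_npz(p, list(other = array(0, c(2, 8, 8))))
  expect_error(readTrial(p, g), "arr_0")
  unlink(p)
  p2 <- tempfile(fileext = ".npz")
  writeTensor(matrix(0, 8, 8), p2)          # rank 2, not a trial
  expect_error(readTrial(p2, g), "shape error")
  unlink(p2)
  p3 <- tempfile(fileext = ".npz")
  writeTensor(array(0, c(5, 4, 4)), p3)     # wrong grid size
  expect_error(readTrial(p3, g), "shape error")
  unlink(p3)
})

test_that("4D preprocessed tensors write and read, including n = 0", {
  for (ext in c("npz", "mat")) {
    p <- tempfile(fileext = paste0(".", ext))
    a <- array(runif(2 * 101 * 75 * 40), dim = c(2, 101, 75, 40))
    writeTensor(a, p)
    rd <- if (ext == "npz") gaitmat:::read_npz(p, "arr_0")$arr_0
          else gaitmat:::read_mat(p, "arr_0")$arr_0
    expect_equal(dim(rd), c(2L, 101L, 75L, 40L))
    expect_equal(unname(rd), unname(a))
    empty <- array(0, dim = c(0, 101, 75, 40))
    writeTensor(empty, p)
    rd <- if (ext == "npz") gaitmat:::read_npz(p, "arr_0")$arr_0
          else gaitmat:::read_mat(p, "arr_0")$arr_0
    expect_equal(dim(rd)[1L], 0L)
    unlink(p)
  }
})

valid_metadata_row <- function() {
  data.frame(ParticipantID = "001", Footwear = "BF", Speed = "W1",
             FootstepID = 0L, PassID = 0L, StartFrame = 100L,
             EndFrame = 160L, Ymin = 50L, Ymax = 110L, Xmin = 60L,
             Xmax = 85L, Orientation = 1L, Side = "Left", Standing = 0L,
             Incomplete = 0L, Rscore = 0.7, Outlier = 0L, Exclude = 0L,
             RotationAngle = 4.5, FootLength = 50L, FootWidth = 18L,
             MeanPressure = 88000.5, stringsAsFactors = FALSE)
}

test_that("schema validator accepts valid rows and the flag identities", {
  md <- valid_metadata_row()
  expect_equal(nrow(validateFootstepMetadata(md)), 0L)
  # Standing forces Exclude
  md2 <- md; md2$Standing <- 1L; md2$Exclude <- 1L
  expect_equal(nrow(validateFootstepMetadata(md2)), 0L)
  md2$Exclude <- 0L
  v <- validateFootstepMetadata(md2)
  expect_true(any(v$field == "Exclude"))
  # Rscore above threshold requires Outlier
  md3 <- md; md3$Rscore <- 2.3
  v <- validateFootstepMetadata(md3)
  expect_true(any(v$field == "Outlier"))
})

test_that("schema validator flags every single-field corruption", {
  corrupt <- list(
    Footwear = "XX", Speed = "W9", Side = "Centre", Orientation = 2,
    Standing = -1, Incomplete = 3, Outlier = "yes", Exclude = 2,
    StartFrame = -4, Ymin = 900, Ymax = -1, Xmin = 500, Xmax = 1e4,
    Rscore = -0.1, RotationAngle = 120, FootLength = 0, FootWidth = 90)
  for (field in names(corrupt)) {
    md <- valid_metadata_row()
    md[[field]] <- corrupt[[field]]
    v <- validateFootstepMetadata(md)
    expect_gt(nrow(v), 0)
  }
  md <- valid_metadata_row()
  md$Extra <- 1
  expect_true(any(validateFootstepMetadata(md)$problem == "unknown column"))
  md <- valid_metadata_row()
  md$Side <- NULL
  expect_true(any(validateFootstepMetadata(md)$problem == "missing column"))
})

test_that("metadata csv round-trips and empty tables validate", {
  md <- rbind(valid_metadata_row(), valid_metadata_row())
  md$FootstepID <- 0:1
  p <- tempfile(fileext = ".csv")
  writeFootstepMetadata(md, p)
  back <- readFootstepMetadata(p)
  expect_equal(names(back), names(md))
  expect_equal(back$Rscore, md$Rscore)
  expect_equal(nrow(validateFootstepMetadata(back)), 0L)
  empty <- md[0, ]
  writeFootstepMetadata(empty, p)
  back <- readFootstepMetadata(p)
  expect_equal(nrow(back), 0L)
  expect_equal(nrow(validateFootstepMetadata(back)), 0L)
  unlink(p)
})

test_that("dataset tree layout matches the published structure", {
  g <- buildGeometry(1, 2, 8)
  mk_trial <- function(task) rawTrial(array(0, c(10, 16, 8)), g, "001", "BF",
                                      task)
  results <- list(
    list(participantID = "001", footwear = "BF", task = "S1",
         trial = mk_trial("S1"), preprocessed = array(0, c(10, 4, 4))),
    list(participantID = "001", footwear = "BF", task = "W1",
         trial = mk_trial("W1"), pipeline1 = array(0, c(2, 5, 4, 3)),
         pipeline2 = array(0, c(2, 5, 4, 3)),
         metadata = valid_metadata_row()))
  root <- file.path(tempdir(), "tree-test")
  unlink(root, recursive = TRUE)
  ppl <- data.frame(ParticipantID = "001", Sex = "Female", Age = 34L,
                    `Weight (Kg)` = 70.5, check.names = FALSE)
  writeDatasetTree(results, root, participants = ppl)
  expect_true(file.exists(file.path(root, "participant_metadata.csv")))
  expect_setequal(list.files(file.path(root, "py", "001", "BF", "S1")),
                  c("trial.npz", "preprocessed.npz"))
  expect_setequal(list.files(file.path(root, "mat", "001", "BF", "W1")),
                  c("trial.mat", "pipeline_1.mat", "pipeline_2.mat",
                    "metadata.csv"))
  expect_error(writeDatasetTree(results, root), "refusing")
  expect_silent(writeDatasetTree(results, root, overwrite = TRUE))
  unlink(root, recursive = TRUE)
})
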
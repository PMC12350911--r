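#' Construct an in-memory RawTrial
#'
#' @param frames numeric or integer array (n x H x W), pressures in kPa.
#' @param geometry a \linkS4class{WalkwayGeometry} the frames must match.
#' @param participantID,footwear,task condition tags.
#' @return A \linkS4class{RawTrial}.
#' @export
rawTrial <- function(frames, geometry, participantID = "", footwear = "",
                     task = "") {
  new("RawTrial", frames = frames, source = list(),
      participantID = as.character(participantID),
      footwear = as.character(footwear), task = as.character(task),
      geometry = geometry)
}

#' RawTrial accessors
#'
#' \code{trialDim} returns c(frames, height, width); \code{nFrames} the frame
#' count; \code{trialFrames} materializes the requested frames as an
#' idx x H x W array (reading from disk for file-backed trials);
#' \code{trialGeometry} the geometry.
#'
#' @param trial a \linkS4class{RawTrial}.
#' @param idx integer frame indices (1-based).
#' @name trial-accessors
#' @export
trialDim <- function(trial) {
  if (length(trial@source)) trial@source$dim else dim(trial@frames)
}

#' @rdname trial-accessors
#' @export
nFrames <- function(trial) trialDim(trial)[1L]

#' @rdname trial-accessors
#' @export
trialFrames <- function(trial, idx = seq_len(nFrames(trial))) {
  if (length(trial@source))
    npz_read_frames(trial@source, idx)
  else
    trial@frames[idx, , , drop = FALSE]
}

#' @rdname trial-accessors
#' @export
trialGeometry <- function(trial) trial@geometry

# materialize a file-backed trial into memory
trial_materialize <- function(trial) {
  if (!length(trial@source)) return(trial)
  rawTrial(trialFrames(trial), trial@geometry, trial@participantID,
           trial@footwear, trial@task)
}

infer_container <- function(path, container) {
  container <- match.arg(container, c("auto", "npz", "mat"))
  if (container != "auto") return(container)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("npz", "mat")) ext
  else stop("cannot infer container from extension '", ext, "'")
}

#' Read a raw trial tensor from an NPZ-style or MAT-style container
#'
#' The tensor must be stored under the top-level key \code{arr_0} as a rank-3
#' array (frames x height x width) of pressures in kPa. With
#' \code{lazy = TRUE} and an uncompressed NPZ-style file, a file-backed trial
#' is returned whose frames are read on demand by \code{\link{trialFrames}},
#' so large raw tensors are never held in memory at once.
#'
#' @param path file path.
#' @param geometry expected \linkS4class{WalkwayGeometry}.
#' @param container "npz", "mat", or "auto" (from the extension).
#' @param lazy return a file-backed trial when the container supports it.
#' @param participantID,footwear,task condition tags to attach.
#' @return A \linkS4class{RawTrial}.
#' @export
readTrial <- function(path, geometry, container = "auto", lazy = FALSE,
                      participantID = "", footwear = "", task = "") {
  container <- infer_container(path, container)
  if (!file.exists(path)) stop("file not found: ", path)
  if (lazy && container == "npz") {
    h <- npz_open_lazy(path, "arr_0")
    if (!is.null(h)) {
      check_trial_shape(h$dim, geometry)
      return(new("RawTrial", frames = array(0, c(0, 0, 0)), source = h,
                 participantID = as.character(participantID),
                 footwear = as.character(footwear), task = as.character(task),
                 geometry = geometry))
    }
  }
  a <- if (container == "npz") read_npz(path, "arr_0")$arr_0
       else read_mat(path, "arr_0")$arr_0
  check_trial_shape(dim(a), geometry)
  rawTrial(a, geometry, participantID, footwear, task)
}

check_trial_shape <- function(d, geometry) {
  if (length(d) != 3L)
    stop("shape error: expected rank-3 tensor, got rank ", length(d))
  if (d[2L] != gridHeight(geometry) || d[3L] != gridWidth(geometry))
    stop(sprintf("shape error: frames are %d x %d but geometry is %d x %d",
                 d[2L], d[3L], gridHeight(geometry), gridWidth(geometry)))
}

#' Write a tensor to an NPZ-style or MAT-style container
#'
#' \code{writeTrial} writes a \linkS4class{RawTrial}'s frames;
#' \code{writeTensor} writes any numeric array (e.g. the 4D
#' n x 101 x 75 x 40 outputs of the normalization pipelines, including n = 0).
#' Both store the array under key \code{arr_0};
#' \code{readTrial(writeTrial(x))} round-trips bit-exactly.
#'
#' @param trial a \linkS4class{RawTrial}.
#' @param a a numeric array.
#' @param path destination path.
#' @param container "npz", "mat", or "auto".
#' @export
writeTrial <- function(trial, path, container = "auto") {
  writeTensor(trialFrames(trial), path, container)
}

#' @rdname writeTrial
#' @export
writeTensor <- function(a, path, container = "auto") {
  container <- infer_container(path, container)
  ok <- dir.exists(dirname(path))
  if (!ok) stop("I/O error: directory does not exist: ", dirname(path))
  if (container == "npz") write_npz(path, list(arr_0 = a))
  else write_mat(path, list(arr_0 = a))
  invisible(path)
}

# --- footstep metadata schema ----------------------------------------------

footstep_metadata_columns <- c(
  "ParticipantID", "Footwear", "Speed", "FootstepID", "PassID", "StartFrame",
  "EndFrame", "Ymin", "Ymax", "Xmin", "Xmax", "Orientation", "Side",
  "Standing", "Incomplete", "Rscore", "Outlier", "Exclude", "RotationAngle",
  "FootLength", "FootWidth", "MeanPressure")

#' Read a per-trial footstep metadata table
#'
#' Reads a \code{metadata.csv} (comma-separated, UTF-8, header row) with one
#' row per footstep. Columns are typed but not silently coerced: use
#' \code{\link{validateFootstepMetadata}} to check the schema.
#'
#' @param path CSV file path.
#' @return data.frame with one row per footstep.
#' @export
readFootstepMetadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                  check.names = FALSE)
}

#' Write a footstep metadata table
#'
#' @param metadata data.frame in the footstep metadata schema.
#' @param path destination CSV path.
#' @export
writeFootstepMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a footstep metadata table against its schema
#'
#' Checks column names, per-field value domains, ordering constraints
#' (StartFrame <= EndFrame, Ymin <= Ymax, Xmin <= Xmax and grid bounds), and
#' the two cross-field identities: Exclude = Standing OR Incomplete OR
#' Outlier, and Outlier = 1 iff Rscore >= the outlier threshold.
#'
#' @param metadata data.frame to validate.
#' @param geometry \linkS4class{WalkwayGeometry} fixing the grid bounds.
#' @param outlierThreshold R-score cutoff the Outlier column must reflect.
#' @return data.frame of violations with columns row, field, problem
#'   (zero rows when the table is valid).
#' @export
validateFootstepMetadata <- function(metadata, geometry = buildGeometry(),
                                     outlierThreshold = 2.0) {
  v <- list()
  bad <- function(row, field, problem)
    v[[length(v) + 1L]] <<- data.frame(row = row, field = field,
                                       problem = problem,
                                       stringsAsFactors = FALSE)
  unknown <- setdiff(names(metadata), footstep_metadata_columns)
  for (u in unknown) bad(NA_integer_, u, "unknown column")
  missing <- setdiff(footstep_metadata_columns, names(metadata))
  for (m in missing) bad(NA_integer_, m, "missing column")
  if (length(missing) || nrow(metadata) == 0L)
    return(do.call(rbind, v) %||%
             data.frame(row = integer(), field = character(),
                        problem = character()))

  chk_domain <- function(field, ok) {
    w <- which(!ok)
    for (i in w) bad(i, field, sprintf("out-of-domain value '%s'",
                                       metadata[[field]][i]))
  }
  num_ok <- function(field) {
    x <- suppressWarnings(as.numeric(metadata[[field]]))
    w <- which(is.na(x))
    for (i in w) bad(i, field, "non-numeric value")
    x
  }
  chk_domain("Footwear", metadata$Footwear %in% c("BF", "ST", "P1", "P2"))
  chk_domain("Speed", metadata$Speed %in% c("W1", "W2", "W3", "W4"))
  chk_domain("Side", metadata$Side %in% c("Left", "Right"))
  for (f in c("Orientation", "Standing", "Incomplete", "Outlier", "Exclude")) {
    x <- num_ok(f)
    chk_domain(f, !is.na(x) & x %in% c(0, 1))
  }
  sf <- num_ok("StartFrame"); ef <- num_ok("EndFrame")
  chk_domain("StartFrame", !is.na(sf) & sf >= 0)
  w <- which(!is.na(sf) & !is.na(ef) & sf > ef)
  for (i in w) bad(i, "StartFrame", "StartFrame > EndFrame")
  ymin <- num_ok("Ymin"); ymax <- num_ok("Ymax")
  xmin <- num_ok("Xmin"); xmax <- num_ok("Xmax")
  H <- gridHeight(geometry); W <- gridWidth(geometry)
  chk_domain("Ymin", !is.na(ymin) & ymin >= 0 & ymin <= H - 1)
  chk_domain("Ymax", !is.na(ymax) & ymax >= 0 & ymax <= H - 1)
  chk_domain("Xmin", !is.na(xmin) & xmin >= 0 & xmin <= W - 1)
  chk_domain("Xmax", !is.na(xmax) & xmax >= 0 & xmax <= W - 1)
  w <- which(!is.na(ymin) & !is.na(ymax) & ymin > ymax)
  for (i in w) bad(i, "Ymin", "Ymin > Ymax")
  w <- which(!is.na(xmin) & !is.na(xmax) & xmin > xmax)
  for (i in w) bad(i, "Xmin", "Xmin > Xmax")
  rs <- num_ok("Rscore")
  chk_domain("Rscore", is.na(rs) | rs >= 0)
  ra <- num_ok("RotationAngle")
  chk_domain("RotationAngle", !is.na(ra) & ra >= -90 & ra <= 90)
  fl <- num_ok("FootLength")
  chk_domain("FootLength", !is.na(fl) & fl >= 1 & fl <= 75)
  fw <- num_ok("FootWidth")
  chk_domain("FootWidth", !is.na(fw) & fw >= 1 & fw <= 40)
  num_ok("MeanPressure")

  st <- suppressWarnings(as.numeric(metadata$Standing))
  inc <- suppressWarnings(as.numeric(metadata$Incomplete))
  ol <- suppressWarnings(as.numeric(metadata$Outlier))
  ex <- suppressWarnings(as.numeric(metadata$Exclude))
  w <- which(!is.na(st + inc + ol + ex) &
             ex != pmin(1, st + inc + ol))
  for (i in w)
    bad(i, "Exclude", "Exclude != Standing OR Incomplete OR Outlier")
  w <- which(!is.na(rs) & !is.na(ol) & ol != as.numeric(rs >= outlierThreshold))
  for (i in w)
    bad(i, "Outlier", sprintf("Outlier inconsistent with Rscore %s at threshold %g",
                              metadata$Rscore[i], outlierThreshold))
  do.call(rbind, v) %||%
    data.frame(row = integer(), field = character(), problem = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- dataset tree -----------------------------------------------------------

#' Write a session's results as a dataset folder tree
#'
#' Lays out results as \code{root/{py,mat}/XXX/{BF,ST,P1,P2}/{S1..S3,W1..W4}/}.
#' Balance leaves receive \code{trial.*} and \code{preprocessed.*}; walking
#' leaves receive \code{trial.*}, \code{pipeline_1.*}, \code{pipeline_2.*} and
#' \code{metadata.csv}. Containers: "py" writes .npz files, "mat" writes .mat.
#'
#' @param results list of per-trial result entries, each a list with elements
#'   \code{participantID}, \code{footwear}, \code{task}, \code{trial}
#'   (\linkS4class{RawTrial}), and, depending on the task, \code{preprocessed}
#'   (3D array) or \code{pipeline1}, \code{pipeline2} (4D arrays) and
#'   \code{metadata} (data.frame).
#' @param root destination directory.
#' @param containers subset of c("py", "mat").
#' @param participants optional data.frame written as the top-level
#'   \code{participant_metadata.csv} (one row per participant).
#' @param overwrite allow writing into an existing non-empty tree.
#' @return invisibly, the paths written.
#' @export
writeDatasetTree <- function(results, root, containers = c("py", "mat"),
                             participants = NULL, overwrite = FALSE) {
  containers <- match.arg(containers, c("py", "mat"), several.ok = TRUE)
  if (dir.exists(root) && length(list.files(root)) && !overwrite)
    stop("refusing to write into existing non-empty tree: ", root,
         " (use overwrite = TRUE)")
  written <- character()
  if (!is.null(participants)) {
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(root, "participant_metadata.csv")
    utils::write.csv(participants, p, row.names = FALSE, fileEncoding = "UTF-8")
    written <- c(written, p)
  }
  for (res in results) {
    for (cont in containers) {
      ext <- if (cont == "py") "npz" else "mat"
      leaf <- file.path(root, cont, res$participantID, res$footwear, res$task)
      dir.create(leaf, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(leaf, paste0("trial.", ext))
      writeTrial(res$trial, p)
      written <- c(written, p)
      if (grepl("^S", res$task)) {
        if (!is.null(res$preprocessed)) {
          p <- file.path(leaf, paste0("preprocessed.", ext))
          writeTensor(res$preprocessed, p)
          written <- c(written, p)
        }
      } else {
        for (nm in c("pipeline1", "pipeline2")) {
          if (is.null(res[[nm]])) next
          p <- file.path(leaf, paste0(sub("pipeline", "pipeline_", nm), ".", ext))
          writeTensor(res[[nm]], p)
          written <- c(written, p)
        }
        if (!is.null(res$metadata)) {
          p <- file.path(leaf, "metadata.csv")
          writeFootstepMetadata(res$metadata, p)
          written <- c(written, p)
        }
      }
    }
  }
  invisible(written)
}
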
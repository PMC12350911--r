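# End-to-end orchestration: detect -> track -> extract -> label -> QC ->
# normalize, producing the per-trial metadata table and preprocessed tensors.

#' Run configuration for trial processing
#'
#' Defaults reproduce the reference device constants: 10 kPa activation,
#' dilation radius 4 / erosion radius 2, 20 px centroid merging, 101 x 75 x 40
#' (and 70 x 25 sole) normalization targets, R-score threshold 2.0.
#'
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @param detection \code{\link{detectionParams}}.
#' @param tracker \code{\link{trackerParams}}.
#' @param gapFrames pass-separation gap (frames).
#' @param qcThreshold R-score outlier threshold.
#' @param pipelines which preset normalizations to run (subset of 1:2).
#' @export
runConfig <- function(geometry = buildGeometry(),
                      detection = detectionParams(),
                      tracker = trackerParams(), gapFrames = 100L,
                      qcThreshold = 2.0, pipelines = c(1L, 2L)) {
  list(geometry = geometry, detection = detection, tracker = tracker,
       gapFrames = as.integer(gapFrames), qcThreshold = qcThreshold,
       pipelines = pipelines)
}

#' Process one walking trial end to end
#'
#' Runs detection, tracking, extraction, labeling (orientation, side,
#' incomplete, standing for W2 trials), pass assignment, R-score quality
#' control and the requested normalization pipelines. Deterministic given the
#' input trial and configuration.
#'
#' @param trial \linkS4class{RawTrial} of a walking recording.
#' @param config \code{\link{runConfig}}.
#' @return list: \code{footsteps} (list of \linkS4class{Footstep}, ordered by
#'   StartFrame), \code{metadata} (data.frame in the footstep metadata
#'   schema, one row per step), \code{pipeline1}/\code{pipeline2} (4D arrays
#'   n x 101 x 75 x 40 when requested), \code{log} (character).
#' @export
processTrial <- function(trial, config = runConfig(trialGeometry(trial))) {
  geometry <- config$geometry
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  objs <- detectTrialObjects(trial, config$detection)
  tracks <- trackFootsteps(objs, config$tracker)
  steps <- extractFootsteps(trial, tracks)
  if (!length(steps)) {
    note("no footsteps detected")
    return(list(footsteps = list(), metadata = empty_metadata(),
                pipeline1 = NULL, pipeline2 = NULL, log = log))
  }
  ord <- order(vapply(steps, function(s) s@box["StartFrame"], integer(1)))
  steps <- steps[ord]
  n <- length(steps)
  note("extracted %d footsteps from %d tracks", n, length(tracks))

  boxes <- do.call(rbind, lapply(steps, function(s) as.data.frame(t(s@box))))
  orientation <- vapply(steps, labelOrientation, integer(1),
                        geometry = geometry)
  boxes$Orientation <- orientation
  pass <- assignPasses(boxes, config$gapFrames)
  side <- vapply(seq_len(n), function(i)
    labelSide(steps[[i]], orientation[i], geometry), character(1))
  incomplete <- flagIncomplete(steps, nFrames(trial), geometry)
  standing <- if (identical(trial@task, "W2")) flagStanding(steps, geometry)
              else integer(n)
  if (length(standing) == 1L) standing <- rep(standing, n)

  norm1 <- norm2 <- vector("list", n)
  rotation <- footlen <- footwid <- meanp <- rep(NA_real_, n)
  try_pipeline <- function(step, preset, ori) {
    tryCatch(suppressWarnings(runPipeline(step, pipelinePreset(preset), ori,
                                          geometry)),
             error = function(e) {
               note("pipeline %d failed for a step: %s", preset,
                    conditionMessage(e))
               NULL
             })
  }
  for (i in seq_len(n)) {
    if (1L %in% config$pipelines)
      norm1[[i]] <- try_pipeline(steps[[i]], 1L, orientation[i])
    if (2L %in% config$pipelines)
      norm2[[i]] <- try_pipeline(steps[[i]], 2L, orientation[i])
    src <- if (!is.null(norm1[[i]])) norm1[[i]] else norm2[[i]]
    if (!is.null(src)) {
      rotation[i] <- src$RotationAngle
      footlen[i] <- src$FootLength
      footwid[i] <- src$FootWidth
      meanp[i] <- src$MeanPressure
    }
  }

  rsc <- rScores(steps, excluded = standing | incomplete, geometry = geometry)
  outlier <- flagOutliers(rsc, config$qcThreshold)
  exclude <- combineExclude(standing, incomplete, outlier)
  for (i in which(exclude == 1L))
    note("step %d excluded (standing=%d incomplete=%d outlier=%d)", i - 1L,
         standing[i], incomplete[i], outlier[i])

  metadata <- data.frame(
    ParticipantID = trial@participantID, Footwear = trial@footwear,
    Speed = trial@task, FootstepID = seq_len(n) - 1L, PassID = pass,
    StartFrame = boxes$StartFrame, EndFrame = boxes$EndFrame,
    Ymin = boxes$Ymin, Ymax = boxes$Ymax, Xmin = boxes$Xmin,
    Xmax = boxes$Xmax, Orientation = orientation, Side = side,
    Standing = standing, Incomplete = incomplete,
    Rscore = round(rsc, 4), Outlier = outlier, Exclude = exclude,
    RotationAngle = round(rotation, 2), FootLength = footlen,
    FootWidth = footwid, MeanPressure = round(meanp, 2),
    stringsAsFactors = FALSE)

  stack4 <- function(lst) {
    ok <- which(!vapply(lst, is.null, logical(1)))
    if (!length(ok)) return(NULL)
    d <- dim(lst[[ok[1L]]]$tensor)
    out <- array(0, dim = c(length(lst), d))   # failed steps stay all-zero
    for (i in ok) out[i, , , ] <- lst[[i]]$tensor
    out
  }
  list(footsteps = steps, metadata = metadata,
       pipeline1 = stack4(norm1), pipeline2 = stack4(norm2), log = log)
}

empty_metadata <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)),
                                   length(footstep_metadata_columns)),
                               footstep_metadata_columns))
  df
}
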
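# Biomechanical representations: GRF, COP, peak-pressure images,
# spatiotemporal gait parameters, balance preprocessing.

tensor3 <- function(x) {
  if (is(x, "Footstep")) x <- x@tensor
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Vertical ground reaction force series
#'
#' GRF(t) [N] = 1000 x A [m^2] x sum_{x,y} p_xy(t) [kPa], with A the area of
#' one sensor. Zero wherever the frame has no pressure.
#'
#' @param x \linkS4class{Footstep} or T x h x w pressure array (kPa).
#' @param geometry \linkS4class{WalkwayGeometry} (fixes A).
#' @return numeric vector, one force in Newtons per frame.
#' @export
grfSeries <- function(x, geometry) {
  x <- tensor3(x)
  1000 * sensorArea(geometry) * apply(x, 1L, sum)
}

#' Center-of-pressure trajectory
#'
#' The pressure-weighted average of the foot's coordinates at each time step:
#' COP_ML(t) = s * sum(x p) / sum(p), COP_AP(t) = s * sum(y p) / sum(p), with
#' s the sensor side length in cm and 0-based pixel coordinates (plus the
#' supplied offsets, e.g. a footstep box origin, to express the trajectory in
#' grid coordinates). Frames with zero total pressure are dropped. The
#' centered variant subtracts the per-component time mean.
#'
#' @param x \linkS4class{Footstep} or pressure array.
#' @param geometry \linkS4class{WalkwayGeometry} (fixes s).
#' @param centered subtract per-component means.
#' @param yOffset,xOffset 0-based origin of the tensor in grid coordinates.
#' @return data.frame with columns \code{frame} (1-based index of retained
#'   frames), \code{ml}, \code{ap} (cm).
#' @export
copSeries <- function(x, geometry, centered = FALSE, yOffset = 0, xOffset = 0) {
  x <- tensor3(x)
  s <- sensorPitch(geometry)
  d <- dim(x)
  tot <- apply(x, 1L, sum)
  keep <- which(tot > 0)
  if (!length(keep)) stop("all frames have zero total pressure")
  ys <- seq_len(d[2L]) - 1 + yOffset
  xs <- seq_len(d[3L]) - 1 + xOffset
  ap <- ml <- numeric(length(keep))
  for (k in seq_along(keep)) {
    fr <- x[keep[k], , ]
    ap[k] <- sum(ys * rowSums(fr)) / tot[keep[k]]
    ml[k] <- sum(xs * colSums(fr)) / tot[keep[k]]
  }
  ml <- ml * s; ap <- ap * s
  if (centered) { ml <- ml - mean(ml); ap <- ap - mean(ap) }
  data.frame(frame = keep, ml = ml, ap = ap)
}

#' Peak-pressure image
#'
#' Element-wise maximum over time: the highest pressure each sensor saw during
#' the stance.
#'
#' @param x \linkS4class{Footstep} or pressure array.
#' @return h x w matrix.
#' @export
peakPressureImage <- function(x) {
  x <- tensor3(x)
  apply(x, c(2L, 3L), max)
}

#' Spatiotemporal gait parameters for one pass
#'
#' Computed from distances between the 3D bounding boxes of consecutive
#' footsteps: step length = |delta y| between consecutive box centroids x
#' pitch, step width = |delta x| x pitch, step time = delta StartFrame / rate
#' (initial contact to initial contact), cadence = 60 / step time, speed =
#' step length / step time, stance time = contact duration. Toe-out is the
#' side-signed principal-axis angle: positive = external (lateral) rotation,
#' computed as -RotationAngle for Right feet and +RotationAngle for Left feet
#' under the package's grid convention.
#'
#' @param steps data.frame of footsteps in one pass, ordered by StartFrame,
#'   with columns StartFrame, EndFrame, Ymin, Ymax, Xmin, Xmax, RotationAngle,
#'   Side.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @return data.frame, one row per step: stanceTimeS, toeOutDeg always;
#'   stepLengthCm, stepWidthCm, stepTimeS, cadence, speedMs from the second
#'   step of the pass on (NA for the first).
#' @export
spatiotemporalParameters <- function(steps, geometry) {
  n <- nrow(steps)
  if (n < 1L) stop("need at least one step")
  pitch <- sensorPitch(geometry)
  rate <- sampleRate(geometry)
  cy <- (steps$Ymin + steps$Ymax) / 2
  cx <- (steps$Xmin + steps$Xmax) / 2
  out <- data.frame(
    stanceTimeS = (steps$EndFrame - steps$StartFrame + 1) / rate,
    toeOutDeg = ifelse(steps$Side == "Right", -1, 1) * steps$RotationAngle,
    stepLengthCm = NA_real_, stepWidthCm = NA_real_, stepTimeS = NA_real_,
    cadence = NA_real_, speedMs = NA_real_)
  if (n >= 2L) {
    i <- 2:n
    out$stepLengthCm[i] <- abs(diff(cy)) * pitch
    out$stepWidthCm[i] <- abs(diff(cx)) * pitch
    out$stepTimeS[i] <- diff(steps$StartFrame) / rate
    out$cadence[i] <- 60 / out$stepTimeS[i]
    out$speedMs[i] <- out$stepLengthCm[i] / 100 / out$stepTimeS[i]
  }
  out
}

rot90_frame <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Preprocess a balance trial
#'
#' Crops the recording to the region of interest (bounding box of every pixel
#' that ever reaches the activation threshold), zero-pads it to
#' \code{outputHW} x \code{outputHW} pixels, rotates in 90-degree increments
#' so the feet are upright (toes toward the top row, heels down), and crops
#' temporally to the last \code{outputFrames} frames.
#'
#' @param trial \linkS4class{RawTrial} of a standing balance recording.
#' @param orientationHint "auto" (long axis made vertical, heel region -- the
#'   peak-pressure maximum -- placed in the lower half) or an explicit number
#'   of 90-degree counterclockwise increments (0-3).
#' @param outputHW spatial output size (pixels).
#' @param outputFrames temporal output length.
#' @param shortPolicy "pad" (zero-pad at the start, with a warning) or
#'   "error" when the trial has fewer than \code{outputFrames} frames.
#' @return array outputFrames x outputHW x outputHW.
#' @export
preprocessBalance <- function(trial, orientationHint = "auto",
                              outputHW = 180L, outputFrames = 3000L,
                              shortPolicy = c("pad", "error")) {
  shortPolicy <- match.arg(shortPolicy)
  geometry <- trialGeometry(trial)
  n <- nFrames(trial)
  # temporal crop first: keep the trailing outputFrames
  if (n >= outputFrames) {
    idx <- (n - outputFrames + 1L):n
    pad_front <- 0L
  } else {
    if (shortPolicy == "error")
      stop("trial has ", n, " < ", outputFrames, " frames")
    warning("trial has ", n, " < ", outputFrames, " frames; zero-padding")
    idx <- seq_len(n)
    pad_front <- outputFrames - n
  }
  frames <- trialFrames(trial, idx)
  peak <- apply(frames, c(2L, 3L), max)
  act <- peak >= geometry@activationKpa
  if (!any(act)) stop("no activity above threshold in balance trial")
  ry <- range(which(rowSums(act) > 0))
  rx <- range(which(colSums(act) > 0))
  h <- ry[2L] - ry[1L] + 1L; w <- rx[2L] - rx[1L] + 1L
  if (max(h, w) > outputHW)
    stop("activity extent ", h, " x ", w, " exceeds ", outputHW, " px")
  if (identical(orientationHint, "auto")) {
    # decide from one foot (largest connected region), not the two-feet union
    sub <- act[ry[1L]:ry[2L], rx[1L]:rx[2L], drop = FALSE]
    lab <- .label_components(sub, 8L)
    big <- which(lab == which.max(tabulate(lab[lab > 0L])), arr.ind = TRUE)
    fh <- diff(range(big[, 1L])); fw <- diff(range(big[, 2L]))
    k <- if (fw > fh) 1L else 0L
    pk <- rot90_frame(peak[ry[1L]:ry[2L], rx[1L]:rx[2L], drop = FALSE], k)
    heel_row <- which(pk == max(pk), arr.ind = TRUE)[1L, 1L]
    if (heel_row < nrow(pk) / 2) k <- k + 2L
  } else k <- as.integer(orientationHint)
  if (k %% 2 == 1L) { tmp <- h; h <- w; w <- tmp }
  if (max(h, w) > outputHW)
    stop("activity extent after rotation exceeds ", outputHW, " px")
  y0 <- (outputHW - h) %/% 2L
  x0 <- (outputHW - w) %/% 2L
  out <- array(0, dim = c(outputFrames, outputHW, outputHW))
  for (t in seq_along(idx)) {
    fr <- rot90_frame(frames[t, ry[1L]:ry[2L], rx[1L]:rx[2L], drop = FALSE], k)
    out[pad_front + t, y0 + seq_len(h), x0 + seq_len(w)] <- fr
  }
  out
}
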
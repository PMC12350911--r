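# Footstep labels: Orientation, Side, Incomplete, Standing.

#' Label walking direction (Orientation)
#'
#' Compares the anteroposterior (grid-frame y) center of pressure at the
#' beginning and end of the footstep: orientation = 1 (walking toward
#' increasing y) when the mean AP COP over the last 10\% of frames exceeds the
#' mean over the first 10\%, else 0. First/last 10\% means (rather than single
#' frames) are robust to touchdown/lift-off noise.
#'
#' @param step \linkS4class{Footstep}.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @return integer 0 or 1 (single-frame steps are labeled 1 with a warning).
#' @export
labelOrientation <- function(step, geometry = buildGeometry()) {
  tens <- tensor3(step)
  if (dim(tens)[1L] < 2L) {
    warning("single-frame step: orientation labeled 1 by convention")
    return(1L)
  }
  cop <- copSeries(tens, geometry)
  n <- nrow(cop)
  k <- max(1L, round(0.1 * n))
  as.integer(mean(cop$ap[(n - k + 1L):n]) > mean(cop$ap[seq_len(k)]))
}

#' Label foot side (Left/Right)
#'
#' The step is aligned upright (principal-axis rotation and orientation flip),
#' the middle third of the sole length is split into two lateral halves, and
#' activated sensors (union over the stance) are counted in each: the half
#' with the smaller count is the medial (arch) side. Medial on the left of
#' the upright toe-up image means a Right foot; on the right, a Left foot.
#'
#' @param step \linkS4class{Footstep}.
#' @param orientation 0/1 walking direction from
#'   \code{\link{labelOrientation}}.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @return "Left" or "Right" (exact ties give "Right" with a message).
#' @export
labelSide <- function(step, orientation, geometry = buildGeometry()) {
  al <- principalAxisAlign(step, orientation, geometry)
  mask <- active_union(al$tensor, geometry@activationKpa)
  rows <- which(rowSums(mask) > 0)
  r0 <- min(rows); r1 <- max(rows)
  len <- r1 - r0 + 1L
  mid <- mask[(r0 + round(len / 3)):(r0 + round(2 * len / 3)), , drop = FALSE]
  w <- ncol(mid)
  half <- w %/% 2L
  left_count <- sum(mid[, seq_len(half)])
  right_count <- sum(mid[, (w - half + 1L):w])
  if (left_count == right_count)
    message("labelSide: tie in medial pixel counts; labeling Right")
  if (left_count <= right_count) "Right" else "Left"
}

#' Flag incomplete footsteps
#'
#' A footstep is incomplete when it was truncated by the recording window
#' (StartFrame = 0 or EndFrame = last frame of the trial) or fell partially
#' off the grid: steps whose spatial box lies near a grid boundary (within
#' \code{boundaryMarginPx}; erosion at the frame edge sets detected boxes a
#' couple of pixels back from it) are flagged when their total
#' activated-sensor count is more than three scaled MADs (1.4826 x MAD) below
#' the trial's median footstep count. With fewer than 3 steps the MAD rule is
#' skipped (boundary/time rules still apply).
#'
#' @param steps list of \linkS4class{Footstep} from one trial.
#' @param nTrialFrames total frame count of the trial.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @param boundaryMarginPx distance from a grid edge that counts as "near".
#' @return integer 0/1 flags.
#' @export
flagIncomplete <- function(steps, nTrialFrames, geometry = buildGeometry(),
                           boundaryMarginPx = 3L) {
  if (!length(steps)) return(integer(0))
  H <- gridHeight(geometry); W <- gridWidth(geometry)
  m <- boundaryMarginPx
  boxes <- do.call(rbind, lapply(steps, function(s) as.data.frame(t(s@box))))
  flags <- as.integer(boxes$StartFrame == 0L |
                      boxes$EndFrame == nTrialFrames - 1L)
  boundary <- boxes$Ymin <= m | boxes$Ymax >= H - 1L - m |
              boxes$Xmin <= m | boxes$Xmax >= W - 1L - m
  counts <- vapply(steps, function(s)
    sum(active_union(s@tensor, geometry@activationKpa)), numeric(1))
  if (length(steps) >= 3L) {
    med <- stats::median(counts)
    thr <- med - 3 * 1.4826 * stats::median(abs(counts - med))
    flags <- as.integer(flags | (boundary & counts < thr))
  } else {
    message("flagIncomplete: < 3 steps; area rule skipped")
  }
  flags
}

#' Flag standing footsteps (slow-to-stop trials)
#'
#' For each footstep the slope of the anteroposterior COP (px/frame) is
#' estimated by least squares; walking steps progress heel-to-toe (nonzero
#' slope) while standing steps do not. A step is flagged when the absolute
#' slope deviates from the trial median absolute slope by more than three
#' scaled MADs. When the MAD is 0 an absolute tolerance of 0.01 px/frame is
#' used instead (with a message).
#'
#' @param steps list of \linkS4class{Footstep} from one slow-to-stop trial.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @return integer 0/1 flags.
#' @export
flagStanding <- function(steps, geometry = buildGeometry()) {
  if (!length(steps)) return(integer(0))
  slopes <- vapply(steps, function(s) {
    cop <- copSeries(s@tensor, geometry)
    if (nrow(cop) < 2L) return(0)
    abs(stats::cov(cop$frame, cop$ap) / stats::var(cop$frame)) /
      sensorPitch(geometry)          # px per frame
  }, numeric(1))
  med <- stats::median(slopes)
  mad_raw <- stats::median(abs(slopes - med))
  if (mad_raw == 0) {
    message("flagStanding: MAD = 0; using absolute tolerance 0.01 px/frame")
    return(as.integer(abs(slopes - med) > 0.01))
  }
  as.integer(abs(slopes - med) > 3 * 1.4826 * mad_raw)
}
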
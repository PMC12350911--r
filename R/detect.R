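# Footstep detection: per-frame segmentation, SORT-style tracking, extraction.

#' Euclidean disc structuring element
#' @param r radius in pixels; r = 0 gives the 1 x 1 identity element.
#' @return 0/1 matrix of size (2r+1) x (2r+1) with ones where dx^2+dy^2 <= r^2.
#' @export
discKernel <- function(r) {
  off <- seq.int(-r, r)
  outer(off, off, function(a, b) as.numeric(a^2 + b^2 <= r^2))
}

#' Detection parameters
#' @param dilateRadius,erodeRadius radii of the circular structuring elements
#'   applied to the thresholded binary frame (dilation then erosion).
#' @param mergeDistancePx objects whose centroids are within this distance are
#'   combined (transitively); accommodates heel/forefoot splits of high-arch
#'   feet. Increase for soles like stiletto heels.
#' @param minPixels components smaller than this (after morphology) are
#'   discarded as specks.
#' @param connectivity 8 (orthogonal + diagonal neighbours) or 4.
#' @export
detectionParams <- function(dilateRadius = 4L, erodeRadius = 2L,
                            mergeDistancePx = 20, minPixels = 5L,
                            connectivity = 8L) {
  list(dilateRadius = as.integer(dilateRadius),
       erodeRadius = as.integer(erodeRadius),
       mergeDistancePx = mergeDistancePx, minPixels = as.integer(minPixels),
       connectivity = as.integer(connectivity))
}

#' Detect objects (regions of activity) in one pressure frame
#'
#' The frame is thresholded at the geometry's activation pressure (active iff
#' pressure >= threshold), dilated and eroded with circular structuring
#' elements, labeled into connected components, small components discarded,
#' and components whose centroids are within \code{mergeDistancePx} merged
#' transitively (union-find) into single objects.
#'
#' @param frame H x W pressure matrix (kPa).
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @param params \code{\link{detectionParams}}.
#' @param frameIndex 0-based frame index to record.
#' @return list with \code{frame} (index), \code{boxes} (data.frame: ymin,
#'   ymax, xmin, xmax 0-based inclusive, cy, cx centroid, npx active-pixel
#'   count) and \code{masks} (list of linear pixel indices into the frame,
#'   one per object). Empty frame gives zero-row boxes.
#' @export
detectFrameObjects <- function(frame, geometry, params = detectionParams(),
                               frameIndex = 0L) {
  H <- nrow(frame); W <- ncol(frame)
  empty <- list(frame = frameIndex,
                boxes = data.frame(ymin = integer(), ymax = integer(),
                                   xmin = integer(), xmax = integer(),
                                   cy = numeric(), cx = numeric(),
                                   npx = integer()),
                masks = list())
  active <- frame >= geometry@activationKpa
  if (!any(active)) return(empty)
  # crop to the active bounding box (+ dilation margin) before morphology
  m <- params$dilateRadius
  ry <- range(which(rowSums(active) > 0))
  rx <- range(which(colSums(active) > 0))
  ys <- max(1L, ry[1L] - m):min(H, ry[2L] + m)
  xs <- max(1L, rx[1L] - m):min(W, rx[2L] + m)
  sub <- active[ys, xs, drop = FALSE]
  mask <- sub
  if (params$dilateRadius > 0)
    mask <- .binary_morph(mask,
                          matrix(as.integer(discKernel(params$dilateRadius)),
                                 2L * params$dilateRadius + 1L), TRUE)
  if (params$erodeRadius > 0)
    mask <- .binary_morph(mask,
                          matrix(as.integer(discKernel(params$erodeRadius)),
                                 2L * params$erodeRadius + 1L), FALSE)
  lab <- .label_components(mask, params$connectivity)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  sizes <- tabulate(lab[lab > 0L], nlab)
  keep <- which(sizes >= params$minPixels)
  if (!length(keep)) return(empty)
  comp <- lapply(keep, function(k) which(lab == k))
  cent <- t(vapply(comp, function(ix) {
    yy <- (ix - 1L) %% nrow(lab) + 1L
    xx <- (ix - 1L) %/% nrow(lab) + 1L
    c(mean(yy), mean(xx))
  }, numeric(2)))
  # transitive centroid merging via union-find
  n <- length(comp)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    dmat <- as.matrix(stats::dist(cent))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (dmat[i, j] <= params$mergeDistancePx) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  boxes <- list(); masks <- list()
  for (g in groups) {
    ix <- unlist(comp[g], use.names = FALSE)
    yy <- (ix - 1L) %% nrow(lab) + 1L
    xx <- (ix - 1L) %/% nrow(lab) + 1L
    gy <- ys[yy]; gx <- xs[xx]               # back to full-frame coords
    masks[[length(masks) + 1L]] <- (gx - 1L) * H + gy   # linear index in frame
    boxes[[length(boxes) + 1L]] <- data.frame(
      ymin = min(gy) - 1L, ymax = max(gy) - 1L,
      xmin = min(gx) - 1L, xmax = max(gx) - 1L,
      cy = mean(gy) - 1, cx = mean(gx) - 1, npx = length(ix))
  }
  list(frame = frameIndex, boxes = do.call(rbind, boxes), masks = masks)
}

#' Detect objects in every frame of a trial
#' @param trial \linkS4class{RawTrial}.
#' @param params \code{\link{detectionParams}}.
#' @param chunk frames per read for file-backed trials.
#' @return list of per-frame detection results (see
#'   \code{\link{detectFrameObjects}}), one per frame, in temporal order.
#' @export
detectTrialObjects <- function(trial, params = detectionParams(),
                               chunk = 500L) {
  n <- nFrames(trial)
  geometry <- trialGeometry(trial)
  out <- vector("list", n)
  for (lo in seq.int(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    block <- trialFrames(trial, lo:hi)
    for (i in lo:hi)
      out[[i]] <- detectFrameObjects(block[i - lo + 1L, , ], geometry, params,
                                     frameIndex = i - 1L)
  }
  out
}

# intersection-over-union of 0-based inclusive boxes (vectors ymin,ymax,xmin,xmax)
box_iou <- function(a, b) {
  iy <- min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1
  ix <- min(a[4L], b[4L]) - max(a[3L], b[3L]) + 1
  if (iy <= 0 || ix <= 0) return(0)
  inter <- iy * ix
  area <- function(z) (z[2L] - z[1L] + 1) * (z[4L] - z[3L] + 1)
  inter / (area(a) + area(b) - inter)
}

#' Tracker parameters (SORT defaults)
#' @param iouThreshold minimum IoU to associate a detection with a track.
#' @param maxAge frames a track survives without a matched detection.
#' @param minHits minimum matched detections for a track to be reported.
#' @export
trackerParams <- function(iouThreshold = 0.3, maxAge = 3L, minHits = 3L) {
  list(iouThreshold = iouThreshold, maxAge = as.integer(maxAge),
       minHits = as.integer(minHits))
}

# --- constant-velocity Kalman filter over (cy, cx, area, aspect) ------------

kf_new <- function(z) {
  x <- c(z, 0, 0, 0)                      # state: cy cx s r vcy vcx vs
  P <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
  list(x = x, P = P)
}

kf_F <- rbind(cbind(diag(4), rbind(diag(3), 0)), cbind(matrix(0, 3, 4), diag(3)))
kf_H <- cbind(diag(4), matrix(0, 4, 3))
kf_Q <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4))
kf_R <- diag(c(1, 1, 10, 10))

kf_predict <- function(kf) {
  kf$x <- as.vector(kf_F %*% kf$x)
  if (kf$x[3L] <= 0) kf$x[3L] <- 1e-6
  kf$P <- kf_F %*% kf$P %*% t(kf_F) + kf_Q
  kf
}

kf_update <- function(kf, z) {
  yv <- z - as.vector(kf_H %*% kf$x)
  S <- kf_H %*% kf$P %*% t(kf_H) + kf_R
  K <- kf$P %*% t(kf_H) %*% solve(S)
  kf$x <- as.vector(kf$x + K %*% yv)
  kf$P <- (diag(7) - K %*% kf_H) %*% kf$P
  kf
}

box_to_z <- function(b) {
  h <- b$ymax - b$ymin + 1; w <- b$xmax - b$xmin + 1
  c(b$cy, b$cx, h * w, w / h)
}

z_to_box <- function(x) {
  s <- max(x[3L], 1); r <- max(x[4L], 1e-3)
  w <- sqrt(s * r); h <- s / w
  c(x[1L] - h / 2, x[1L] + h / 2, x[2L] - w / 2, x[2L] + w / 2)
}

#' Track detected objects across frames (SORT)
#'
#' Constant-velocity Kalman tracking of per-frame objects: each live track's
#' box is predicted one frame ahead, detections are associated greedily by
#' intersection-over-union against the predictions, unmatched detections
#' spawn tracks, and tracks unmatched for more than \code{maxAge} frames are
#' terminated. Each finished track with at least \code{minHits} detections is
#' one candidate footstep.
#'
#' @param frameObjects list from \code{\link{detectTrialObjects}} (temporal
#'   order).
#' @param params \code{\link{trackerParams}}.
#' @return list of tracks; each track is a list with \code{id},
#'   \code{frames} (0-based frame indices with a matched detection),
#'   \code{boxes} (data.frame, one row per matched frame), \code{masks}
#'   (list of linear pixel index vectors per matched frame).
#' @export
trackFootsteps <- function(frameObjects, params = trackerParams()) {
  live <- list()
  done <- list()
  next_id <- 1L
  for (fo in frameObjects) {
    nt <- length(live)
    nd <- if (is.null(fo$boxes)) 0L else nrow(fo$boxes)
    # predict
    pred <- vector("list", nt)
    for (i in seq_len(nt)) {
      live[[i]]$kf <- kf_predict(live[[i]]$kf)
      pred[[i]] <- z_to_box(live[[i]]$kf$x)
    }
    matched_t <- rep(FALSE, nt); matched_d <- rep(FALSE, nd)
    if (nt > 0L && nd > 0L) {
      iou <- matrix(0, nt, nd)
      for (i in seq_len(nt)) for (j in seq_len(nd)) {
        b <- fo$boxes[j, ]
        iou[i, j] <- box_iou(pred[[i]],
                             c(b$ymin, b$ymax, b$xmin, b$xmax))
      }
      repeat {
        best <- which.max(iou)
        if (iou[best] < params$iouThreshold) break
        i <- (best - 1L) %% nt + 1L
        j <- (best - 1L) %/% nt + 1L
        matched_t[i] <- TRUE; matched_d[j] <- TRUE
        iou[i, ] <- -1; iou[, j] <- -1
        b <- fo$boxes[j, ]
        live[[i]]$kf <- kf_update(live[[i]]$kf, box_to_z(b))
        live[[i]]$frames <- c(live[[i]]$frames, fo$frame)
        live[[i]]$boxes[[length(live[[i]]$boxes) + 1L]] <- b
        live[[i]]$masks[[length(live[[i]]$masks) + 1L]] <- fo$masks[[j]]
        live[[i]]$age <- 0L
        if (all(matched_d) || all(matched_t)) break
      }
    }
    # unmatched detections spawn tracks
    for (j in which(!matched_d)) {
      b <- fo$boxes[j, ]
      live[[length(live) + 1L]] <- list(
        id = next_id, kf = kf_new(box_to_z(b)), frames = fo$frame,
        boxes = list(b), masks = list(fo$masks[[j]]), age = 0L)
      next_id <- next_id + 1L
    }
    # age unmatched tracks, retire the stale
    keep <- logical(length(live))
    for (i in seq_along(live)) {
      if (i <= nt && !matched_t[i]) live[[i]]$age <- live[[i]]$age + 1L
      keep[i] <- live[[i]]$age <= params$maxAge
    }
    done <- c(done, live[!keep])
    live <- live[keep]
  }
  done <- c(done, live)
  done <- Filter(function(tr) length(tr$frames) >= params$minHits, done)
  done <- lapply(done, function(tr) {
    tr$boxes <- do.call(rbind, tr$boxes)
    tr$kf <- NULL; tr$age <- NULL
    tr
  })
  done[order(vapply(done, function(tr) tr$frames[1L], numeric(1)))]
}

#' Extract footstep tensors from tracks
#'
#' For each track, StartFrame/EndFrame are the first/last frames with a
#' matched detection, the spatial box is the union of the member frame boxes,
#' and the tensor is cropped from the raw frames with pixels outside the
#' track's per-frame masks zeroed (frames inside the span without a matched
#' detection use the union of the track's masks).
#'
#' @param trial \linkS4class{RawTrial} the tracks came from.
#' @param tracks result of \code{\link{trackFootsteps}}.
#' @return list of \linkS4class{Footstep}; degenerate tracks (no active pixel)
#'   are dropped with a message.
#' @export
extractFootsteps <- function(trial, tracks) {
  H <- gridHeight(trialGeometry(trial))
  out <- list()
  for (tr in tracks) {
    sf <- min(tr$frames); ef <- max(tr$frames)
    ymin <- min(tr$boxes$ymin); ymax <- max(tr$boxes$ymax)
    xmin <- min(tr$boxes$xmin); xmax <- max(tr$boxes$xmax)
    span <- sf:ef
    raw <- trialFrames(trial, span + 1L)
    tens <- array(0, dim = c(length(span), ymax - ymin + 1L, xmax - xmin + 1L))
    union_mask <- unique(unlist(tr$masks, use.names = FALSE))
    for (k in seq_along(span)) {
      fidx <- match(span[k], tr$frames)
      ix <- if (is.na(fidx)) union_mask else tr$masks[[fidx]]
      yy <- (ix - 1L) %% H + 1L
      xx <- (ix - 1L) %/% H + 1L
      fr <- raw[k, , ]
      sl <- tens[k, , ]
      sl[cbind(yy - ymin, xx - xmin)] <- fr[cbind(yy, xx)]
      tens[k, , ] <- sl
    }
    if (all(tens < trialGeometry(trial)@activationKpa)) {
      message("dropping degenerate track ", tr$id, " (no active pixels)")
      next
    }
    out[[length(out) + 1L]] <- new("Footstep", tensor = tens,
      box = c(StartFrame = as.integer(sf), EndFrame = as.integer(ef),
              Ymin = as.integer(ymin), Ymax = as.integer(ymax),
              Xmin = as.integer(xmin), Xmax = as.integer(xmax)),
      trackId = as.integer(tr$id))
  }
  out
}

#' Assign pass identifiers to footsteps
#'
#' PassID starts at 0 and increments when no footstep is in contact for at
#' least \code{gapFrames} between consecutive steps, or when Orientation
#' changes between consecutive steps.
#'
#' @param steps data.frame with StartFrame, EndFrame and Orientation, sorted
#'   by StartFrame.
#' @param gapFrames minimum contact-free gap that separates passes.
#' @return integer vector of pass ids.
#' @export
assignPasses <- function(steps, gapFrames = 100L) {
  n <- nrow(steps)
  if (n == 0L) return(integer(0))
  pass <- integer(n)
  run_end <- steps$EndFrame[1L]
  for (i in seq_len(n)[-1L]) {
    gap <- steps$StartFrame[i] - run_end
    turn <- gap >= gapFrames ||
      steps$Orientation[i] != steps$Orientation[i - 1L]
    pass[i] <- pass[i - 1L] + as.integer(turn)
    run_end <- max(run_end, steps$EndFrame[i])
  }
  pass
}
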
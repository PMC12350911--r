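# Parametric walkway simulator. Every pipeline stage is validated against the
# ground truth this module emits, so its conventions are documented carefully:
#
# * Canonical foot template: toe at row 1 ("toe up"), heel at high rows. For a
#   Right foot the medial side (arch) is at low columns; Left is the exact
#   column mirror of Right.
# * Rotation angles are measured from the +y grid axis toward +x, in degrees,
#   range (-90, 90]. When walking toward +y (Orientation 1) the walker's left
#   side is at larger x; toe-out (external rotation) therefore corresponds to
#   a grid angle of -toeOut for Right feet and +toeOut for Left feet, for
#   either walking direction.

#' Foot shape parameters
#'
#' The synthetic foot is a union of a toe ellipse, a metatarsal (forefoot)
#' band, a lateral midfoot strip and a heel ellipse. \code{archDepth} in
#' [0, 1] controls medial midfoot suppression: 0 gives a flat foot whose
#' midfoot spans the full width, 1 leaves only a narrow lateral strip (a high
#' arch). Pressures are plateau values per region scaled by \code{peakKpa}.
#'
#' @param soleLengthCm,soleWidthCm contact dimensions in cm.
#' @param side "Left" or "Right".
#' @param archDepth medial midfoot suppression fraction in [0, 1].
#' @param peakKpa peak plateau pressure in kPa.
#' @param weighting "rollout" (heel-dominant early, forefoot-dominant late)
#'   or "constant" (every stance frame identical).
#' @return list of class "FootParams".
#' @export
footParams <- function(soleLengthCm = 26, soleWidthCm = 9.5, side = "Right",
                       archDepth = 0.7, peakKpa = 400,
                       weighting = c("rollout", "constant")) {
  side <- match.arg(side, c("Left", "Right"))
  weighting <- match.arg(weighting)
  stopifnot(soleLengthCm > 0, soleWidthCm > 0, archDepth >= 0, archDepth <= 1,
            peakKpa > 0)
  structure(list(soleLengthCm = soleLengthCm, soleWidthCm = soleWidthCm,
                 side = side, archDepth = archDepth, peakKpa = peakKpa,
                 weighting = weighting), class = "FootParams")
}

#' Gait parameters
#'
#' Kinematics are required to be internally consistent:
#' speed = stepLengthCm * cadence / 60 / 100 within 10%. If \code{cadence} is
#' NULL it is derived from speed and step length. Task presets (defaults used
#' by the walking simulator): W1 preferred 1.12 m/s, W2 = W1 with a ~1 s
#' two-foot stop at each pass end, W3 slow 0.83 m/s, W4 fast 1.45 m/s.
#'
#' @param speed gait speed in m/s.
#' @param stepLengthCm,stepWidthCm step length / width in cm.
#' @param cadence steps/min (derived when NULL).
#' @param toeOutDeg external foot rotation per side, degrees.
#' @param stanceS stance duration in s (default 1.2 x step interval).
#' @param task walking task code.
#' @return list of class "GaitParams".
#' @export
gaitParams <- function(speed = 1.12, stepLengthCm = 60, stepWidthCm = 12,
                       cadence = NULL, toeOutDeg = 7, stanceS = NULL,
                       task = c("W1", "W2", "W3", "W4")) {
  task <- match.arg(task)
  if (is.null(cadence)) cadence <- speed * 100 / stepLengthCm * 60
  implied <- stepLengthCm * cadence / 60 / 100
  if (abs(implied - speed) > 0.1 * speed)
    stop("inconsistent kinematics: speed ", speed, " m/s vs step_length*cadence = ",
         round(implied, 3), " m/s")
  if (is.null(stanceS)) stanceS <- 1.2 * 60 / cadence
  structure(list(speed = speed, stepLengthCm = stepLengthCm,
                 stepWidthCm = stepWidthCm, cadence = cadence,
                 toeOutDeg = toeOutDeg, stanceS = stanceS, task = task),
            class = "GaitParams")
}

#' Task preset gait parameters
#' @param task one of W1..W4.
#' @return a \code{\link{gaitParams}} list.
#' @export
taskGait <- function(task = c("W1", "W2", "W3", "W4")) {
  task <- match.arg(task)
  switch(task,
    W1 = gaitParams(1.12, 60, 12, task = "W1"),
    W2 = gaitParams(1.12, 60, 12, task = "W2"),
    W3 = gaitParams(0.83, 54, 13, task = "W3"),
    W4 = gaitParams(1.45, 66, 11, task = "W4"))
}

# Region masks of the canonical upright foot, L x W pixels, Right side.
foot_region_masks <- function(L, W, archDepth) {
  ell <- function(cy, cx, ry, rx) {
    outer(seq_len(L), seq_len(W),
          function(y, x) ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1)
  }
  toe <- ell(0.10 * L, 0.50 * W, 0.11 * L, 0.36 * W)
  fore <- ell(0.30 * L, 0.50 * W, 0.17 * L, 0.50 * W)
  heel <- ell(0.86 * L, 0.50 * W, 0.15 * L, 0.42 * W)
  mid <- matrix(FALSE, L, W)
  rows <- seq.int(max(1L, round(0.40 * L)), min(L, round(0.78 * L)))
  stripw <- max(2L, round(W * (1 - 0.7 * archDepth)))
  cols <- seq.int(W - stripw + 1L, W)  # lateral strip (high cols for Right)
  mid[rows, cols] <- TRUE
  list(toe = toe, fore = fore, mid = mid, heel = heel)
}

# Stance-phase weighting for the two pressure groups (heel+midfoot vs
# forefoot+toe); phi in [0,1]. An onset/offset ramp keeps first/last frames
# active while making early frames heel-dominant and late frames toe-dominant.
rollout_weights <- function(phi) {
  ramp <- pmin(1, phi / 0.12 + 0.3, (1 - phi) / 0.12 + 0.3)
  heel <- pmin(1, pmax(0, (0.72 - phi) / 0.22))
  heel <- pmax(heel, ifelse(phi < 0.5, 0.35, 0))
  fore <- pmin(1, pmax(0.12, (phi - 0.05) / 0.3))
  list(heel = heel * ramp, fore = fore * ramp)
}

#' Build a stance-resolved foot pressure template
#'
#' Returns a T x L x W pressure stack (kPa, unquantized) of one stance in
#' canonical upright pose (toe at row 1). With the default "rollout"
#' weighting, early frames are heel-dominant and late frames
#' forefoot/toe-dominant; "constant" weighting makes every frame the identical
#' union mask. A Left template is the exact column mirror of the Right
#' template with the same parameters.
#'
#' @param fp \code{\link{footParams}}.
#' @param geometry \linkS4class{WalkwayGeometry} (fixes the pixel pitch).
#' @param stanceFrames number of stance frames T.
#' @return numeric array T x L x W.
#' @export
makeFootTemplate <- function(fp, geometry, stanceFrames = 60L) {
  pitch <- sensorPitch(geometry)
  L <- round(fp$soleLengthCm / pitch)
  W <- round(fp$soleWidthCm / pitch)
  if (L > gridHeight(geometry) || W > gridWidth(geometry))
    stop("invalid params: foot larger than the sensing grid")
  m <- foot_region_masks(L, W, fp$archDepth)
  base_heel <- 1.0 * m$heel + 0.35 * m$mid * !m$heel
  base_fore <- pmax(0.9 * m$fore, 0.7 * m$toe)
  out <- array(0, dim = c(stanceFrames, L, W))
  for (t in seq_len(stanceFrames)) {
    phi <- if (stanceFrames == 1L) 0.5 else (t - 1) / (stanceFrames - 1)
    w <- if (fp$weighting == "constant") list(heel = 1, fore = 1)
         else rollout_weights(phi)
    out[t, , ] <- fp$peakKpa * pmax(base_heel * w$heel, base_fore * w$fore)
  }
  if (fp$side == "Left") out <- out[, , W:1, drop = FALSE]
  out
}

quantize_pressure <- function(x, geometry) {
  # sequential steps keep at most one whole-array temporary alive
  q <- geometry@pressureResKpa
  x <- round(x / q)
  x <- x * q
  x <- pmin(x, geometry@pressureMaxKpa)
  x
}

# Rotate each frame of a T x h x w stack by theta degrees (from +y toward +x)
# about the stack center, using nearest-neighbour inverse mapping onto an
# output canvas large enough to contain the rotated content.
rotate_stack_nn <- function(stack, theta_deg, out_dims = NULL) {
  d <- dim(stack)
  h <- d[2L]; w <- d[3L]
  th <- theta_deg * pi / 180
  if (is.null(out_dims)) {
    oh <- ceiling(abs(h * cos(th)) + abs(w * sin(th))) + 2L
    ow <- ceiling(abs(h * sin(th)) + abs(w * cos(th))) + 2L
  } else { oh <- out_dims[1L]; ow <- out_dims[2L] }
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ocy <- (oh + 1) / 2; ocx <- (ow + 1) / 2
  gy <- rep(seq_len(oh), times = ow) - ocy
  gx <- rep(seq_len(ow), each = oh) - ocx
  # inverse rotation of output coords into input coords
  sy <- round(cos(th) * gy + sin(th) * gx + cy)
  sx <- round(-sin(th) * gy + cos(th) * gx + cx)
  ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  idx <- ifelse(ok, (sx - 1L) * h + sy, NA_integer_)
  out <- array(0, dim = c(d[1L], oh, ow))
  for (t in seq_len(d[1L])) {
    fr <- stack[t, , ]
    of <- numeric(oh * ow)
    of[ok] <- fr[idx[ok]]
    out[t, , ] <- of
  }
  out
}

# rotate 180 degrees (reverse both axes) - NOT a mirror
rot180_stack <- function(stack) {
  d <- dim(stack)
  stack[, d[2L]:1, d[3L]:1, drop = FALSE]
}

# Nearest-neighbour index rescale of a stance stack in time and space
# (used for stride-to-stride variability of cached rotated templates).
nn_rescale_stack <- function(stack, st = 1, ss = 1) {
  d <- dim(stack)
  nt <- max(2L, round(d[1L] * st))
  oh <- max(1L, round(d[2L] * ss))
  ow <- max(1L, round(d[3L] * ss))
  ti <- pmin(d[1L], pmax(1L, ceiling((seq_len(nt) - 0.5) * d[1L] / nt)))
  ri <- pmin(d[2L], pmax(1L, ceiling((seq_len(oh) - 0.5) * d[2L] / oh)))
  ci <- pmin(d[3L], pmax(1L, ceiling((seq_len(ow) - 0.5) * d[3L] / ow)))
  stack[ti, ri, ci, drop = FALSE]
}

# Boundary ring of a binary mask (pixels with a 4-neighbour outside the mask).
mask_edge_ring <- function(m) {
  er <- m
  er[-1, ] <- er[-1, ] & m[-nrow(m), ]
  er[-nrow(m), ] <- er[-nrow(m), ] & m[-1, ]
  er[, -1] <- er[, -1] & m[, -ncol(m)]
  er[, -ncol(m)] <- er[, -ncol(m)] & m[, -1]
  m & !er
}

# Per-footfall contact variability: each pixel on the contact boundary fails
# to register with probability p (partial edge contact), applied across the
# whole stance.
drop_edge_pixels <- function(stack, p, rng) {
  if (p <= 0) return(stack)
  d <- dim(stack)
  m <- apply(stack > 0, c(2L, 3L), any)
  ring <- which(mask_edge_ring(m))
  if (!length(ring)) return(stack)
  drop <- ring[rng$runif(length(ring)) < p]
  if (!length(drop)) return(stack)
  yy <- (drop - 1L) %% d[2L] + 1L
  xx <- (drop - 1L) %/% d[2L] + 1L
  pos <- as.vector(outer(seq_len(d[1L]),
                         (yy - 1L) * d[1L] + (xx - 1L) * d[1L] * d[2L], `+`))
  stack[pos] <- 0
  stack
}

# Compute the placement of one footfall: truth row plus the pixel block the
# caller must blend (with pmax) into the trial array. Returns NULL when no
# rendered pixel reaches the activation threshold, or when the mask would be
# cropped by the grid edge and allowPartial is FALSE.
place_footfall <- function(nfr, stack, start_frame, cy, cx, geometry,
                           allowPartial = TRUE) {
  d <- dim(stack)
  H <- gridHeight(geometry); W <- gridWidth(geometry)
  y0 <- round(cy - (d[2L] + 1) / 2)          # 0-based offset of row 1
  x0 <- round(cx - (d[3L] + 1) / 2)
  ys <- seq_len(d[2L]) + y0                  # 1-based grid rows
  xs <- seq_len(d[3L]) + x0
  gy <- which(ys >= 1 & ys <= H)
  gx <- which(xs >= 1 & xs <= W)
  if (!length(gy) || !length(gx)) return(NULL)
  off_grid <- length(gy) < d[2L] || length(gx) < d[3L]
  if (off_grid && !allowPartial) return(NULL)
  q <- quantize_pressure(stack[, gy, gx, drop = FALSE], geometry)
  act <- q >= geometry@activationKpa
  tact <- apply(act, 1L, any)
  gl <- start_frame + seq_len(d[1L]) - 1L    # 1-based global frames
  inrec <- gl >= 1 & gl <= nfr
  keep <- which(tact & inrec)
  if (!length(keep)) return(NULL)
  umask <- apply(act[keep, , , drop = FALSE], c(2L, 3L), any)
  ry <- range(which(rowSums(umask) > 0)); rx <- range(which(colSums(umask) > 0))
  truncated <- any(tact & !inrec)
  list(truth = list(
         StartFrame = gl[keep[1L]] - 1L, EndFrame = gl[keep[length(keep)]] - 1L,
         Ymin = ys[gy][ry[1L]] - 1L, Ymax = ys[gy][ry[2L]] - 1L,
         Xmin = xs[gx][rx[1L]] - 1L, Xmax = xs[gx][rx[2L]] - 1L,
         Incomplete = as.integer(off_grid || truncated),
         CenterY = cy - 1, CenterX = cx - 1),
       render = list(frames = gl[keep], ys = ys[gy], xs = xs[gx],
                     vals = {v <- q[keep, , , drop = FALSE]
                             storage.mode(v) <- "integer"; v}))
}

#' Simulate a walking trial with ground truth
#'
#' Generates alternating left/right footfalls along +y then -y passes with
#' off-grid turn gaps, optional natural variability (timing/position/pressure
#' jitter), W2 two-foot standing stops at pass ends, incomplete boundary and
#' recording-edge steps, and hardware quantization. Deterministic given
#' \code{seed}.
#'
#' @param gait \code{\link{gaitParams}}.
#' @param feet list with elements \code{Left} and \code{Right}
#'   (\code{\link{footParams}}); a single FootParams is mirrored.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @param durationS recording duration in seconds.
#' @param seed integer seed.
#' @param noise optional \code{\link{noiseSpec}} applied after rendering.
#' @param jitter list of natural-variability magnitudes (each clamped at two
#'   standard deviations): \code{timingSdFrames} (footfall timing),
#'   \code{posSdPx} (placement), \code{pressureSd} (fractional amplitude),
#'   \code{scaleSd} (fractional contact-size), \code{stanceSdFrames} (stance
#'   duration), \code{edgeDropP} (probability that a contact-boundary sensor
#'   fails to register during a footfall). Set all to 0 for an exactly
#'   periodic, perfectly repeatable gait.
#' @param startOffsetPx y position (px, 1-based) of the first footfall center
#'   of each pass, measured from the entry edge. The default places all steps
#'   of the default geometry fully inside the grid; small values make the
#'   first/last footfalls straddle the boundary.
#' @param turnS off-grid turning time between passes, seconds.
#' @return list with elements \code{trial} (\linkS4class{RawTrial}) and
#'   \code{truth} (data.frame, one row per emitted footstep: box, Side,
#'   Orientation, Standing, Incomplete, RotationAngle, ToeOut, pass id,
#'   artifact flag).
#' @export
simulateWalkingTrial <- function(gait = taskGait("W1"),
                                 feet = footParams(),
                                 geometry = buildGeometry(),
                                 durationS = 10, seed = 1, noise = NULL,
                                 jitter = list(timingSdFrames = 1,
                                               posSdPx = 1.5,
                                               pressureSd = 0.04,
                                               scaleSd = 0,
                                               stanceSdFrames = 2,
                                               edgeDropP = 0.3),
                                 startOffsetPx = NULL, turnS = 2) {
  if (durationS <= 0) stop("duration must be > 0")
  if (inherits(feet, "FootParams")) {
    right <- feet; right$side <- "Right"
    left <- feet; left$side <- "Left"
    feet <- list(Left = left, Right = right)
  }
  rng <- local_rng(seed)
  rate <- sampleRate(geometry)
  H <- gridHeight(geometry); W <- gridWidth(geometry)
  pitch <- sensorPitch(geometry)
  nfr <- round(durationS * rate)
  interval_fr <- 60 / gait$cadence * rate
  stance_fr <- max(2L, round(gait$stanceS * rate))
  step_len <- gait$stepLengthCm / pitch
  step_w <- gait$stepWidthCm / pitch
  for (nm in c("timingSdFrames", "posSdPx", "pressureSd", "scaleSd",
               "stanceSdFrames", "edgeDropP"))
    if (is.null(jitter[[nm]])) jitter[[nm]] <- 0
  auto_layout <- is.null(startOffsetPx)
  if (is.null(startOffsetPx)) {
    # place footfall centers so every step of either pass direction lands
    # fully inside the grid (with rotation + jitter margin); explicit offsets
    # can be passed to create boundary-straddling steps
    lpx <- max(feet$Left$soleLengthCm, feet$Right$soleLengthCm) / pitch
    wpx <- max(feet$Left$soleWidthCm, feet$Right$soleWidthCm) / pitch
    th <- abs(gait$toeOutDeg) * pi / 180
    half_f <- ceiling((lpx * cos(th) + wpx * sin(th)) / 2) + 8L
    nsteps <- floor((H + 1 - 2 * half_f) / step_len) + 1
    if (nsteps < 1) stop("invalid params: foot/stride too large for the grid")
    startOffsetPx <- round((H + 1 - (nsteps - 1) * step_len) / 2)
  }

  # pre-rotate one template stack per (side, orientation); grid angle is
  # -toeOut for Right, +toeOut for Left (see header comment)
  tmpl <- list()
  # grid-frame principal-axis angle of each placed foot: the applied rotation
  # plus the template's intrinsic principal-axis offset (the arch asymmetry
  # tilts the PC axis away from the nominal sole axis); this is what the
  # alignment stage measures, so it is what truth reports
  pc_truth <- list()
  wrap90 <- function(a) { a <- (a + 90) %% 180 - 90; if (a == -90) 90 else a }
  for (side in c("Left", "Right")) {
    alpha <- if (side == "Right") -gait$toeOutDeg else gait$toeOutDeg
    base <- makeFootTemplate(feet[[side]], geometry, stance_fr)
    um <- apply(quantize_pressure(base, geometry) >= geometry@activationKpa,
                c(2L, 3L), any)
    delta <- pc_angle_mask(um)
    if (is.null(delta)) delta <- 0
    pc_truth[[side]] <- wrap90(alpha + delta)
    stand_fp <- feet[[side]]; stand_fp$weighting <- "constant"
    stand_fr <- max(2L, round((gait$stanceS + 1.0) * rate))
    stand <- makeFootTemplate(stand_fp, geometry, stand_fr)
    for (o in c(0, 1)) {
      s <- if (o == 1) rot180_stack(base) else base
      st <- if (o == 1) rot180_stack(stand) else stand
      tmpl[[paste(side, o)]] <- rotate_stack_nn(s, alpha)
      tmpl[[paste("stand", side, o)]] <- rotate_stack_nn(st, alpha)
    }
  }

  frames <- array(0L, dim = c(nfr, H, W))   # already-quantized kPa integers
  pending <- list()                # render blocks, blended at the end
  truth <- list()
  cx_mid <- (W + 1) / 2
  frame_cursor <- 1 + round(0.3 * rate)   # brief silence before first contact
  pass <- 0L
  orientation <- 1L
  side <- if (rng$runif(1) < 0.5) "Left" else "Right"
  jt <- function(sd) if (sd > 0)
    round(max(-2 * sd, min(2 * sd, rng$rnorm(1, 0, sd)))) else 0

  while (frame_cursor <= nfr) {
    dir <- if (orientation == 1L) 1 else -1
    y <- if (orientation == 1L) startOffsetPx else H + 1 - startOffsetPx
    k <- 0L
    pass_rows <- list()
    while (y > -step_len && y < H + step_len) {
      if (gait$task == "W2" &&
          ((dir > 0 && y > H - step_len) || (dir < 0 && y < step_len)))
        break   # leave room on the grid for the two-foot stop
      on_walk_side <- (orientation == 1L) == (side == "Right")  # TRUE: low x
      cx <- cx_mid + (if (on_walk_side) -1 else 1) * step_w / 2 + jt(jitter$posSdPx)
      cy <- y + jt(jitter$posSdPx)
      start <- round(frame_cursor + k * interval_fr) + jt(jitter$timingSdFrames)
      stack <- tmpl[[paste(side, orientation)]]
      jc <- function(sd) if (sd > 0)
        max(-2 * sd, min(2 * sd, rng$rnorm(1, 0, sd))) else 0
      scale <- 1 + jc(jitter$pressureSd)
      if (jitter$scaleSd > 0 || jitter$stanceSdFrames > 0) {
        st <- (stance_fr + round(jc(jitter$stanceSdFrames))) / stance_fr
        stack <- nn_rescale_stack(stack, st = st, ss = 1 + jc(jitter$scaleSd))
      }
      stack <- drop_edge_pixels(stack, jitter$edgeDropP, rng)
      pf <- place_footfall(nfr, stack * scale, start, cy, cx, geometry,
                           allowPartial = !auto_layout)
      if (!is.null(pf)) {
        pending[[length(pending) + 1L]] <- pf$render
        row <- pf$truth
        row$Side <- side; row$Orientation <- orientation
        row$Standing <- 0L; row$PassID <- pass
        row$RotationAngle <- pc_truth[[side]]
        row$ToeOut <- (if (side == "Right") -1 else 1) * pc_truth[[side]]
        pass_rows[[length(pass_rows) + 1L]] <- row
      }
      if (start > nfr) break
      side <- if (side == "Left") "Right" else "Left"
      k <- k + 1L
      y <- y + dir * step_len
    }
    last_start <- frame_cursor + (k - 1L) * interval_fr
    if (gait$task == "W2" && length(pass_rows) >= 1L) {
      # two-foot stop one step beyond the last walking footfall, held ~1 s
      ys <- min(max(y, step_len / 2), H - step_len / 2)
      start <- round(last_start + interval_fr)
      sep <- max(step_w, 20 / pitch)  # feet at least 20 cm apart when standing
      for (s2 in c(side, if (side == "Left") "Right" else "Left")) {
        on_walk_side <- (orientation == 1L) == (s2 == "Right")
        cx <- cx_mid + (if (on_walk_side) -1 else 1) * sep / 2 + jt(jitter$posSdPx)
        stack <- tmpl[[paste("stand", s2, orientation)]]
        pf <- place_footfall(nfr, stack, start + jt(jitter$timingSdFrames),
                             ys + jt(jitter$posSdPx), cx, geometry)
        if (!is.null(pf)) {
          pending[[length(pending) + 1L]] <- pf$render
          row <- pf$truth
          row$Side <- s2; row$Orientation <- orientation
          row$Standing <- 1L; row$PassID <- pass
          row$RotationAngle <- pc_truth[[s2]]
          row$ToeOut <- (if (s2 == "Right") -1 else 1) * pc_truth[[s2]]
          pass_rows[[length(pass_rows) + 1L]] <- row
        }
        start <- start + round(0.3 * rate)   # second foot lands shortly after
      }
      last_start <- start + rate             # hold before turning
      side <- if (rng$runif(1) < 0.5) "Left" else "Right"
    }
    truth <- c(truth, pass_rows)
    frame_cursor <- round(last_start + interval_fr + turnS * rate)
    orientation <- 1L - orientation
    pass <- pass + 1L
  }

  for (r in pending)
    for (t in seq_along(r$frames)) {
      g <- r$frames[t]
      frames[g, r$ys, r$xs] <- pmax(frames[g, r$ys, r$xs], r$vals[t, , ])
    }
  trial <- rawTrial(frames, geometry, task = gait$task)
  truth_df <- do.call(rbind, lapply(truth, as.data.frame))
  if (is.null(truth_df)) truth_df <- data.frame()
  else {
    truth_df <- truth_df[order(truth_df$StartFrame), , drop = FALSE]
    rownames(truth_df) <- NULL
    truth_df$FootstepID <- seq_len(nrow(truth_df)) - 1L
    truth_df$Artifact <- 0L
  }
  out <- list(trial = trial, truth = truth_df)
  if (!is.null(noise)) out <- injectArtifacts(out, noise, seed = seed + 1L)
  out
}

#' Simulate a standing balance trial
#'
#' Static feet with small seeded center-of-pressure sway (a slow sinusoidal
#' heel/forefoot weight shift); \code{swayAmplitude = 0} yields frames that
#' are constant over time. The frame count is durationS x rate plus
#' \code{extraFrames} (recordings "may differ slightly" in length).
#'
#' @param feet,geometry,seed as in \code{\link{simulateWalkingTrial}}.
#' @param durationS recording duration, seconds.
#' @param stance "both", "left" or "right".
#' @param swayAmplitude fractional weight-shift amplitude.
#' @param extraFrames extra frames beyond the nominal count.
#' @return list(trial, truth) as in \code{\link{simulateWalkingTrial}}.
#' @export
simulateBalanceTrial <- function(feet = footParams(),
                                 geometry = buildGeometry(), durationS = 30,
                                 stance = c("both", "left", "right"),
                                 seed = 1, swayAmplitude = 0.05,
                                 extraFrames = 0L) {
  stance <- match.arg(stance)
  if (inherits(feet, "FootParams")) {
    right <- feet; right$side <- "Right"
    left <- feet; left$side <- "Left"
    feet <- list(Left = left, Right = right)
  }
  rng <- local_rng(seed)
  rate <- sampleRate(geometry)
  H <- gridHeight(geometry); W <- gridWidth(geometry)
  pitch <- sensorPitch(geometry)
  nfr <- round(durationS * rate) + extraFrames
  sides <- switch(stance, both = c("Left", "Right"), left = "Left",
                  right = "Right")
  cy <- round(H * rng$runif(1, 0.35, 0.65))
  sep <- 16 / pitch
  frames <- array(0L, dim = c(nfr, H, W))
  pending <- list()
  truth <- list()
  phase <- rng$runif(1, 0, 2 * pi)
  for (s in sides) {
    fp <- feet[[s]]; fp$weighting <- "constant"
    one <- makeFootTemplate(fp, geometry, 1L)[1L, , ]
    d <- dim(one)
    m <- foot_region_masks(d[1L], d[2L], feet[[s]]$archDepth)
    heelish <- m$heel | m$mid
    if (s == "Left") heelish <- heelish[, d[2L]:1]
    cx <- (W + 1) / 2 + (if (s == "Left") 1 else -1) * (sep / 2) * (stance == "both")
    tt <- seq_len(nfr) / rate
    wshift <- swayAmplitude * sin(2 * pi * 0.3 * tt + phase)
    stack <- array(0, dim = c(nfr, d[1L], d[2L]))
    for (t in seq_len(nfr))
      stack[t, , ] <- one * (1 + wshift[t] * ifelse(heelish, 1, -1))
    pf <- place_footfall(nfr, stack, 1L, cy, cx, geometry)
    if (!is.null(pf)) {
      pending[[length(pending) + 1L]] <- pf$render
      row <- pf$truth
      row$Side <- s; row$Orientation <- 1L; row$Standing <- 1L
      row$PassID <- 0L; row$RotationAngle <- 0; row$ToeOut <- 0
      truth[[length(truth) + 1L]] <- row
    }
  }
  for (r in pending)
    for (t in seq_along(r$frames)) {
      g <- r$frames[t]
      frames[g, r$ys, r$xs] <- pmax(frames[g, r$ys, r$xs], r$vals[t, , ])
    }
  truth_df <- do.call(rbind, lapply(truth, as.data.frame))
  truth_df$FootstepID <- seq_len(nrow(truth_df)) - 1L
  truth_df$Artifact <- 0L
  list(trial = rawTrial(frames, geometry, task = "S1"), truth = truth_df)
}

#' Sensor-artifact specification
#'
#' @param noiseSdKpa additive Gaussian noise (kPa), clipped and re-quantized.
#' @param ghostRate fraction of footsteps that leave ghosting.
#' @param ghostFrames frames a ghosting sensor stays held after lift-off.
#' @param ghostSensors number of sensors held per ghosted step.
#' @param deadTile NULL or c(tileRow, tileCol) (1-based) of a disconnected
#'   tile whose pixels read 0 in every frame.
#' @param shortContactRate fraction of steps truncated to
#'   \code{shortContactFraction} of their stance (premature lift-off).
#' @param shortContactFraction retained fraction of stance for truncated steps.
#' @return list of class "NoiseSpec".
#' @export
noiseSpec <- function(noiseSdKpa = 0, ghostRate = 0, ghostFrames = 30L,
                      ghostSensors = 12L, deadTile = NULL,
                      shortContactRate = 0, shortContactFraction = 0.5) {
  structure(list(noiseSdKpa = noiseSdKpa, ghostRate = ghostRate,
                 ghostFrames = as.integer(ghostFrames),
                 ghostSensors = as.integer(ghostSensors), deadTile = deadTile,
                 shortContactRate = shortContactRate,
                 shortContactFraction = shortContactFraction),
            class = "NoiseSpec")
}

#' Inject sensor artifacts into a simulated trial
#'
#' Ghosting holds chosen active sensors at their lift-off value for k frames
#' after the step ends; a dead tile zeroes a whole tile region; noise is
#' additive Gaussian, clipped to the sensing range and re-quantized; short
#' contacts zero a step's pixels after a fraction of its stance. The truth
#' table's \code{Artifact} column marks affected steps. A spec with all rates
#' zero is the identity.
#'
#' @param sim list(trial, truth) from a simulator, or a bare
#'   \linkS4class{RawTrial}.
#' @param spec \code{\link{noiseSpec}}.
#' @param seed integer seed.
#' @return same structure as \code{sim}, with artifacts applied.
#' @export
injectArtifacts <- function(sim, spec, seed = 1) {
  bare <- is(sim, "RawTrial")
  trial <- if (bare) sim else sim$trial
  truth <- if (bare) NULL else sim$truth
  geometry <- trialGeometry(trial)
  frames <- trialFrames(trial)
  rng <- local_rng(seed)
  nfr <- dim(frames)[1L]

  if (!is.integer(frames)) {
    frames <- quantize_pressure(pmax(frames, 0), geometry)
    storage.mode(frames) <- "integer"
  }
  if (!is.null(truth) && nrow(truth) > 0 &&
      (spec$ghostRate > 0 || spec$shortContactRate > 0)) {
    for (i in seq_len(nrow(truth))) {
      ys <- (truth$Ymin[i]:truth$Ymax[i]) + 1L
      xs <- (truth$Xmin[i]:truth$Xmax[i]) + 1L
      ef <- truth$EndFrame[i] + 1L
      sf <- truth$StartFrame[i] + 1L
      if (spec$ghostRate > 0 && rng$runif(1) < spec$ghostRate && ef < nfr) {
        last <- frames[ef, ys, xs]
        act <- which(last >= geometry@activationKpa)
        if (length(act)) {
          pick <- unique(act[rng$int(min(spec$ghostSensors, length(act)),
                                     length(act))])
          gframes <- (ef + 1L):min(nfr, ef + spec$ghostFrames)
          blk <- frames[gframes, ys, xs, drop = FALSE]
          for (t in seq_along(gframes)) {
            sl <- blk[t, , ]
            sl[pick] <- pmax(sl[pick], last[pick])
            blk[t, , ] <- sl
          }
          frames[gframes, ys, xs] <- blk
          truth$Artifact[i] <- 1L
        }
      } else if (spec$shortContactRate > 0 && rng$runif(1) < spec$shortContactRate) {
        cut <- sf + max(1L, round((ef - sf + 1L) * spec$shortContactFraction)) - 1L
        if (cut < ef) {
          frames[(cut + 1L):ef, ys, xs] <- 0L
          truth$EndFrame[i] <- cut - 1L
          truth$Artifact[i] <- 1L
        }
      }
    }
  }
  if (!is.null(spec$deadTile)) {
    n <- geometry@sensorsPerTileSide
    ys <- (spec$deadTile[1L] - 1L) * n + seq_len(n)
    xs <- (spec$deadTile[2L] - 1L) * n + seq_len(n)
    frames[, ys, xs] <- 0L
  }
  if (spec$noiseSdKpa > 0) {
    # add noise frame-by-frame to avoid a second whole-trial array
    d <- dim(frames)
    storage.mode(frames) <- "double"
    for (i in seq_len(d[1L])) {
      fr <- frames[i, , ] + rng$rnorm(d[2L] * d[3L], 0, spec$noiseSdKpa)
      frames[i, , ] <- quantize_pressure(pmax(fr, 0), geometry)
    }
    storage.mode(frames) <- "integer"
  }
  trial2 <- rawTrial(frames, geometry, trial@participantID, trial@footwear,
                     trial@task)
  if (bare) trial2 else list(trial = trial2, truth = truth)
}
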
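# Footstep alignment and the configurable normalization menu, including the
# two released preset pipelines:
#   Pipeline 1: rotate -> zero-pad 75 x 40 + center -> 101-frame resampling
#   Pipeline 2: rotate -> measure -> resize sole to 70 x 25 -> pad 75 x 40 ->
#               101-frame resampling -> amplitude (mean total pressure)

# Nearest-neighbour resampling index: maps output index i (1..nOut) onto an
# input index so endpoints map to endpoints and exact halves round DOWN
# (0->first, 100%->last; the half-down tie-break reproduces the enumerated
# mapping for small inputs, e.g. n=3: outputs 1-26 copy input 1, 27-76 copy
# input 2, 77-101 copy input 3).
resample_index <- function(nIn, nOut) {
  if (nIn == 1L) return(rep(1L, nOut))
  x <- (seq_len(nOut) - 1) * (nIn - 1) / (nOut - 1)
  pmin(nIn, pmax(1L, as.integer(ceiling(x - 0.5)) + 1L))
}

active_union <- function(tens, threshold) {
  apply(tens >= threshold, c(2L, 3L), any)
}

crop_to_content <- function(tens) {
  nz <- apply(tens > 0, c(2L, 3L), any)
  if (!any(nz)) return(tens)
  ry <- range(which(rowSums(nz) > 0))
  rx <- range(which(colSums(nz) > 0))
  tens[, ry[1L]:ry[2L], rx[1L]:rx[2L], drop = FALSE]
}

# Angle of the first principal axis of TRUE pixels in a mask (optionally
# weighted), measured from the +y (row) axis toward +x, degrees in (-90, 90].
# NULL when the pixel cloud is too isotropic to orient.
pc_angle_mask <- function(mask, weights = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(NULL)
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights[mask]
  mu <- colSums(idx * w) / sum(w)
  cc <- sweep(idx, 2L, mu)
  cv <- crossprod(cc * sqrt(w / sum(w)))
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] <= 0 || eg$values[1L] / eg$values[2L] < 1.05) return(NULL)
  v <- eg$vectors[, 1L]
  a <- atan2(v[2L], v[1L]) * 180 / pi
  if (a <= -90) a <- a + 180
  if (a > 90) a <- a - 180
  a
}

#' Rotate a footstep upright along its principal axis
#'
#' The first principal-component axis of the unweighted active-pixel
#' coordinates (union over the stance) is computed; every frame is rotated
#' (nearest-neighbour resampling, which preserves pressure values and their
#' quantization) so this axis is vertical, and the stack is rotated 180
#' degrees when the walking direction implies the toe would point down, giving
#' a canonical toe-up pose. The reported angle is the signed angle between
#' the original axis and the grid long (y) axis, degrees in (-90, 90],
#' positive toward +x.
#'
#' @param step \linkS4class{Footstep} or pressure array.
#' @param orientation 0/1 walking direction (1 = toward increasing y).
#' @param geometry \linkS4class{WalkwayGeometry} (activation threshold).
#' @param weighted use pressure-weighted instead of binary coordinates.
#' @return list(tensor = rotated stack cropped to content, angle = degrees).
#' @export
principalAxisAlign <- function(step, orientation, geometry = buildGeometry(),
                               weighted = FALSE) {
  tens <- tensor3(step)
  mask <- active_union(tens, geometry@activationKpa)
  if (sum(mask) < 2L) stop("need at least 2 active pixels to align")
  angle <- pc_angle_mask(mask,
                         weights = if (weighted) peakPressureImage(tens))
  if (is.null(angle)) {
    warning("nearly isotropic pixel cloud; rotation angle set to 0")
    angle <- 0
  }
  rot <- rotate_stack_nn(tens, -angle)
  if (orientation == 1) rot <- rot180_stack(rot)
  list(tensor = crop_to_content(rot), angle = angle)
}

#' Zero-pad a footstep to fixed spatial dimensions, centered
#'
#' Pads every frame to H x W with the input's bounding-box centroid at the
#' center of the padded area; all added pixels are zero, so each frame's total
#' pressure is conserved exactly.
#'
#' @param tens T x h x w array (h <= H, w <= W).
#' @param H,W output dimensions.
#' @return T x H x W array.
#' @export
padAndCenter <- function(tens, H = 75L, W = 40L) {
  tens <- tensor3(tens)
  d <- dim(tens)
  if (d[2L] > H || d[3L] > W)
    stop("overflow: input ", d[2L], " x ", d[3L],
         " does not fit in ", H, " x ", W)
  y0 <- round((H - d[2L]) / 2)
  x0 <- round((W - d[3L]) / 2)
  out <- array(0, dim = c(d[1L], H, W))
  out[, y0 + seq_len(d[2L]), x0 + seq_len(d[3L])] <- tens
  out
}

#' Temporal normalization by nearest-neighbour frame resampling
#'
#' Standardizes a footstep to \code{T} frames, each representing a fixed
#' percentage of the stance; every output frame is an exact copy of some
#' input frame (output i copies input round(i (T_in - 1) / (T - 1)), 0-based,
#' with exact halves rounding down).
#'
#' @param tens T_in x h x w array (T_in >= 1).
#' @param T output frame count.
#' @return T x h x w array.
#' @export
normalizeTime <- function(tens, T = 101L) {
  tens <- tensor3(tens)
  tens[resample_index(dim(tens)[1L], T), , , drop = FALSE]
}

#' Sole contact dimensions of an aligned footstep
#'
#' From the stance-union active mask of an upright footstep: length is the
#' maximum count of active pixels along the vertical axis in any single
#' column, width the maximum along the horizontal axis in any single row.
#'
#' @param tens aligned T x h x w array.
#' @param geometry \linkS4class{WalkwayGeometry} (activation threshold).
#' @return c(FootLength, FootWidth) in pixels.
#' @export
soleDimensions <- function(tens, geometry = buildGeometry()) {
  tens <- tensor3(tens)
  mask <- active_union(tens, geometry@activationKpa)
  if (!any(mask)) stop("no active pixels")
  c(FootLength = max(colSums(mask)), FootWidth = max(rowSums(mask)))
}

#' Resize an aligned footstep to common sole dimensions
#'
#' Per-frame nearest-neighbour spatial rescale by factors L / FootLength
#' (vertical) and W / FootWidth (horizontal); nearest-neighbour copies values,
#' so per-frame maxima are preserved.
#'
#' @param tens aligned T x h x w array.
#' @param dims target c(L, W) sole dimensions in pixels.
#' @param measured measured c(FootLength, FootWidth) (from
#'   \code{\link{soleDimensions}}).
#' @param maxDims optional c(H, W) canvas bound (e.g. the downstream padding
#'   dimensions): the scale factors are clamped so the resized canvas fits.
#'   Sole counts are slightly smaller than spatial extents, so the clamp only
#'   binds for degenerate shapes such as tiny incomplete boundary fragments.
#' @return resized array.
#' @export
resizeSole <- function(tens, dims = c(70L, 25L), measured, maxDims = NULL) {
  tens <- tensor3(tens)
  d <- dim(tens)
  sy <- dims[1L] / measured[1L]
  sx <- dims[2L] / measured[2L]
  if (!is.null(maxDims)) {
    sy <- min(sy, maxDims[1L] / d[2L])
    sx <- min(sx, maxDims[2L] / d[3L])
  }
  oh <- max(1L, round(d[2L] * sy))
  ow <- max(1L, round(d[3L] * sx))
  ri <- pmin(d[2L], pmax(1L, ceiling((seq_len(oh) - 0.5) / sy)))
  ci <- pmin(d[3L], pmax(1L, ceiling((seq_len(ow) - 0.5) / sx)))
  tens[, ri, ci, drop = FALSE]
}

#' Amplitude normalization
#'
#' "mean-pressure" divides all values by the time-averaged per-frame total
#' pressure (so per-frame totals average 1); "min-max" maps values linearly
#' to [0, 1]; "body-mass" divides by the participant's mass in kg.
#'
#' @param tens pressure array.
#' @param mode one of "mean-pressure", "min-max", "body-mass".
#' @param bodyMass mass in kg (body-mass mode).
#' @return list(tensor, meanPressure): meanPressure is the average total
#'   pressure (kPa) recorded before rescaling.
#' @export
normalizeAmplitude <- function(tens, mode = c("mean-pressure", "min-max",
                                              "body-mass"), bodyMass = NULL) {
  mode <- match.arg(mode)
  tens <- tensor3(tens)
  if (all(tens == 0)) stop("all-zero tensor cannot be amplitude-normalized")
  meanP <- mean(apply(tens, 1L, sum))
  out <- switch(mode,
    "mean-pressure" = tens / meanP,
    "min-max" = (tens - min(tens)) / (max(tens) - min(tens)),
    "body-mass" = {
      if (is.null(bodyMass) || bodyMass <= 0) stop("body_mass must be > 0")
      tens / bodyMass
    })
  list(tensor = out, meanPressure = meanP)
}

#' Normalization pipeline configuration
#'
#' A pipeline is an explicit ordered list of operations drawn from the menu:
#' \code{rotate} (principal-axis alignment), \code{pad} (zero-pad H x W +
#' center), \code{resize} (sole to L x W), \code{interpolate} (T frames),
#' \code{amplitude} (mode). Spatial measuring/resizing requires a prior
#' rotate; pad dimensions must be able to hold resize dimensions.
#'
#' @param ... operation specs, each a list with an \code{op} element and its
#'   parameters, applied in the given order.
#' @return list of class "PipelineConfig".
#' @examples
#' cfg <- pipelineConfig(list(op = "rotate"), list(op = "pad", H = 75, W = 40))
#' @export
pipelineConfig <- function(...) {
  ops <- list(...)
  known <- c("rotate", "pad", "resize", "interpolate", "amplitude")
  seen_rotate <- FALSE
  for (o in ops) {
    if (!is.list(o) || is.null(o$op) || !(o$op %in% known))
      stop("config error: unknown op '", if (is.list(o)) o$op else o, "'")
    if (o$op == "rotate") seen_rotate <- TRUE
    if (o$op %in% c("resize") && !seen_rotate)
      stop("config error: '", o$op, "' requires a prior 'rotate'")
  }
  pads <- Filter(function(o) o$op == "pad", ops)
  res <- Filter(function(o) o$op == "resize", ops)
  if (length(pads) && length(res)) {
    if (pads[[1L]]$H < res[[1L]]$L || pads[[1L]]$W < res[[1L]]$W)
      stop("config error: pad dims must be >= resize dims")
  }
  structure(ops, class = "PipelineConfig")
}

#' Preset pipelines
#' @param which 1 (rotate, pad 75 x 40, 101 frames) or 2 (rotate, resize sole
#'   to 70 x 25, pad, 101 frames, mean-pressure amplitude).
#' @return a \code{\link{pipelineConfig}}.
#' @export
pipelinePreset <- function(which) {
  if (which == 1)
    pipelineConfig(list(op = "rotate"), list(op = "pad", H = 75L, W = 40L),
                   list(op = "interpolate", T = 101L))
  else if (which == 2)
    pipelineConfig(list(op = "rotate"), list(op = "resize", L = 70L, W = 25L),
                   list(op = "pad", H = 75L, W = 40L),
                   list(op = "interpolate", T = 101L),
                   list(op = "amplitude", mode = "mean-pressure"))
  else stop("unknown preset ", which)
}

#' Run a normalization pipeline on one footstep
#'
#' Applies the configured operations in order and collects the derived
#' metadata fields: RotationAngle (when rotate ran), FootLength/FootWidth
#' (measured after alignment), MeanPressure (average total pressure of the
#' input, kPa).
#'
#' @param step \linkS4class{Footstep}.
#' @param config \code{\link{pipelineConfig}} or \code{\link{pipelinePreset}}.
#' @param orientation 0/1 walking direction of the step.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @param bodyMass participant mass (body-mass amplitude mode only).
#' @return list of class "NormalizedFootstep": \code{tensor} plus
#'   \code{RotationAngle}, \code{FootLength}, \code{FootWidth},
#'   \code{MeanPressure} (NA where the corresponding op did not run;
#'   MeanPressure is always recorded).
#' @export
runPipeline <- function(step, config, orientation,
                        geometry = buildGeometry(), bodyMass = NULL) {
  if (!inherits(config, "PipelineConfig"))
    config <- do.call(pipelineConfig, config)
  tens <- tensor3(step)
  meta <- list(RotationAngle = NA_real_, FootLength = NA_real_,
               FootWidth = NA_real_,
               MeanPressure = mean(apply(tens, 1L, sum)))
  for (o in config) {
    tens <- switch(o$op,
      rotate = {
        al <- principalAxisAlign(tens, orientation, geometry)
        meta$RotationAngle <- al$angle
        sd <- soleDimensions(al$tensor, geometry)
        meta$FootLength <- unname(sd[1L]); meta$FootWidth <- unname(sd[2L])
        al$tensor
      },
      pad = padAndCenter(tens, o$H, o$W),
      resize = {
        if (is.na(meta$FootLength)) stop("config error: resize before rotate")
        pads <- Filter(function(p) p$op == "pad", config)
        lim <- if (length(pads)) c(pads[[1L]]$H, pads[[1L]]$W) else NULL
        crop_to_content(
          resizeSole(tens, c(o$L, o$W), c(meta$FootLength, meta$FootWidth),
                     maxDims = lim))
      },
      interpolate = normalizeTime(tens, o$T),
      amplitude = normalizeAmplitude(tens, o$mode, bodyMass)$tensor)
  }
  structure(c(list(tensor = tens), meta), class = "NormalizedFootstep")
}
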
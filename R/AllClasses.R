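#' @useDynLib gaitmat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' WalkwayGeometry: physical model of the pressure-sensing walkway
#'
#' Holds the instrument constants of a modular tile walkway: a
#' \code{tilesAcross} x \code{tilesAlong} grid of square tiles, each carrying a
#' \code{sensorsPerTileSide} x \code{sensorsPerTileSide} sensor grid at
#' \code{pitchCm} spacing, sampled at \code{sampleRateHz}. All downstream
#' operations take a geometry argument, so pipelines can run on reduced grids;
#' the defaults reproduce a 2 x 6 tile, 720 x 240 sensor, 100 Hz device with
#' 0.5 cm pitch (1.2 m x 3.6 m active area, 172,800 sensors).
#'
#' Grid coordinates throughout the package: frames are matrices with rows
#' indexing the long walkway axis (y, 0-based 0..height-1) and columns the
#' short axis (x, 0..width-1). Tiles are numbered in reading order with Tiles
#' 1-2 at y = 0; Orientation = 1 means walking toward increasing y. When
#' walking toward +y the walker's left side is at larger x.
#'
#' @slot tilesAcross integer, tiles across the walkway width.
#' @slot tilesAlong integer, tiles along the walking direction.
#' @slot sensorsPerTileSide integer, sensors along one tile edge.
#' @slot pitchCm numeric, sensor pitch in cm (sensor side length s).
#' @slot sampleRateHz numeric, frame rate in Hz.
#' @slot activationKpa numeric, activation threshold in kPa (default 10).
#' @slot pressureMaxKpa numeric, sensing range ceiling in kPa (default 1510).
#' @slot pressureResKpa numeric, quantization step in kPa (default 10).
#' @name WalkwayGeometry-class
#' @aliases WalkwayGeometry
#' @exportClass WalkwayGeometry
setClass("WalkwayGeometry",
  representation(
    tilesAcross = "integer",
    tilesAlong = "integer",
    sensorsPerTileSide = "integer",
    pitchCm = "numeric",
    sampleRateHz = "numeric",
    activationKpa = "numeric",
    pressureMaxKpa = "numeric",
    pressureResKpa = "numeric"
  )
)

setValidity("WalkwayGeometry", function(object) {
  msgs <- character()
  for (s in c("tilesAcross", "tilesAlong", "sensorsPerTileSide")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msgs <- c(msgs, sprintf("'%s' must be a single count >= 1", s))
  }
  for (s in c("pitchCm", "sampleRateHz", "activationKpa",
              "pressureMaxKpa", "pressureResKpa")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single positive number", s))
  }
  if (length(msgs)) msgs else TRUE
})

#' SessionPlan: ordered trial schedule for one recording session
#'
#' @slot participantID character scalar.
#' @slot trials data.frame with columns \code{footwear}, \code{task},
#'   \code{duration_s}, one row per trial in recording order.
#' @name SessionPlan-class
#' @aliases SessionPlan
#' @exportClass SessionPlan
setClass("SessionPlan",
  representation(participantID = "character", trials = "data.frame")
)

setValidity("SessionPlan", function(object) {
  tr <- object@trials
  need <- c("footwear", "task", "duration_s")
  if (!all(need %in% names(tr)))
    return("trials must have columns footwear, task, duration_s")
  if (!all(tr$footwear %in% c("BF", "ST", "P1", "P2")))
    return("unknown footwear code")
  if (!all(tr$task %in% c("S1", "S2", "S3", "W1", "W2", "W3", "W4")))
    return("unknown task code")
  TRUE
})

#' RawTrial: one continuous pressure recording
#'
#' A trial is a stack of pressure frames (kPa) with condition tags. Frames are
#' held either fully in memory (numeric/integer array n x H x W) or as a
#' file-backed handle created by \code{\link{readTrial}} with
#' \code{lazy = TRUE}, which reads frames on demand so 3 GB raw tensors never
#' need to be materialized.
#'
#' @slot frames array (n x H x W) of pressures in kPa, or an empty array when
#'   file-backed.
#' @slot source list; for file-backed trials, the container handle.
#' @slot participantID,footwear,task character condition tags.
#' @slot geometry WalkwayGeometry.
#' @name RawTrial-class
#' @aliases RawTrial
#' @exportClass RawTrial
setClass("RawTrial",
  representation(
    frames = "array",
    source = "list",
    participantID = "character",
    footwear = "character",
    task = "character",
    geometry = "WalkwayGeometry"
  )
)

setValidity("RawTrial", function(object) {
  lazy <- length(object@source) > 0L
  d <- if (lazy) object@source$dim else dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a rank-3 array (frames x height x width)")
  g <- object@geometry
  if (d[2L] != gridHeight(g) || d[3L] != gridWidth(g))
    return(sprintf("frame shape %d x %d does not match geometry %d x %d",
                   d[2L], d[3L], gridHeight(g), gridWidth(g)))
  if (!lazy && length(object@frames)) {
    rng <- range(object@frames)
    if (is.na(rng[1L])) return("frames contain NA")
    if (rng[1L] < 0) return("negative pressures")
    if (rng[2L] > g@pressureMaxKpa) return("pressure exceeds sensing range")
  }
  TRUE
})

#' Footstep: one extracted footstep
#'
#' @slot tensor array (T x h x w) of pressures in kPa, cropped to the
#'   footstep's spatial box with pixels outside the track's masks zeroed.
#' @slot box named integer vector with elements StartFrame, EndFrame, Ymin,
#'   Ymax, Xmin, Xmax (zero-indexed, inclusive) locating the tensor in the
#'   parent trial.
#' @slot trackId integer track identifier.
#' @name Footstep-class
#' @aliases Footstep
#' @exportClass Footstep
setClass("Footstep",
  representation(tensor = "array", box = "integer", trackId = "integer")
)

setValidity("Footstep", function(object) {
  b <- object@box
  need <- c("StartFrame", "EndFrame", "Ymin", "Ymax", "Xmin", "Xmax")
  if (!all(need %in% names(b))) return("box must name StartFrame..Xmax")
  if (b["StartFrame"] > b["EndFrame"]) return("StartFrame > EndFrame")
  if (b["Ymin"] > b["Ymax"] || b["Xmin"] > b["Xmax"])
    return("degenerate spatial box")
  d <- dim(object@tensor)
  if (length(d) != 3L) return("tensor must be rank 3")
  if (d[1L] != b["EndFrame"] - b["StartFrame"] + 1L)
    return("tensor frame count disagrees with box")
  if (any(object@tensor < 0)) return("negative pressures in tensor")
  TRUE
})

setMethod("show", "WalkwayGeometry", function(object) {
  cat(sprintf(
    "WalkwayGeometry: %d x %d tiles, %d px/tile side -> %d x %d sensors\n",
    object@tilesAcross, object@tilesAlong, object@sensorsPerTileSide,
    gridHeight(object), gridWidth(object)))
  cat(sprintf("  pitch %.2f cm (A = %.3g m^2), %g Hz, active area %.2f x %.2f m\n",
    object@pitchCm, sensorArea(object), object@sampleRateHz,
    gridWidth(object) * object@pitchCm / 100,
    gridHeight(object) * object@pitchCm / 100))
  cat(sprintf("  activation %g kPa, range [0, %g] kPa @ %g kPa resolution\n",
    object@activationKpa, object@pressureMaxKpa, object@pressureResKpa))
})

setMethod("show", "SessionPlan", function(object) {
  cat(sprintf("SessionPlan for participant %s: %d trials, %.0f min total\n",
    object@participantID, nrow(object@trials),
    sum(object@trials$duration_s) / 60))
  cat("  order:", paste(paste0(object@trials$footwear, ":", object@trials$task),
      collapse = " "), "\n")
})

setMethod("show", "RawTrial", function(object) {
  d <- trialDim(object)
  cat(sprintf("RawTrial %s/%s/%s: %d frames x %d x %d (%s)\n",
    object@participantID, object@footwear, object@task, d[1L], d[2L], d[3L],
    if (length(object@source)) "file-backed" else "in-memory"))
})

setMethod("show", "Footstep", function(object) {
  b <- object@box
  cat(sprintf(
    "Footstep (track %d): frames %d-%d, y %d-%d, x %d-%d (%d active px)\n",
    object@trackId, b["StartFrame"], b["EndFrame"], b["Ymin"], b["Ymax"],
    b["Xmin"], b["Xmax"], sum(apply(object@tensor, c(2, 3), max) > 0)))
})
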
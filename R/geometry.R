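#' Build a walkway geometry
#'
#' Constructs the physical model of the sensing walkway. Derived quantities
#' (grid dimensions, sensor area, active area) are available through accessors
#' and are consistent by construction: grid height = tilesAlong x
#' sensorsPerTileSide, width = tilesAcross x sensorsPerTileSide, sensor area
#' A = (pitch/100)^2 m^2.
#'
#' @param tilesAcross,tilesAlong tile counts across / along the walkway.
#' @param sensorsPerTileSide sensors along one tile edge.
#' @param pitchCm sensor pitch (side length s) in cm.
#' @param sampleRateHz frame rate in Hz.
#' @param activationKpa activation threshold in kPa.
#' @param pressureMaxKpa sensing ceiling in kPa.
#' @param pressureResKpa quantization step in kPa.
#' @return A \linkS4class{WalkwayGeometry}.
#' @examples
#' g <- buildGeometry()
#' nSensors(g)    # 172800
#' sensorArea(g)  # 2.5e-5 m^2
#' @export
buildGeometry <- function(tilesAcross = 2L, tilesAlong = 6L,
                          sensorsPerTileSide = 120L, pitchCm = 0.5,
                          sampleRateHz = 100, activationKpa = 10,
                          pressureMaxKpa = 1510, pressureResKpa = 10) {
  counts <- c(tilesAcross, tilesAlong, sensorsPerTileSide)
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != round(counts)))
    stop("invalid geometry: tile/sensor counts must be integers >= 1")
  if (!is.finite(pitchCm) || pitchCm <= 0)
    stop("invalid geometry: pitch must be > 0")
  if (!is.finite(sampleRateHz) || sampleRateHz <= 0)
    stop("invalid geometry: sample rate must be > 0")
  new("WalkwayGeometry",
    tilesAcross = as.integer(tilesAcross),
    tilesAlong = as.integer(tilesAlong),
    sensorsPerTileSide = as.integer(sensorsPerTileSide),
    pitchCm = pitchCm, sampleRateHz = sampleRateHz,
    activationKpa = activationKpa, pressureMaxKpa = pressureMaxKpa,
    pressureResKpa = pressureResKpa)
}

#' Geometry accessors
#'
#' @param geometry a \linkS4class{WalkwayGeometry}.
#' @return \code{gridHeight}/\code{gridWidth}: sensor counts along y / x;
#'   \code{nSensors}: total sensors; \code{sensorArea}: area of one sensor in
#'   m^2; \code{activeArea}: c(width, length) of the sensing surface in m;
#'   \code{sampleRate}: Hz; \code{sensorPitch}: cm.
#' @name geometry-accessors
#' @export
gridHeight <- function(geometry) geometry@tilesAlong * geometry@sensorsPerTileSide

#' @rdname geometry-accessors
#' @export
gridWidth <- function(geometry) geometry@tilesAcross * geometry@sensorsPerTileSide

#' @rdname geometry-accessors
#' @export
nSensors <- function(geometry) gridHeight(geometry) * gridWidth(geometry)

#' @rdname geometry-accessors
#' @export
sensorArea <- function(geometry) (geometry@pitchCm / 100)^2

#' @rdname geometry-accessors
#' @export
activeArea <- function(geometry)
  c(width_m = gridWidth(geometry) * geometry@pitchCm / 100,
    length_m = gridHeight(geometry) * geometry@pitchCm / 100)

#' @rdname geometry-accessors
#' @export
sampleRate <- function(geometry) geometry@sampleRateHz

#' @rdname geometry-accessors
#' @export
sensorPitch <- function(geometry) geometry@pitchCm

#' Build a randomized session plan
#'
#' One session comprises 28 trials: for each of 4 footwear conditions (BF, ST,
#' P1, P2), three 30-second balance trials (S1-S3, in fixed order) followed by
#' four 90-second walking trials (W1-W4). The footwear block order and the
#' within-block walking-speed order are permutations drawn from a seeded
#' generator, so the same seed always yields the same plan. Totals: 30 min of
#' recording, 24 min of it walking.
#'
#' @param participantID identifier string.
#' @param seed integer seed for the permutations.
#' @return A \linkS4class{SessionPlan}.
#' @examples
#' plan <- buildSessionPlan("001", seed = 7)
#' nrow(sessionTrials(plan))        # 28
#' sum(sessionTrials(plan)$duration_s) / 60  # 30
#' @export
buildSessionPlan <- function(participantID, seed) {
  rng <- local_rng(seed)
  footwear_order <- rng$sample(c("BF", "ST", "P1", "P2"))
  rows <- lapply(footwear_order, function(fw) {
    speeds <- rng$sample(c("W1", "W2", "W3", "W4"))
    data.frame(
      footwear = fw,
      task = c("S1", "S2", "S3", speeds),
      duration_s = c(30, 30, 30, 90, 90, 90, 90),
      stringsAsFactors = FALSE)
  })
  new("SessionPlan", participantID = as.character(participantID),
      trials = do.call(rbind, rows))
}

#' @rdname buildSessionPlan
#' @param plan a SessionPlan.
#' @export
sessionTrials <- function(plan) plan@trials

# Seeded RNG helper: isolates all simulator/plan randomness from the global
# RNG state (restores it on exit of each draw).
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    res <- expr
    state <<- get(".Random.seed", globalenv())
    res
  }
  list(
    sample = function(x, ...) with_state(sample(x, ...)),
    runif = function(n, min = 0, max = 1) with_state(runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    rpois = function(n, lambda) with_state(rpois(n, lambda)),
    int = function(n, max) with_state(sample.int(max, n, replace = TRUE))
  )
}
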
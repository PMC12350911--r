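# Per-trial robust quality scoring: every footstep is compared to the trial's
# representative median footstep through three characteristics (active-sensor
# count, duration, GRF profile), each standardized robustly; the R-score is
# the root mean square of the three robust deviations, so for approximately
# normal measurements it reads as "number of standard deviations from the
# trial center". Footsteps at or above the threshold (default 2.0) are
# outliers.

#' Robust z-scores
#'
#' z_i = (v_i - median(v)) / (1.4826 * MAD(v)), MAD = median(|v - median(v)|).
#' When MAD = 0 the score is 0 for values equal to the median and +/-Inf
#' otherwise (degenerate pool; a message is emitted).
#'
#' @param values numeric vector (length >= 3).
#' @param pool optional reference pool to take the median/MAD from (defaults
#'   to \code{values} itself).
#' @return numeric vector of robust z-scores.
#' @export
robustZ <- function(values, pool = values) {
  if (length(pool) < 3L) stop("need at least 3 values")
  med <- stats::median(pool)
  mad_raw <- stats::median(abs(pool - med))
  if (mad_raw == 0) {
    message("robustZ: MAD = 0; scores are 0 at the median, +/-Inf elsewhere")
    return(ifelse(values == med, 0, sign(values - med) * Inf))
  }
  (values - med) / (1.4826 * mad_raw)
}

#' Characteristics of one footstep used for quality scoring
#'
#' @param step \linkS4class{Footstep}.
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @return list: \code{activeCount} (sensors active at any time during the
#'   step), \code{duration} (frames), \code{grf101} (GRF profile resampled to
#'   101 points).
#' @export
stepCharacteristics <- function(step, geometry) {
  tens <- step@tensor
  act <- apply(tens >= geometry@activationKpa, c(2L, 3L), any)
  grf <- grfSeries(tens, geometry)
  list(activeCount = sum(act), duration = dim(tens)[1L],
       grf101 = grf[resample_index(length(grf), 101L)])
}

#' Per-trial footstep R-scores
#'
#' The reference footstep is the per-feature median over the non-excluded
#' steps of the trial (element-wise median for the GRF profile). Each step
#' receives three robust deviations -- active-sensor count, duration, and the
#' RMS distance between its 101-point GRF profile and the median profile --
#' standardized against the non-excluded pool, and
#' Rscore = sqrt(mean(z_count^2, z_duration^2, z_grf^2)) >= 0.
#'
#' @param steps list of \linkS4class{Footstep} from one trial.
#' @param excluded logical/0-1 vector: steps left out of the reference pool
#'   (e.g. already flagged standing or incomplete).
#' @param geometry \linkS4class{WalkwayGeometry}.
#' @return numeric vector of R-scores (NA for all, with a message, when fewer
#'   than 3 usable steps exist).
#' @export
rScores <- function(steps, excluded = rep(FALSE, length(steps)),
                    geometry = buildGeometry()) {
  excluded <- as.logical(excluded)
  n <- length(steps)
  use <- which(!excluded)
  if (length(use) < 3L) {
    message("rScores: fewer than 3 non-excluded steps; scores undefined")
    return(rep(NA_real_, n))
  }
  chars <- lapply(steps, stepCharacteristics, geometry = geometry)
  counts <- vapply(chars, `[[`, numeric(1), "activeCount")
  durs <- vapply(chars, `[[`, numeric(1), "duration")
  grfs <- do.call(rbind, lapply(chars, `[[`, "grf101"))
  med_curve <- apply(grfs[use, , drop = FALSE], 2L, stats::median)
  dists <- sqrt(rowMeans((grfs - matrix(med_curve, n, 101L, byrow = TRUE))^2))
  zc <- robustZ(counts, counts[use])
  zd <- robustZ(durs, durs[use])
  zg <- robustZ(dists, dists[use])
  sqrt((zc^2 + zd^2 + zg^2) / 3)
}

#' Flag outliers by R-score
#' @param rscores numeric vector.
#' @param threshold flag when Rscore >= threshold (default 2.0).
#' @return integer 0/1 flags (NA scores give 0).
#' @export
flagOutliers <- function(rscores, threshold = 2.0) {
  as.integer(!is.na(rscores) & rscores >= threshold)
}

#' Combine exclusion flags
#' @param standing,incomplete,outlier 0/1 vectors.
#' @return Exclude = Standing OR Incomplete OR Outlier, as 0/1.
#' @export
combineExclude <- function(standing, incomplete, outlier) {
  as.integer(standing | incomplete | outlier)
}
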
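#' @include AllClasses.R
NULL

#' Step velocity between two sampled observations
#'
#' Converts the centroid displacement between consecutive sampled frames to a
#' physical speed: \eqn{\|S_c - S_p\| \cdot s / (stride / fps)} um/s, where
#' \eqn{s} is the pixel scale in um/px. The (non-physical) literal mode
#' divides the pixel displacement by the frame rate instead, ignoring both
#' the pixel scale and the sampling stride; it is retained only for
#' comparison and clearly produces px*s/frame units.
#'
#' @param sp,sc previous and current centroids, length-2 (x, y) in pixels.
#' @param stride frames between the two observations (>= 1).
#' @param fps frame rate (> 0).
#' @param pixelScaleUm micrometres per pixel.
#' @param literal use the literal displacement / frame-rate form.
#' @return velocity in um/s (or px*s/frame in literal mode).
#' @examples
#' stepVelocity(c(0, 0), c(30, 40), stride = 10, fps = 50,
#'              pixelScaleUm = 0.2)   # 50 um/s
#' @export
stepVelocity <- function(sp, sc, stride = 10L, fps = 50,
                         pixelScaleUm = 0.2, literal = FALSE) {
  if (stride < 1 || fps <= 0) stop("stride must be >= 1 and fps > 0")
  disp <- euclideanDistance(sc, sp)
  if (literal) return(disp / fps)
  disp * pixelScaleUm / (stride / fps)
}

#' Mean velocity of a track
#'
#' Arithmetic mean of the step velocities over all consecutive observation
#' pairs of the track. Tracks with fewer than two observations have velocity
#' 0 (no displacement was ever measured).
#'
#' @param track a track record (list with \code{frames}, \code{x}, \code{y}).
#' @param fps frame rate.
#' @param pixelScaleUm micrometres per pixel.
#' @param literal passed to \code{\link{stepVelocity}}.
#' @return mean velocity in um/s.
#' @export
trackMeanVelocity <- function(track, fps, pixelScaleUm, literal = FALSE) {
  n <- length(track$frames)
  if (n < 2L) return(0)
  v <- vapply(2:n, function(k)
    stepVelocity(c(track$x[k - 1L], track$y[k - 1L]),
                 c(track$x[k], track$y[k]),
                 stride = track$frames[k] - track$frames[k - 1L],
                 fps = fps, pixelScaleUm = pixelScaleUm, literal = literal),
    numeric(1L))
  mean(v)
}

#' WHO motility class from mean velocity
#'
#' WHO classes: fast progressive at or above \code{vFast} (25 um/s), slow
#' progressive below it, immotile below \code{vImmotileEps} (effectively
#' zero). Monotone in velocity.
#'
#' @param meanVelocity mean velocity in um/s (>= 0); vectorized.
#' @param vFast fast-progressive boundary (default 25 um/s, inclusive).
#' @param vImmotileEps velocities below this count as immotile (default
#'   1 um/s; rasterization and centroid noise keep truly still objects below
#'   it).
#' @return character vector in \{"immotile", "slow_progressive",
#'   "fast_progressive"\}.
#' @examples
#' classifyWHO(c(0, 10, 25, 30))
#' @export
classifyWHO <- function(meanVelocity, vFast = 25, vImmotileEps = 1) {
  if (any(meanVelocity < 0)) stop("velocity must be >= 0")
  ifelse(meanVelocity >= vFast, "fast_progressive",
         ifelse(meanVelocity < vImmotileEps, "immotile", "slow_progressive"))
}

#' Classify a sample as normal or abnormal from class counts
#'
#' A sample is normal when the motile fraction — fast plus slow progressive
#' sperm over the total (immotile + FP + SP) — reaches \code{normalFraction}
#' (40\%, boundary inclusive). Only the sum of the two motile classes
#' matters for the call.
#'
#' @param nImmotile,nFast,nSlow class counts (total must be > 0).
#' @param normalFraction motile-fraction boundary (default 0.40).
#' @return a \linkS4class{SampleSummary} with the counts, motile fraction and
#'   classification (velocity fields NA).
#' @examples
#' classifySample(12, 14, 7)    # motile fraction 21/33 -> normal
#' @export
classifySample <- function(nImmotile, nFast, nSlow, normalFraction = 0.40) {
  if (any(c(nImmotile, nFast, nSlow) < 0)) stop("counts must be >= 0")
  total <- nImmotile + nFast + nSlow
  if (total <= 0) stop("sample is undefined: total sperm count is zero")
  mf <- (nFast + nSlow) / total
  new("SampleSummary", nImmotile = as.integer(nImmotile),
      nFast = as.integer(nFast), nSlow = as.integer(nSlow),
      meanVelocityFast = NA_real_, sdVelocityFast = NA_real_,
      meanVelocitySlow = NA_real_, sdVelocitySlow = NA_real_,
      motileFraction = mf,
      classification = if (mf >= normalFraction) "normal" else "abnormal")
}

#' Motility records for every track
#'
#' @param trackSet a \linkS4class{TrackSet}.
#' @param vFast,vImmotileEps WHO boundaries (um/s).
#' @param literal use the literal velocity form (see
#'   \code{\link{stepVelocity}}).
#' @return data.frame with \code{track_id}, \code{mean_velocity},
#'   \code{velocity_sd}, \code{n_obs}, \code{who_class}.
#' @export
motilityTable <- function(trackSet, vFast = 25, vImmotileEps = 1,
                          literal = FALSE) {
  stopifnot(is(trackSet, "TrackSet"))
  rows <- lapply(trackSet@tracks, function(trk) {
    tt <- trackTable(initialize(trackSet, tracks = list(trk)))
    v <- tt$velocity_um_s[-1L]
    data.frame(track_id = trk$id,
               mean_velocity = trackMeanVelocity(trk, trackSet@fps,
                                                 trackSet@pixelScaleUm,
                                                 literal),
               velocity_sd = if (length(v) >= 2L) sd(v) else NA_real_,
               n_obs = length(trk$frames))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), mean_velocity = numeric(0),
               velocity_sd = numeric(0), n_obs = integer(0))
  out$who_class <- if (nrow(out)) classifyWHO(out$mean_velocity, vFast,
                                              vImmotileEps) else character(0)
  out
}

#' Summarize a sample's motility from its tracks
#'
#' Classifies every track by WHO class and aggregates to the sample level.
#' The background model only ever detects movers, so the immotile count is
#' obtained by subtraction: \code{totalSpermCount} (from ground truth, a
#' static count of the first frame, or operator input) minus the number of
#' tracks, plus any tracks whose mean velocity falls below the immotile
#' epsilon. Within the fast- and slow-progressive groups the mean and
#' standard deviation of the track mean velocities are reported.
#'
#' @param trackSet a \linkS4class{TrackSet}.
#' @param totalSpermCount total sperm in the sample (>= number of tracks).
#' @param vFast,vImmotileEps WHO boundaries (um/s).
#' @param normalFraction motile-fraction boundary for the sample call.
#' @param literal use the literal velocity form.
#' @return a \linkS4class{SampleSummary}.
#' @export
summarizeSample <- function(trackSet, totalSpermCount, vFast = 25,
                            vImmotileEps = 1, normalFraction = 0.40,
                            literal = FALSE) {
  mt <- motilityTable(trackSet, vFast, vImmotileEps, literal)
  if (totalSpermCount < nrow(mt))
    stop("totalSpermCount is smaller than the number of tracks")
  nFast <- sum(mt$who_class == "fast_progressive")
  nSlow <- sum(mt$who_class == "slow_progressive")
  nImm <- (totalSpermCount - nrow(mt)) + sum(mt$who_class == "immotile")
  vF <- mt$mean_velocity[mt$who_class == "fast_progressive"]
  vS <- mt$mean_velocity[mt$who_class == "slow_progressive"]
  base <- classifySample(nImm, nFast, nSlow, normalFraction)
  initialize(base,
    meanVelocityFast = if (length(vF)) mean(vF) else NA_real_,
    sdVelocityFast = if (length(vF) >= 2L) sd(vF) else NA_real_,
    meanVelocitySlow = if (length(vS)) mean(vS) else NA_real_,
    sdVelocitySlow = if (length(vS) >= 2L) sd(vS) else NA_real_)
}
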
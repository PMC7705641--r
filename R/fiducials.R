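# Fiducial detection: beat feet and end-systole.
#
# Both detectors work on a locally smoothed trace because max -dP/dt and the
# second-derivative foot are noise-sensitive. Smoothing is Savitzky-Golay
# (local cubic polynomial) with a configurable window; derivatives are
# central differences on the smoothed trace.

# odd window length in samples for a requested width in seconds
.sg_window <- function(width_s, dt, n) {
  w <- max(5L, as.integer(round(width_s / dt)))
  if (w %% 2L == 0L) w <- w + 1L
  # sgolayfilt needs window <= series length
  if (w > n) w <- if (n %% 2L == 1L) n else n - 1L
  max(w, 5L)
}

.smooth <- function(values, width_s, dt) {
  n <- length(values)
  w <- .sg_window(width_s, dt, n)
  if (w >= n) return(values)
  signal::sgolayfilt(values, p = 3, n = w)
}

# central differences, one-sided at the ends
.gradient <- function(values, dt) {
  n <- length(values)
  g <- numeric(n)
  g[1] <- (values[2] - values[1]) / dt
  g[n] <- (values[n] - values[n - 1]) / dt
  if (n > 2)
    g[2:(n - 1)] <- (values[3:n] - values[1:(n - 2)]) / (2 * dt)
  g
}

#' Detect end-systole from the pressure waveform
#'
#' End-systole is located at the maximum negative rate of pressure change
#' (max \eqn{-dP/dt}), the conventional pressure-only surrogate for the
#' cessation of aortic flow. The derivative is computed by central
#' differences after Savitzky-Golay smoothing; the global minimum of the
#' smoothed derivative over the samples after the foot is returned, with
#' ties broken in favour of the earliest sample.
#'
#' @param beat A [beat_segment()] with at least 10 samples after the foot.
#' @param smooth_window Smoothing window in seconds (default 20 ms).
#' @return Sample index (1-based) of end-systole.
#' @examples
#' sim <- simulate_windkessel(half_sine_inflow(n_beats = 2),
#'                            windkessel_spec(Z_c = 0.05))
#' b <- beat_segment(series_window(sim$pressure, 1001, 2001))
#' (detect_end_systole(b) - 1) * 0.001  # close to T_sys = 0.3 s
#' @export
detect_end_systole <- function(beat, smooth_window = 0.02) {
  stopifnot(inherits(beat, "beat_segment"))
  p <- beat$pressure
  n <- length(p$values)
  if (n - beat$i_foot < 10L)
    stop("need at least 10 samples after the foot")
  dp <- .gradient(.smooth(p$values, smooth_window, p$dt), p$dt)
  search <- (beat$i_foot + 1L):n
  seg <- dp[search]
  if (all(seg >= 0))
    stop("no end-systole detectable: pressure derivative is nonnegative ",
         "after the foot")
  search[which.min(seg)]
}

#' Segment a continuous pressure record into beats
#'
#' Beat feet (onsets of the systolic upstroke) are located as the peak of
#' the second time-derivative of smoothed pressure in a window preceding
#' each systolic upstroke (upstrokes themselves are found as prominent
#' maxima of dP/dt separated by at least `min_period`). The record is cut at
#' the feet; each segment runs from one foot up to (not including) the next,
#' and the final segment runs from the last foot to the end of the record.
#' Candidate beats shorter than `min_period` are merged into their
#' predecessor.
#'
#' @param p A pressure [uniform_series()].
#' @param min_period Minimum admissible beat duration in seconds.
#' @param flow Optional flow [uniform_series()] on the same grid, carried
#'   into each returned segment.
#' @param smooth_window Smoothing window in seconds (default 20 ms).
#' @return List of [beat_segment()]s, ordered and non-overlapping, each with
#'   `i_foot = 1` and `i_es = NA` (annotate with [detect_end_systole()]).
#' @export
segment_beats <- function(p, min_period = 0.4, flow = NULL,
                          smooth_window = 0.02) {
  stopifnot(inherits(p, "uniform_series"))
  if (p$quantity != "pressure") stop("`p` must be a pressure series")
  if (min_period <= 0) stop("`min_period` must be positive")
  dt <- p$dt
  n <- length(p$values)
  sm <- .smooth(p$values, smooth_window, dt)
  dp <- .gradient(sm, dt)
  d2p <- .gradient(dp, dt)

  # prominent upstrokes: local maxima of dP/dt above half the global max,
  # separated by at least min_period
  thr <- 0.5 * max(dp)
  if (max(dp) <= 0) stop("no beats found")
  cand <- which(dp > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[dp[cand] >= dp[cand - 1] & dp[cand] >= dp[cand + 1]]
  if (length(cand) == 0L) stop("no beats found")
  # enforce separation, keeping the larger peak
  ups <- integer(0)
  for (i in order(-dp[cand])) {
    ci <- cand[i]
    if (all(abs(ci - ups) * dt >= min_period)) ups <- c(ups, ci)
  }
  ups <- sort(ups)

  # foot: peak of second derivative in a window before each upstroke peak
  back <- max(3L, as.integer(round(min(0.2, min_period / 2) / dt)))
  feet <- vapply(ups, function(u) {
    lo <- max(1L, u - back)
    lo + which.max(d2p[lo:u]) - 1L
  }, integer(1))
  feet <- sort(unique(feet))
  # merge feet closer than min_period (beats too short to be real)
  if (length(feet) > 1L) {
    keep <- feet[1]
    for (f in feet[-1])
      if ((f - keep[length(keep)]) * dt >= min_period) keep <- c(keep, f)
    feet <- keep
  }
  if (length(feet) == 0L) stop("no beats found")

  bounds <- c(feet, n + 1L)
  out <- vector("list", length(feet))
  for (k in seq_along(feet)) {
    from <- bounds[k]; to <- bounds[k + 1L] - 1L
    ps <- series_window(p, from, to)
    fs <- if (!is.null(flow)) series_window(flow, from, to) else NULL
    out[[k]] <- beat_segment(ps, flow = fs, i_foot = 1L)
  }
  out
}
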
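#' One cardiac cycle of pressure, optionally with flow
#'
#' A beat segment holds the pressure trace of a single cardiac cycle together
#' with its fiducial sample indices: the foot (onset of the systolic
#' upstroke) and end-systole. Flow, when present, must share the pressure
#' grid sample-for-sample.
#'
#' Indices are 1-based inside R; machine-readable CLI output reports them
#' 0-based.
#'
#' @param pressure A [uniform_series()] with quantity `"pressure"`.
#' @param flow Optional [uniform_series()] with quantity `"flow_volumetric"`
#'   or `"flow_velocity"`, same `dt` and length as `pressure`.
#' @param i_foot Sample index of the beat foot (default 1).
#' @param i_es Sample index of end-systole, or `NA` if not yet detected (see
#'   [detect_end_systole()]).
#'
#' @return An object of class `beat_segment` with fields `pressure`, `flow`,
#'   `i_foot`, `i_es` and `duration` (seconds).
#' @export
beat_segment <- function(pressure, flow = NULL, i_foot = 1L, i_es = NA_integer_) {
  stopifnot(inherits(pressure, "uniform_series"))
  if (pressure$quantity != "pressure")
    stop("`pressure` must have quantity \"pressure\"")
  n <- length(pressure$values)
  i_foot <- as.integer(i_foot)
  if (i_foot < 1L || i_foot >= n)
    stop("`i_foot` out of range")
  if (!is.na(i_es)) {
    i_es <- as.integer(i_es)
    if (i_es <= i_foot || i_es > n)
      stop("need i_foot < i_es <= number of samples")
  }
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "uniform_series"))
    if (!flow$quantity %in% c("flow_volumetric", "flow_velocity"))
      stop("`flow` must be a flow series")
    if (length(flow$values) != n || abs(flow$dt - pressure$dt) > 1e-12)
      stop("flow must share the pressure time grid")
  }
  structure(list(pressure = pressure, flow = flow,
                 i_foot = i_foot, i_es = as.integer(i_es),
                 duration = n * pressure$dt),
            class = "beat_segment")
}

#' @export
print.beat_segment <- function(x, ...) {
  cat(sprintf("<beat_segment> %d samples (%.3f s), foot @ %d, end-systole @ %s%s\n",
              length(x$pressure$values), x$duration, x$i_foot,
              ifelse(is.na(x$i_es), "?", as.character(x$i_es)),
              if (is.null(x$flow)) "" else ", with flow"))
  invisible(x)
}

# time of each sample relative to the beat foot (s)
.foot_time <- function(beat) {
  (seq_along(beat$pressure$values) - beat$i_foot) * beat$pressure$dt
}
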
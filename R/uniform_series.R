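#' Uniformly sampled physiological signal
#'
#' Container for an evenly sampled pressure or flow trace. All analysis
#' functions in the package assume uniform sampling; irregularly timed input
#' should be resampled first (see [read_waveform()], which does this
#' automatically).
#'
#' @param values Numeric vector of samples. Pressure is in mmHg, volumetric
#'   flow in mL/s, flow velocity in m/s.
#' @param dt Sampling interval in seconds; must be positive and finite.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param quantity One of `"pressure"`, `"flow_volumetric"`, `"flow_velocity"`.
#'   The quantity fixes the units and guards against mixing incompatible
#'   signals in arithmetic.
#'
#' @return An object of class `uniform_series`.
#' @examples
#' p <- uniform_series(100 + 10 * sin(seq(0, 2 * pi, length.out = 100)),
#'                     dt = 0.01)
#' series_time(p)[1:5]
#' @export
uniform_series <- function(values, dt, t0 = 0,
                           quantity = c("pressure", "flow_volumetric",
                                        "flow_velocity")) {
  quantity <- match.arg(quantity)
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive finite number")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number")
  if (length(values) < 2L)
    stop("a uniform series needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("all samples must be finite")
  structure(list(t0 = t0, dt = dt, values = values, quantity = quantity),
            class = "uniform_series")
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Sample times of a uniform series
#'
#' @param x A [uniform_series()].
#' @return Numeric vector `t0 + (0:(n-1)) * dt`.
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
print.uniform_series <- function(x, ...) {
  unit <- switch(x$quantity,
                 pressure = "mmHg",
                 flow_volumetric = "mL/s",
                 flow_velocity = "m/s")
  cat(sprintf("<uniform_series> %s, %d samples @ %g Hz, t0 = %g s\n",
              x$quantity, length(x$values), 1 / x$dt, x$t0))
  cat(sprintf("  range %.3f to %.3f %s\n",
              min(x$values), max(x$values), unit))
  invisible(x)
}

# Arithmetic between series requires matching quantity and grid; a series
# combined with a plain scalar keeps its quantity.
#' @export
Ops.uniform_series <- function(e1, e2) {
  if (!missing(e2) && inherits(e1, "uniform_series") &&
      inherits(e2, "uniform_series")) {
    if (e1$quantity != e2$quantity)
      stop("cannot mix quantities in arithmetic: ",
           e1$quantity, " vs ", e2$quantity)
    if (length(e1$values) != length(e2$values) ||
        abs(e1$dt - e2$dt) > 1e-12)
      stop("series are not on the same time grid")
    out <- get(.Generic)(e1$values, e2$values)
    base <- e1
  } else if (inherits(e1, "uniform_series")) {
    out <- get(.Generic)(e1$values, e2)
    base <- e1
  } else {
    out <- get(.Generic)(e1, e2$values)
    base <- e2
  }
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) return(out)
  base$values <- out
  base
}

#' Subset a uniform series by sample index
#'
#' Extracts a contiguous run of samples, adjusting the time offset so that
#' absolute sample times are preserved.
#'
#' @param x A [uniform_series()].
#' @param from,to First and last sample index (1-based, inclusive).
#' @return A `uniform_series`.
#' @export
series_window <- function(x, from, to) {
  stopifnot(inherits(x, "uniform_series"))
  n <- length(x$values)
  if (from < 1L || to > n || from >= to)
    stop("invalid sample window [", from, ", ", to, "]")
  uniform_series(x$values[from:to], dt = x$dt,
                 t0 = x$t0 + (from - 1) * x$dt, quantity = x$quantity)
}

#' Add reproducible Gaussian measurement noise to a series
#'
#' Used by the simulators so that every fit test has a single, seedable
#' source of randomness. When `seed` is given the global RNG state is saved
#' and restored, so calling this function does not perturb an enclosing
#' simulation.
#'
#' @param x A [uniform_series()].
#' @param sd Noise standard deviation in the units of `x`.
#' @param seed Optional integer seed.
#' @return A `uniform_series` with noise added.
#' @export
add_gaussian_noise <- function(x, sd, seed = NULL) {
  stopifnot(inherits(x, "uniform_series"), sd >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  x$values <- x$values + stats::rnorm(length(x$values), 0, sd)
  x
}
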
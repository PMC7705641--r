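# Synthetic-data generators: half-sine aortic inflow and two-/three-element
# Windkessel pressures. These provide analytic ground truth (true R, C, Z_c,
# P_zf and the true end-systole time) for every fitting routine.

# Exact one-step integrator for x' = -rate * x + forcing(t) with the forcing
# piecewise-linear between samples (product integration against the
# exponential kernel). Exact for piecewise-linear forcing; second-order for
# smooth forcing. rate = 0 degenerates to the trapezoid rule.
#
# Returns the full solution series including x0.
.exp_step_series <- function(x0, rate, forcing, dt) {
  n <- length(forcing)
  if (rate > 0) {
    E <- exp(-rate * dt)
    g1 <- (1 - E) / rate        # int_0^h e^{-rate (h-s)} ds
    g2 <- (dt - g1) / rate      # int_0^h s e^{-rate (h-s)} ds
  } else {
    E <- 1
    g1 <- dt
    g2 <- dt^2 / 2
  }
  f0 <- forcing[-n]
  m <- (forcing[-1] - f0) / dt
  b <- f0 * g1 + m * g2
  x <- stats::filter(b, E, method = "recursive", init = x0)
  c(x0, as.numeric(x))
}

#' Half-sine systolic inflow
#'
#' Canonical test inflow: within each beat,
#' \eqn{Q_{in}(t) = Q_{pk} \sin(\pi t / T_{sys})} for \eqn{0 \le t \le
#' T_{sys}} and zero through the rest of the cycle, with
#' \eqn{Q_{pk} = \pi \cdot SV / (2 T_{sys})} so that each beat ejects
#' exactly the stroke volume. The end of inflow defines the true
#' end-systole time used by the fiducial tests.
#'
#' @param SV Stroke volume per beat (mL), default 70.
#' @param T_sys Systolic (ejection) duration in seconds, default 0.3.
#' @param T_beat Beat period in seconds, default 1.
#' @param n_beats Number of beats, default 1.
#' @param dt Sampling interval in seconds, default 1 ms.
#' @return A flow [uniform_series()] covering `[0, n_beats * T_beat]`
#'   inclusive of both endpoints.
#' @export
half_sine_inflow <- function(SV = 70, T_sys = 0.3, T_beat = 1,
                             n_beats = 1, dt = 1e-3) {
  stopifnot(SV > 0, T_sys > 0, T_sys < T_beat, n_beats >= 1, dt > 0)
  n <- as.integer(round(n_beats * T_beat / dt)) + 1L
  t <- (seq_len(n) - 1) * dt
  tmod <- t - T_beat * floor(t / T_beat + 1e-9)
  Qpk <- pi * SV / (2 * T_sys)
  q <- ifelse(tmod <= T_sys + 1e-12, Qpk * sin(pi * pmin(tmod, T_sys) / T_sys), 0)
  uniform_series(q, dt = dt, quantity = "flow_volumetric")
}

#' Windkessel simulator parameters
#'
#' @param R Total peripheral resistance (mmHg·s/mL), default 1.2.
#' @param C Total arterial compliance (mL/mmHg), default 1.4.
#' @param Z_c Characteristic impedance (mmHg·s/mL); 0 gives the
#'   two-element model, default 0.
#' @param P_zf Zero-flow (asymptotic) pressure in mmHg, default 20.
#' @param P0 Initial pressure in mmHg, default 80.
#' @return A list of class `windkessel_spec`.
#' @export
windkessel_spec <- function(R = 1.2, C = 1.4, Z_c = 0, P_zf = 20, P0 = 80) {
  stopifnot(R > 0, C > 0, Z_c >= 0)
  structure(list(R = R, C = C, Z_c = Z_c, P_zf = P_zf, P0 = P0),
            class = "windkessel_spec")
}

#' Simulate a two- or three-element Windkessel pressure
#'
#' Integrates \eqn{C\,dP_{wk}/dt = Q_{in} - (P_{wk} - P_{zf})/R} with an
#' exponential-integrator step that is exact per sample for piecewise-linear
#' inflow, then returns the measured pressure \eqn{P = P_{wk} + Z_c Q_{in}}.
#' With `Z_c = 0` this is the classical two-element Windkessel.
#'
#' @param inflow Volumetric flow [uniform_series()] (mL/s).
#' @param spec A [windkessel_spec()].
#' @return A list of class `wk_sim` with elements `pressure` (measured, =
#'   `p_wk` + `Z_c * Q`), `p_wk` (compartment pressure), `inflow`, and
#'   `spec`.
#' @examples
#' sim <- simulate_windkessel(half_sine_inflow(n_beats = 10),
#'                            windkessel_spec())
#' mean(sim$pressure$values)  # approaches P_zf + R * mean(Q)
#' @export
simulate_windkessel <- function(inflow, spec = windkessel_spec()) {
  stopifnot(inherits(inflow, "uniform_series"),
            inherits(spec, "windkessel_spec"))
  if (inflow$quantity != "flow_volumetric")
    stop("`inflow` must be volumetric flow (mL/s)")
  q <- inflow$values
  x <- .exp_step_series(spec$P0 - spec$P_zf, rate = 1 / (spec$R * spec$C),
                        forcing = q / spec$C, dt = inflow$dt)
  pwk <- uniform_series(spec$P_zf + x, dt = inflow$dt, t0 = inflow$t0,
                        quantity = "pressure")
  p <- pwk
  p$values <- pwk$values + spec$Z_c * q
  structure(list(pressure = p, p_wk = pwk, inflow = inflow, spec = spec),
            class = "wk_sim")
}

#' Extract one steady-state beat from a multi-beat Windkessel simulation
#'
#' Convenience used throughout the tests: simulates `n_beats` beats and
#' returns the final full beat as an annotated [beat_segment()] (foot at the
#' first sample, end-systole at the known end of inflow), together with the
#' ground-truth parameters.
#'
#' @param spec A [windkessel_spec()].
#' @param SV,T_sys,T_beat,n_beats,dt Passed to [half_sine_inflow()];
#'   `n_beats` defaults to 12 so the final beat is in periodic steady state.
#' @return List with `beat` (a [beat_segment()] with flow), `truth` (list of
#'   true parameter values, incl. `k_d`, `k_s`, `t_es`), and `sim`.
#' @export
steady_state_beat <- function(spec = windkessel_spec(), SV = 70, T_sys = 0.3,
                              T_beat = 1, n_beats = 12, dt = 1e-3) {
  q <- half_sine_inflow(SV = SV, T_sys = T_sys, T_beat = T_beat,
                        n_beats = n_beats, dt = dt)
  sim <- simulate_windkessel(q, spec)
  i0 <- as.integer(round((n_beats - 1) * T_beat / dt)) + 1L
  i1 <- length(sim$pressure$values)
  beat <- beat_segment(series_window(sim$pressure, i0, i1),
                       flow = series_window(sim$inflow, i0, i1),
                       i_foot = 1L,
                       i_es = as.integer(round(T_sys / dt)) + 1L)
  truth <- list(R = spec$R, C = spec$C, Z_c = spec$Z_c, P_zf = spec$P_zf,
                k_d = 1 / (spec$R * spec$C),
                k_s = if (spec$Z_c > 0) 1 / (spec$Z_c * spec$C) else Inf,
                t_es = T_sys, SV = SV)
  list(beat = beat, truth = truth, sim = sim)
}
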
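# Shared fixtures: all synthetic, generated in code at test time.

# steady-state three-element beat with known ground truth
wk3_beat <- function(R = 1.2, C = 1.4, Z_c = 0.05, P_zf = 20, ...) {
  steady_state_beat(windkessel_spec(R = R, C = C, Z_c = Z_c, P_zf = P_zf),
                    ...)
}

# pure mono-exponential "diastole" beat: P(t) = P_inf + (P_es-P_inf) e^{-kd t}
# for t >= 0; one pre-decay sample is prepended so end-systole (sample 2)
# sits exactly at t = 0 where P = P_es
exp_decay_beat <- function(P_inf = 30, P_es = 90, kd = 1 / 1.5,
                           dur = 0.7, dt = 1e-3) {
  t <- seq(-dt, dur, by = dt)
  p <- uniform_series(P_inf + (P_es - P_inf) * exp(-kd * pmax(t, 0)),
                      dt = dt)
  beat_segment(p, i_foot = 1L, i_es = 2L)
}

# symmetric 3-vessel tree; scaling L by f and A by 1/f scales every transit
# time by f while leaving each compliance unchanged
sym_tree <- function(scale = 1) {
  reservoir_network(data.frame(
    id = c(1, 2, 3), parent = c(NA, 1, 1),
    L = c(0.2, 0.2, 0.2) * scale, A = c(5e-4, 2.5e-4, 2.5e-4) / scale,
    v = 5, rho = 1050, R_term = c(NA, 2.4, 2.4)))
}

# cumulative trapezoid
ctrapz <- function(v, dt) dt * (cumsum(v) - (v + v[1]) / 2)

two_studies <- data.frame(label = c("a", "b"), n = c(10, 10),
                          y = c(10, 14), se = c(1, 1))
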
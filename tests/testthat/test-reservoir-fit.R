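# Reservoir/excess decomposition: diastolic fit, R-C estimation, both
# solution algorithms, k_s search, indices.

test_that("diastolic fit recovers an exact mono-exponential", {
  b <- exp_decay_beat(P_inf = 30, P_es = 90, kd = 1 / 1.5)
  f <- fit_diastolic_decay(b, window = c(0.001, 0.7))
  expect_equal(f$k_d, 1 / 1.5, tolerance = 1e-6)
  expect_equal(f$P_inf, 30, tolerance = 1e-6)
  expect_equal(f$P_es, 90, tolerance = 1e-6)
  expect_lt(f$rmse, 1e-6)
  expect_false(f$implausible_P_inf)
})

test_that("diastolic fit is unbiased under measurement noise", {
  kd_hat <- numeric(100); pinf_hat <- numeric(100)
  for (s in 1:100) {
    b <- exp_decay_beat()
    b$pressure <- add_gaussian_noise(b$pressure, 0.5, seed = s)
    f <- fit_diastolic_decay(b, window = c(0.001, 0.7))
    kd_hat[s] <- f$k_d; pinf_hat[s] <- f$P_inf
  }
  expect_lt(abs(mean(kd_hat) - 1 / 1.5) / (1 / 1.5), 0.05)
  expect_lt(abs(mean(pinf_hat) - 30), 2)
  # individual fits stay in a sane band too
  expect_gt(mean(abs(kd_hat - 1 / 1.5) / (1 / 1.5) < 0.15), 0.9)
})

test_that("diastolic fit fails cleanly on constant pressure", {
  b <- beat_segment(uniform_series(rep(80, 800), dt = 1e-3),
                    i_foot = 1L, i_es = 2L)
  expect_error(fit_diastolic_decay(b, window = c(0.01, 0.7)),
               "diastolic fit failed")
})

test_that("an implausible asymptote is flagged, not clipped", {
  b <- exp_decay_beat(P_inf = 30, P_es = 90)
  # forcing the asymptote to sit above the window minimum must flag it
  expect_warning(
    f <- fit_diastolic_decay(b, window = c(0.001, 0.7),
                             P_inf_fixed = min(b$pressure$values) + 5),
    "implausible")
  expect_true(f$implausible_P_inf)
  expect_equal(f$P_inf, min(b$pressure$values) + 5)  # reported as-is
})

test_that("R and C follow from mean pressure and the decay constant", {
  p <- uniform_series(rep(100, 500), dt = 1e-3)
  q <- uniform_series(rep(70, 500), dt = 1e-3, quantity = "flow_volumetric")
  b <- beat_segment(p, flow = q, i_foot = 1L, i_es = 2L)
  f <- structure(list(k_d = 1 / 1.5, P_inf = 30), class = "diastolic_fit")
  rc <- estimate_rc(b, f)
  expect_equal(rc$R, 1.0)
  expect_equal(rc$C, 1.5)
  f$P_inf <- 120
  expect_error(estimate_rc(b, f), "nonpositive resistance")
})

test_that("two-element simulation returns R within 1% and C within 2%", {
  ss <- wk3_beat(R = 1.2, C = 1.4, Z_c = 0, P_zf = 20)
  f <- fit_diastolic_decay(ss$beat)
  rc <- estimate_rc(ss$beat, f)
  expect_lt(abs(rc$R - 1.2) / 1.2, 0.01)
  expect_lt(abs(rc$C - 1.4) / 1.4, 0.02)
})

test_that("velocity input rescales R and C but not their product", {
  ss <- wk3_beat(Z_c = 0)
  b <- ss$beat
  f <- fit_diastolic_decay(b)
  rc_vol <- estimate_rc(b, f)
  # same waveform as velocity over a 4 cm^2 aorta: Q[mL/s] = 4e2 * v[m/s]... area scaling only
  area <- 400
  bv <- b
  bv$flow$values <- b$flow$values / area
  bv$flow$quantity <- "flow_velocity"
  rc_vel <- estimate_rc(bv, f)
  expect_equal(rc_vel$R, rc_vol$R * area, tolerance = 1e-12)
  expect_equal(rc_vel$C, rc_vol$C / area, tolerance = 1e-12)
  expect_equal(rc_vel$R * rc_vel$C, rc_vol$R * rc_vol$C, tolerance = 1e-12)
})

test_that("zero-inflow reservoir follows the mono-exponential closed form", {
  n <- 1501
  q <- uniform_series(rep(0, n), dt = 1e-3, quantity = "flow_volumetric")
  p <- uniform_series(rep(90, n), dt = 1e-3)
  b <- beat_segment(p, flow = q)
  r <- compute_pres_pq(b, R = 1.5, C = 1, P_zf = 30, P_res0 = 90)
  expect_equal(r$P_res$values[n], 30 + 60 * exp(-1), tolerance = 1e-6)
  # whole trajectory, not just the endpoint
  t <- series_time(p)
  expect_equal(r$P_res$values, 30 + 60 * exp(-t / 1.5), tolerance = 1e-9)
})

test_that("reservoir equals pressure on two-element Windkessel data", {
  q <- half_sine_inflow(n_beats = 10)
  sim <- simulate_windkessel(q, windkessel_spec(R = 1.2, C = 1.4, Z_c = 0,
                                                P_zf = 20))
  b <- beat_segment(sim$pressure, flow = q)
  r <- compute_pres_pq(b, R = 1.2, C = 1.4, P_zf = 20)
  pp <- diff(range(sim$pressure$values))
  expect_lt(max(abs(r$P_res$values - sim$pressure$values)), 1e-6 * pp)
  expect_lt(max(abs(r$P_xs$values)), 1e-6 * pp)
})

test_that("excess pressure equals Z_c * Q_in on three-element data", {
  ss <- wk3_beat(Z_c = 0.05)
  r <- compute_pres_pq(ss$beat, R = 1.2, C = 1.4, P_zf = 20)
  pxs_true <- 0.05 * ss$beat$flow$values
  expect_lt(max(abs(r$P_xs$values - pxs_true)) / max(pxs_true), 0.005)
  expect_equal(r$indices$int_pxs, 0.05 * 70, tolerance = 0.005)
  expect_equal(r$indices$peak_pxs, 0.05 * pi * 70 / 0.6, tolerance = 1e-3)
})

test_that("additivity P_res + P_xs = P holds to machine precision", {
  ss <- wk3_beat()
  for (r in list(compute_pres_pq(ss$beat, 1.2, 1.4, 20),
                 compute_pres_p(ss$beat, 14.3, 0.595, 20))) {
    expect_equal(r$P_res$values + r$P_xs$values,
                 ss$beat$pressure$values, tolerance = 1e-14)
  }
})

test_that("pressure-only solution honours its fixed point and limits", {
  p <- uniform_series(rep(50, 600), dt = 1e-3)
  b <- beat_segment(p)
  r <- compute_pres_p(b, k_s = 3, k_d = 0.6, P_zf = 50, P_res0 = 50)
  expect_equal(r$P_res$values, rep(50, 600), tolerance = 1e-12)

  ss <- wk3_beat()
  big <- compute_pres_p(ss$beat, k_s = 1e6, k_d = 0.595, P_zf = 20)
  expect_lt(max(abs(big$P_res$values - ss$beat$pressure$values)), 0.05)
})

test_that("pressure-only and pressure+flow solutions agree on matched data", {
  ss <- wk3_beat(Z_c = 0.05)
  rq <- compute_pres_pq(ss$beat, R = 1.2, C = 1.4, P_zf = 20)
  rp <- compute_pres_p(ss$beat, k_s = 1 / (0.05 * 1.4), k_d = 1 / (1.2 * 1.4),
                       P_zf = 20)
  pp <- diff(range(ss$beat$pressure$values))
  expect_lt(max(abs(rq$P_res$values - rp$P_res$values)), 0.02 * pp)
  expect_lt(abs(max(rq$P_res$values) - max(rp$P_res$values)), 2)
})

test_that("k_s recovery, scale invariance, and grid-search oracle", {
  ss <- wk3_beat(Z_c = 0.05)
  b <- ss$beat
  f <- fit_diastolic_decay(b)
  ks <- fit_ks(b, k_d = f$k_d, P_zf = f$P_inf)
  expect_lt(abs(ks - ss$truth$k_s) / ss$truth$k_s, 0.05)

  # doubling all pressures (and P_zf) leaves the minimiser unchanged
  b2 <- b
  b2$pressure$values <- 2 * b$pressure$values
  ks2 <- fit_ks(b2, k_d = f$k_d, P_zf = 2 * f$P_inf)
  expect_equal(ks2, ks, tolerance = 1e-4)

  # brute-force oracle: same first-local-minimum rule on a fine log grid
  d <- artres:::.diastolic_idx(b, NULL, 0.03, 0.03)
  pv <- b$pressure$values
  obj <- function(ks) {
    r <- compute_pres_p(b, ks, f$k_d, f$P_inf)
    sum((pv[d$idx] - r$P_res$values[d$idx])^2)
  }
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 10000))
  vals <- vapply(grid, obj, numeric(1))
  interior <- 2:(length(grid) - 1)
  lm1 <- interior[vals[interior] <= vals[interior - 1] &
                  vals[interior] <= vals[interior + 1]][1]
  spacing <- grid[lm1 + 1] - grid[lm1 - 1]
  expect_lt(abs(ks - grid[lm1]), spacing)
})

test_that("summary indices behave as offsets and integrals should", {
  ss <- wk3_beat(Z_c = 0.05)
  r <- compute_pres_pq(ss$beat, 1.2, 1.4, 20)
  P_d <- ss$beat$pressure$values[1]

  # P_res == P_d, P_xs == 0 gives all-zero indices
  flatr <- r
  flatr$P_res$values <- rep(P_d, length(r$P_res$values))
  flatr$P_xs$values <- rep(0, length(r$P_xs$values))
  idx0 <- reservoir_indices(flatr, P_d)
  expect_equal(unname(unlist(idx0)), rep(0, 4))

  # adding a constant to both P and P_res leaves every index unchanged
  shifted <- r
  shifted$beat$pressure$values <- shifted$beat$pressure$values + 11
  shifted$P_res$values <- shifted$P_res$values + 11
  i1 <- reservoir_indices(r, P_d)
  i2 <- reservoir_indices(shifted, P_d + 11)
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("quadrature error drops ~4x when dt is halved", {
  ref <- wk3_beat(Z_c = 0, dt = 1.25e-4, n_beats = 3)
  errs <- vapply(c(1e-3, 5e-4), function(dt) {
    ss <- wk3_beat(Z_c = 0, dt = dt, n_beats = 3)
    # compare simulated (exact-for-linear-inflow) pressure against the
    # fine-dt reference at shared sample times
    step <- as.integer(round(dt / 1.25e-4))
    fine <- ref$sim$pressure$values[seq(1, length(ref$sim$pressure$values),
                                        by = step)]
    max(abs(ss$sim$pressure$values - fine))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3)
  expect_lt(errs[1] / errs[2], 6)
})

test_that("derived rate constants satisfy their identities exactly", {
  ss <- wk3_beat()
  r <- compute_pres_pq(ss$beat, R = 1.2, C = 1.4, P_zf = 20)
  expect_equal(r$params$k_d, 1 / (1.2 * 1.4), tolerance = 1e-12)
  rp <- reservoir_p(ss$beat)
  expect_true(is.na(rp$params$R))  # no flow used, no volumetric units
  expect_gt(rp$params$k_s, 0)
})

test_that("end-to-end pipelines run and record the P_zf mode", {
  ss <- wk3_beat()
  rq <- reservoir_pq(ss$beat)
  expect_equal(rq$params$pzf_mode, "fit")
  expect_equal(rq$fit$P_inf, 20, tolerance = 0.01)
  rfix <- reservoir_p(ss$beat, pzf_mode = "fixed", pzf = 0)
  expect_equal(rfix$params$P_zf, 0)
  expect_equal(rfix$params$pzf_mode, "fixed")
  expect_error(reservoir_p(ss$beat, pzf_mode = "fixed"), "needs a `pzf`")
})
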
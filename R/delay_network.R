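# Time-delay network reservoir.
#
# The reservoir is a rooted tree of vessel segments. The pressure in vessel
# n is the root reservoir pressure delayed by the wave transit time tau(n),
# so mass conservation collapses to a scalar delay-differential equation for
# the root history:
#
#   Q_in(t) - sum_n C_n P'(t - tau(n)) - sum_k (P(t - tau(k)) - P_zf)/R_k = 0
#
# solved by the method of steps: zero-delay terms (the root compliance, and
# any zero-delay terminal conductance) are advanced with the exact
# exponential-integrator step, delayed terms are read from the stored
# solution history with linear interpolation and treated as piecewise-linear
# forcing. With a single vessel and tau = 0 the scheme degenerates,
# arithmetic included, to the lumped Windkessel integrator.

MMHG_PA <- 133.322  # pascals per mmHg

#' Compliance of a uniform vessel segment
#'
#' \eqn{C_n = L A / (\rho v^2)}, converted from SI (m^3/Pa) to mL/mmHg.
#'
#' @param L Segment length (m).
#' @param A Cross-sectional area (m^2).
#' @param v Wave speed (m/s).
#' @param rho Blood density (kg/m^3), default 1050.
#' @return Compliance in mL/mmHg.
#' @examples
#' vessel_compliance(0.1, 5e-4, 5)  # 0.2539 mL/mmHg
#' @export
vessel_compliance <- function(L, A, v, rho = 1050) {
  stopifnot(all(L > 0), all(A > 0), all(v > 0), all(rho > 0))
  L * A / (rho * v^2) * MMHG_PA * 1e6
}

#' Build a branching reservoir network
#'
#' Vessels are given as a data frame with one row per segment: `id`,
#' `parent` (`NA` for the root), geometry `L` (m), `A` (m^2), wave speed `v`
#' (m/s), optional density `rho` (kg/m^3, default 1050), and `R_term`
#' (terminal resistance in mmHg·s/mL at leaves, `NA` elsewhere). Compliance
#' `C_n` and the per-segment transit contribution `tau_n = L/v` are always
#' recomputed from these primitives. The cumulative delay `tau` of a vessel
#' is the transit time from the root to its entrance (sum of ancestor
#' `tau_n`), so `tau(root) = 0`; a terminal resistance inherits the delay of
#' its vessel.
#'
#' @param vessels Data frame as described above.
#' @param max_transit Budget for the largest distal transit time
#'   (`tau + tau_n`) in seconds; default 0.08 (the measured aorto-iliac
#'   transit time in humans is below 80 ms).
#' @return Object of class `reservoir_network` with per-vessel `C_n`,
#'   `tau_n`, `tau`, plus totals `C_total` and `R_total`
#'   (\eqn{1/R_{tot} = \sum_k 1/R_k}).
#' @export
reservoir_network <- function(vessels, max_transit = 0.08) {
  req <- c("id", "parent", "L", "A", "v")
  if (!all(req %in% names(vessels)))
    stop("`vessels` needs columns ", paste(req, collapse = ", "))
  if (is.null(vessels$rho)) vessels$rho <- 1050
  if (is.null(vessels$R_term)) vessels$R_term <- NA_real_
  n <- nrow(vessels)
  root <- which(is.na(vessels$parent))
  if (length(root) != 1L) stop("network must have exactly one root")
  idx <- match(vessels$parent, vessels$id)
  if (any(is.na(idx[-root]))) stop("unknown parent id")

  vessels$C_n <- vessel_compliance(vessels$L, vessels$A, vessels$v,
                                   vessels$rho)
  vessels$tau_n <- vessels$L / vessels$v
  # cumulative delay to vessel entrance; tree so depth is finite
  tau <- rep(NA_real_, n)
  tau[root] <- 0
  remaining <- setdiff(seq_len(n), root)
  guard <- 0L
  while (length(remaining) > 0L) {
    ready <- remaining[!is.na(tau[idx[remaining]])]
    if (length(ready) == 0L) stop("parent links do not form a rooted tree")
    tau[ready] <- tau[idx[ready]] + vessels$tau_n[idx[ready]]
    remaining <- setdiff(remaining, ready)
    guard <- guard + 1L
    if (guard > n) stop("parent links do not form a rooted tree")
  }
  vessels$tau <- tau

  is_leaf <- !(vessels$id %in% vessels$parent)
  if (any(is_leaf & (is.na(vessels$R_term) | vessels$R_term <= 0)))
    stop("every leaf needs a positive terminal resistance R_term")
  if (max(vessels$tau + vessels$tau_n) > max_transit)
    stop(sprintf("distal transit time %.1f ms exceeds the %.0f ms budget",
                 1000 * max(vessels$tau + vessels$tau_n), 1000 * max_transit))

  structure(list(vessels = vessels,
                 root = root,
                 leaves = which(is_leaf),
                 C_total = sum(vessels$C_n),
                 R_total = 1 / sum(1 / vessels$R_term[is_leaf])),
            class = "reservoir_network")
}

#' @export
print.reservoir_network <- function(x, ...) {
  cat(sprintf("<reservoir_network> %d vessels, %d termini, C_total = %.3f mL/mmHg, R_total = %.3f mmHg.s/mL, max distal transit %.1f ms\n",
              nrow(x$vessels), length(x$leaves), x$C_total, x$R_total,
              1000 * max(x$vessels$tau + x$vessels$tau_n)))
  invisible(x)
}

# linear interpolation into the solution history; constant value before t0
.hist_read <- function(vals, tq, dt, before) {
  if (tq <= 0) return(before)
  j <- floor(tq / dt)
  w <- tq / dt - j
  j <- as.integer(j) + 1L  # 1-based index of the sample at or before tq
  if (j >= length(vals)) return(vals[length(vals)])
  (1 - w) * vals[j] + w * vals[j + 1L]
}

#' Solve the delayed-reservoir network equation
#'
#' Integrates the scalar delay equation for the root reservoir pressure by
#' the method of steps, with the solution history initialised at the
#' constant `P_init` for \eqn{t \le 0}. Per-vessel pressures are the root
#' solution shifted by each vessel's transit delay; the total outflow is
#' \eqn{Q_{out}(t) = \sum_k (P(t - \tau(k)) - P_{zf}) / R_k}.
#'
#' @param net A [reservoir_network()].
#' @param inflow Volumetric inflow [uniform_series()]; its `dt` must resolve
#'   the delays (`dt` at most a quarter of the smallest positive delay).
#' @param P_zf Zero-flow pressure (mmHg).
#' @param P_init Constant history pressure (mmHg).
#' @return List of class `delay_sim`: `root` (root reservoir pressure
#'   [uniform_series()]), `vessel_pressure` (matrix, one column per vessel,
#'   delayed per Eq.-of-state), `Q_out` (flow [uniform_series()]), `net`.
#' @export
simulate_delay_network <- function(net, inflow, P_zf = 20, P_init = 80) {
  stopifnot(inherits(net, "reservoir_network"),
            inherits(inflow, "uniform_series"))
  if (inflow$quantity != "flow_volumetric")
    stop("`inflow` must be volumetric flow")
  v <- net$vessels
  dt <- inflow$dt
  pos <- v$tau[v$tau > 0]
  tauR <- v$tau[net$leaves]
  posR <- tauR[tauR > 0]
  mind <- suppressWarnings(min(c(pos, posR)))
  if (is.finite(mind) && dt > mind / 4)
    stop(sprintf("refine dt: dt = %g s but the smallest delay is %g s", dt, mind))

  q <- inflow$values
  n <- length(q)
  C0 <- sum(v$C_n[v$tau == 0])          # zero-delay compliance (incl. root)
  Rk <- v$R_term[net$leaves]
  G0 <- sum(1 / Rk[tauR == 0])          # zero-delay terminal conductance
  dC <- which(v$tau > 0)                # delayed compliance terms
  dR <- which(tauR > 0)                 # delayed resistance terms
  rate <- G0 / C0
  if (rate > 0) {
    E <- exp(-rate * dt); g1 <- (1 - E) / rate; g2 <- (dt - g1) / rate
  } else {
    E <- 1; g1 <- dt; g2 <- dt^2 / 2
  }

  P <- numeric(n); dP <- numeric(n)
  P[1] <- P_init
  forcing_at <- function(i, t) {
    f <- q[i]
    for (j in dC)
      f <- f - v$C_n[j] * .hist_read(dP, t - v$tau[j], dt, 0)
    for (j in seq_along(dR)) {
      k <- dR[j]
      f <- f - (.hist_read(P, t - posR[j], dt, P_init) - P_zf) / Rk[k]
    }
    f
  }
  F_i <- forcing_at(1L, 0)
  dP[1] <- (F_i - G0 * (P[1] - P_zf)) / C0
  for (i in seq_len(n - 1L)) {
    F_n <- forcing_at(i + 1L, i * dt)
    x <- P[i] - P_zf
    m <- (F_n - F_i) / dt
    P[i + 1L] <- P_zf + E * x + (F_i * g1 + m * g2) / C0
    dP[i + 1L] <- (F_n - G0 * (P[i + 1L] - P_zf)) / C0
    F_i <- F_n
  }

  tgrid <- (seq_len(n) - 1) * dt
  vp <- vapply(seq_len(nrow(v)), function(j) {
    if (v$tau[j] == 0) return(P)
    vapply(tgrid, function(t) .hist_read(P, t - v$tau[j], dt, P_init),
           numeric(1))
  }, numeric(n))
  colnames(vp) <- as.character(v$id)
  qout <- rowSums(vapply(seq_along(net$leaves), function(j) {
    tauj <- tauR[j]
    if (tauj == 0) (P - P_zf) / Rk[j]
    else vapply(tgrid, function(t)
      (.hist_read(P, t - tauj, dt, P_init) - P_zf) / Rk[j], numeric(1))
  }, numeric(n)))

  structure(list(root = uniform_series(P, dt = dt, t0 = inflow$t0,
                                       quantity = "pressure"),
                 vessel_pressure = vp,
                 Q_out = uniform_series(qout, dt = dt, t0 = inflow$t0,
                                        quantity = "flow_volumetric"),
                 P_zf = P_zf, P_init = P_init, net = net),
            class = "delay_sim")
}
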
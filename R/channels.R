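# Membrane mechanisms of the Destexhe model family, as pure functions of
# voltage, gate state, and intracellular calcium. The same functional forms
# (and the same constants, via kin_vector()) drive the compiled integrator.
#
# Sign convention for the T-type window shift: a positive `vshift` moves the
# window current toward more negative voltages; gates are evaluated at
# (v + vshift).

FARADAY <- 96485.332
GAS_CONSTANT <- 8.314462

#' Default membrane mechanism constants
#'
#' Returns the full kinetic configuration of the mechanism family used by the
#' cell models: fast Na/K spiking currents (Traub-style `hh2`), the generic
#' T-type calcium current `IT` (m^2 h, calcium reversal from the Nernst
#' equation) with a window-current voltage-shift parameter, the SK-type
#' calcium-activated potassium current `IAHP` (m^2, calcium-gated), the
#' calcium-activated nonselective cation current `ICAN` (m^2, calcium-gated),
#' the A-type transient potassium current `IA` (m^4 h), first-order calcium
#' dynamics `cad` (150 ms decay), and the passive leak (`e_pas = -70` mV).
#' Every rate constant is exposed here and may be overridden.
#'
#' Fixed reversal potentials: `ena = 20` mV, `ek = -80` mV; the IAHP reversal
#' is `ek + ahp_rev_shift` (default +10 mV, a signed configuration value).
#' Gating rates carry `q10` temperature factors referred to `t_ref = 25` C.
#'
#' @param overrides named list merged over the defaults (nested lists merge
#'   recursively).
#' @return a named list of mechanism constant lists.
#' @export
trn_mechanisms <- function(overrides = list()) {
  base <- list(
    hh2 = list(
      vtraub = -55, ena = 20, ek = -80, q10 = 3, t_ref = 25,
      na_m = c(a_rate = 0.32, a_v = 13, a_k = 4, b_rate = 0.28, b_v = 40, b_k = 5),
      na_h = c(a_rate = 0.128, a_v = 17, a_k = 18, b_rate = 4, b_v = 40, b_k = 5),
      k_n = c(a_rate = 0.032, a_v = 15, a_k = 5, b_rate = 0.5, b_v = 10, b_k = 40)),
    it = list(
      q10 = 2.5, t_ref = 24,
      m = c(vhalf = -52, k = 7.4, tau0 = 3, tauamp = 1,
            v1 = 25, k1 = 10, v2 = 100, k2 = 15),
      h = c(vhalf = -80, k = 5, tau0 = 85, tauamp = 1,
            v1 = 46, k1 = 4, v2 = 405, k2 = 50)),
    iahp = list(q10 = 3, t_ref = 25, cac = 0.05, beta = 0.03, taumin = 0.5),
    ican = list(q10 = 3, t_ref = 25, cac = 0.01, beta = 0.003, taumin = 1,
                e_rev = 0),
    ia = list(
      q10 = 3, t_ref = 25,
      m = c(vhalf = -60, k = 8.5, tau0 = 0.27, tauamp = 1,
            v1 = 35.8, k1 = 19.7, v2 = 79.7, k2 = 12.7),
      h = c(vhalf = -78, k = 6, tau0 = 5, tauamp = 1,
            v1 = 46, k1 = 5, v2 = 238, k2 = 37.5)),
    cad = list(depth = 1, decay_tau = 150, ca_inf = 2.4e-4, cao = 2),
    pas = list(e_pas = -70, q10 = 1),
    # signed shift of the IAHP reversal from ek; -5 mV lets the slow AHP
    # undershoot rest (de-inactivating IT between bursts, which sustained
    # rebound bursting requires) while keeping the -80 mV hold quiescent;
    # a +10 mV shift caps the inter-burst AHP at rest and abolishes
    # re-bursting altogether
    ahp_rev_shift = -5)
  merge_rec(base, overrides)
}

merge_rec <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Temperature scaling factor
#'
#' `q10^((T - t_ref) / 10)`; multiplies gating rate constants (equivalently,
#' divides time constants) when simulating away from the reference
#' temperature.
#'
#' @param temperature simulation temperature (deg C).
#' @param t_ref reference temperature of the kinetics (deg C).
#' @param q10 fold change of rates per 10 deg C (> 0).
#' @return dimensionless scale factor.
#' @export
q10_scale <- function(temperature, t_ref = 25, q10 = 3) {
  if (any(q10 <= 0)) stop_invalid("q10 must be positive")
  q10^((temperature - t_ref) / 10)
}

#' Calcium Nernst potential
#'
#' Reversal potential of a calcium-permeant channel,
#' `(R T) / (2 F) * ln(cao / cai)` in mV.
#'
#' @param cai intracellular calcium (mM).
#' @param cao extracellular calcium (mM).
#' @param temperature deg C.
#' @return reversal potential in mV.
#' @export
nernst_eca <- function(cai, cao = 2, temperature = 25) {
  if (any(cai <= 0) || any(cao <= 0)) {
    stop_invalid("calcium concentrations must be positive")
  }
  1000 * GAS_CONSTANT * (temperature + 273.15) / (2 * FARADAY) * log(cao / cai)
}

#' Linear dendritic IT density gradient
#'
#' Maximal T-type conductance as a function of path distance `d` from the
#' soma: `g0 * (1 + d * slope)`, floored at zero.
#'
#' @param dist list with `g0` (S/cm^2) and `slope` (1/um); see
#'   [it_distribution()].
#' @param d path distance(s) from the soma (um, >= 0).
#' @return conductance density in S/cm^2.
#' @export
it_density <- function(dist, d) {
  if (any(d < 0)) stop_invalid("path distance must be non-negative")
  pmax(0, dist$g0 * (1 + d * dist$slope))
}

#' @rdname it_density
#' @param g0 somatic-end maximal conductance (S/cm^2).
#' @param slope linear gradient (1/um); positive values increase the density
#'   away from the soma.
#' @export
it_distribution <- function(g0, slope = 0) {
  if (g0 < 0) stop_invalid("g0 must be non-negative")
  list(g0 = g0, slope = slope)
}

# ---- gate specifications -------------------------------------------------

vtrap <- function(x, k) ifelse(abs(x / k) < 1e-6, k * (1 - x / k / 2),
                               x / (exp(x / k) - 1))

rate_gate <- function(alpha, beta, exponent) {
  list(steady_state = function(v) alpha(v) / (alpha(v) + beta(v)),
       time_constant = function(v) 1 / (alpha(v) + beta(v)),
       exponent = exponent)
}

boltz_gate <- function(p, exponent, inactivation = FALSE) {
  force(p)
  ss <- function(v) {
    s <- 1 / (1 + exp(-(v - p[["vhalf"]]) / p[["k"]]))
    if (inactivation) 1 - s else s
  }
  tc <- function(v) {
    p[["tau0"]] + p[["tauamp"]] /
      (exp((v + p[["v1"]]) / p[["k1"]]) + exp(-(v + p[["v2"]]) / p[["k2"]]))
  }
  list(steady_state = ss, time_constant = tc, exponent = exponent)
}

ca_gate <- function(cac, beta, taumin, exponent) {
  list(steady_state = function(ca) {
    car <- (ca / cac)^2
    car / (1 + car)
  },
  time_constant = function(ca) {
    car <- (ca / cac)^2
    pmax(taumin, 1 / (beta * (1 + car)))
  },
  exponent = exponent)
}

#' Gate kinetics of a mechanism
#'
#' Returns the gate specifications (steady state, time constant, exponent) of
#' one mechanism, as closures over the constants in `mech`. Voltage-gated
#' specs take voltage (mV); the calcium-gated `iahp`/`ican` activation takes
#' intracellular calcium (mM).
#'
#' @param name one of `"hh2_Na"`, `"hh2_K"`, `"IT"`, `"IAHP"`, `"ICAN"`, `"IA"`.
#' @param mech mechanism constants, see [trn_mechanisms()].
#' @return named list of gate specs.
#' @export
gate_specs <- function(name, mech = trn_mechanisms()) {
  switch(name,
    hh2_Na = {
      p <- mech$hh2
      vt <- p$vtraub
      m <- rate_gate(
        function(v) p$na_m[["a_rate"]] * vtrap(p$na_m[["a_v"]] - (v - vt), p$na_m[["a_k"]]),
        function(v) p$na_m[["b_rate"]] * vtrap((v - vt) - p$na_m[["b_v"]], p$na_m[["b_k"]]),
        3)
      h <- rate_gate(
        function(v) p$na_h[["a_rate"]] * exp((p$na_h[["a_v"]] - (v - vt)) / p$na_h[["a_k"]]),
        function(v) p$na_h[["b_rate"]] / (1 + exp((p$na_h[["b_v"]] - (v - vt)) / p$na_h[["b_k"]])),
        1)
      list(m = m, h = h)
    },
    hh2_K = {
      p <- mech$hh2
      vt <- p$vtraub
      n <- rate_gate(
        function(v) p$k_n[["a_rate"]] * vtrap(p$k_n[["a_v"]] - (v - vt), p$k_n[["a_k"]]),
        function(v) p$k_n[["b_rate"]] * exp((p$k_n[["b_v"]] - (v - vt)) / p$k_n[["b_k"]]),
        4)
      list(n = n)
    },
    IT = list(m = boltz_gate(mech$it$m, 2),
              h = boltz_gate(mech$it$h, 1, inactivation = TRUE)),
    IA = list(m = boltz_gate(mech$ia$m, 4),
              h = boltz_gate(mech$ia$h, 1, inactivation = TRUE)),
    IAHP = list(m = ca_gate(mech$iahp$cac, mech$iahp$beta, mech$iahp$taumin, 2)),
    ICAN = list(m = ca_gate(mech$ican$cac, mech$ican$beta, mech$ican$taumin, 2)),
    stop_invalid(paste("unknown mechanism:", name)))
}

#' Exponential-Euler gate update
#'
#' Relaxes a gate toward its steady state over one time step:
#' `g + (inf - g) * (1 - exp(-dt * tadj / tau))`, clamped to `[0, 1]`.
#'
#' @param g current gate value in `[0, 1]`.
#' @param v voltage (mV) -- or calcium (mM) for calcium-gated specs.
#' @param spec a gate spec from [gate_specs()].
#' @param dt time step (ms).
#' @param tadj temperature factor from [q10_scale()] (divides the time
#'   constant).
#' @param vshift optional voltage shift: the gate is evaluated at `v + vshift`.
#' @return updated gate value in `[0, 1]`.
#' @export
gate_step <- function(g, v, spec, dt, tadj = 1, vshift = 0) {
  vv <- v + vshift
  inf <- spec$steady_state(vv)
  tau <- spec$time_constant(vv) / tadj
  out <- inf + (g - inf) * exp(-dt / tau)
  pmin(1, pmax(0, out))
}

#' Membrane current of one mechanism
#'
#' Ohmic current density `gbar * prod(gates^exponent) * (v - e_rev)` in
#' mA/cm^2 (positive outward). The T-type reversal comes from the calcium
#' Nernst potential; the IAHP reversal is `ek + ahp_rev_shift`; IAHP and ICAN
#' activation depends on intracellular calcium, not voltage.
#'
#' @param params list with `name` (one of `"pas"`, `"hh2_Na"`, `"hh2_K"`,
#'   `"IT"`, `"IAHP"`, `"ICAN"`, `"IA"`), `gbar` (S/cm^2), and optionally
#'   `vshift` (mV, IT only).
#' @param gates named numeric vector of gate values (e.g. `c(m = .., h = ..)`);
#'   ignored for `pas`.
#' @param v membrane voltage (mV).
#' @param cai intracellular calcium (mM; used by IT's reversal).
#' @param mech mechanism constants.
#' @param temperature deg C (for the calcium Nernst potential).
#' @return current density in mA/cm^2.
#' @export
mechanism_current <- function(params, gates = NULL, v, cai = 2.4e-4,
                              mech = trn_mechanisms(), temperature = 25) {
  gbar <- params$gbar
  if (gbar < 0) stop_invalid("gbar must be non-negative")
  switch(params$name,
    pas = gbar * (v - mech$pas$e_pas),
    hh2_Na = gbar * gates[["m"]]^3 * gates[["h"]] * (v - mech$hh2$ena),
    hh2_K = gbar * gates[["n"]]^4 * (v - mech$hh2$ek),
    IT = {
      eca <- nernst_eca(cai, mech$cad$cao, temperature)
      gbar * gates[["m"]]^2 * gates[["h"]] * (v - eca)
    },
    IAHP = gbar * gates[["m"]]^2 * (v - (mech$hh2$ek + mech$ahp_rev_shift)),
    ICAN = gbar * gates[["m"]]^2 * (v - mech$ican$e_rev),
    IA = gbar * gates[["m"]]^4 * gates[["h"]] * (v - mech$hh2$ek),
    stop_invalid(paste("unknown mechanism:", params$name)))
}

#' Split the generic IT conductance into two voltage-shifted isoforms
#'
#' Replaces one generic T-type channel by an up-shifted and a down-shifted
#' copy (`vshift + delta_v` and `vshift - delta_v`), partitioning the maximal
#' conductance as `fraction_up * gbar` and `(1 - fraction_up) * gbar`; total
#' conductance is conserved exactly. Mimics a mixture of Cav3 channel
#' subtypes with a generic kinetic template.
#'
#' @param it list with `gbar` and `vshift` describing the single generic IT.
#' @param delta_v symmetric shift magnitude (mV).
#' @param fraction_up fraction of the conductance given to the `+delta_v`
#'   copy, in `[0, 1]`.
#' @return list of two IT parameter lists (`up`, `down`).
#' @export
split_it_isoforms <- function(it, delta_v, fraction_up = 0.5) {
  if (fraction_up < 0 || fraction_up > 1) {
    stop_invalid("fraction_up must be in [0, 1]")
  }
  vs <- it$vshift %||% 0
  list(up = list(name = "IT", gbar = fraction_up * it$gbar, vshift = vs + delta_v),
       down = list(name = "IT", gbar = (1 - fraction_up) * it$gbar, vshift = vs - delta_v))
}

#' T-type window current profile
#'
#' The steady-state open probability `m_inf^2 * h_inf` of the generic T-type
#' channel over a voltage grid, after applying the window shift.
#'
#' @param v voltage grid (mV).
#' @param vshift window shift (mV); positive moves the window to more
#'   negative voltages.
#' @param mech mechanism constants.
#' @return tibble with `v` and `open` columns.
#' @export
it_window <- function(v = seq(-110, -40, by = 0.1), vshift = 0,
                      mech = trn_mechanisms()) {
  gs <- gate_specs("IT", mech)
  vv <- v + vshift
  tibble::tibble(v = v,
                 open = gs$m$steady_state(vv)^2 * gs$h$steady_state(vv))
}

# ---- kinetic vector for the compiled core --------------------------------

# layout must match the Kin enum in src/trn_sim.cpp
kin_vector <- function(mech, temperature = 25) {
  rates6 <- function(p) unname(p[c("a_rate", "a_v", "a_k", "b_rate", "b_v", "b_k")])
  gate8 <- function(p) unname(p[c("vhalf", "k", "tau0", "tauamp", "v1", "k1", "v2", "k2")])
  c(mech$hh2$vtraub,
    rates6(mech$hh2$na_m), rates6(mech$hh2$na_h), rates6(mech$hh2$k_n),
    gate8(mech$it$m), gate8(mech$it$h),
    mech$iahp$cac, mech$iahp$beta, mech$iahp$taumin,
    mech$ican$cac, mech$ican$beta, mech$ican$taumin,
    gate8(mech$ia$m), gate8(mech$ia$h),
    mech$cad$depth, mech$cad$decay_tau, mech$cad$ca_inf, mech$cad$cao,
    mech$pas$e_pas, mech$ican$e_rev, mech$ahp_rev_shift,
    q10_scale(temperature, mech$hh2$t_ref, mech$hh2$q10),
    q10_scale(temperature, mech$it$t_ref, mech$it$q10),
    q10_scale(temperature, mech$ia$t_ref, mech$ia$q10),
    q10_scale(temperature, mech$iahp$t_ref, mech$iahp$q10),
    q10_scale(temperature, mech$ican$t_ref, mech$ican$q10),
    mech$hh2$ena, mech$hh2$ek, temperature)
}
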
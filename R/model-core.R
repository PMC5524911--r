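# Constitutive relations and the simulation engine.

#' Time-varying elastance ("double-Hill")
#'
#' The normalized elastance waveform is the product of an activating Hill
#' curve (exponent `m1`, half-activation time `alpha1 * T`) and a
#' deactivating one (exponent `m2`, time constant `alpha2 * T`).  The
#' waveform is rescaled so that its maximum over one cycle equals
#' `e_max` exactly and its value at contraction onset is `e_min`.  The
#' rescaling factor has no closed form; it is found numerically (dense
#' grid + golden-section refinement) once per parameter set.
#'
#' @param t Time (s); vectorized.  The waveform is evaluated at
#'   `(t - onset) mod T`, so negative onsets shift activation earlier.
#' @param e_min,e_max Minimal / maximal elastance (mmHg/mL).
#' @param m1,m2 Contraction / relaxation rate constants (dimensionless).
#' @param alpha1,alpha2 Systolic / diastolic time constants (fraction of
#'   the cycle length).
#' @param onset Contraction onset time (s); may be negative.
#' @param T Cardiac cycle length (s).
#' @return Elastance (mmHg/mL), same length as `t`.
#' @examples
#' elastance(0.25, 0.08, 3, 1.32, 27.4, 0.269, 0.452, 0, 0.9)
#' @export
elastance <- function(t, e_min, e_max, m1, m2, alpha1, alpha2,
                      onset = 0, T = 1) {
  stopifnot(T > 0, e_max >= e_min, e_min > 0, m1 > 0, m2 > 0,
            alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1)
  out <- cpp_elastance(as.numeric(t), e_min, e_max, m1, m2, alpha1, alpha2,
                       onset, T)
  if (any(!is.finite(out))) stop("non-finite elastance: invalid parameters")
  out
}

#' Chamber pressure from the elastance relation
#'
#' P = E (V - V0) (1 - Ks q), where q is the instantaneous outflow of the
#' chamber.  The flow-dependent term models the pressure fall-off of the
#' contracting chamber as a source resistance.  The chamber's viscous
#' loss resistance acts at the chamber outlet and is applied in the
#' circuit equations, not here.
#'
#' @param V Chamber volume (mL).
#' @param q Chamber outflow (mL/s).
#' @param E Instantaneous elastance (mmHg/mL).
#' @param V0 Unstressed volume (mL).
#' @param Ks Source resistance coefficient (s/mL).
#' @return Pressure (mmHg).
#' @export
chamber_pressure <- function(V, q, E, V0, Ks = 0) {
  stopifnot(is.finite(V), is.finite(q), is.finite(E))
  E * (V - V0) * (1 - Ks * q)
}

#' Pressure gradient across the mitral valve (open state)
#'
#' @param Q Transvalvular flow (mL/s).
#' @param dQdt Flow rate of change (mL/s^2).
#' @param R_mv Valve resistance (mmHg s/mL).
#' @param L_mv Valve inertance (mmHg s^2/mL).
#' @return Pressure gradient (mmHg).
#' @export
mitral_gradient <- function(Q, dQdt, R_mv, L_mv) {
  R_mv * Q + L_mv * dQdt
}

#' Energy loss coefficient of the aortic valve
#'
#' `E_L_CO = EOA * A_ao / (A_ao - EOA)` accounts for pressure recovery
#' downstream of the vena contracta: the effective resistance of the
#' valve is governed by this coefficient rather than by the orifice area
#' alone.
#'
#' @param eoa_av Effective orifice area (cm^2).
#' @param a_ao Aortic cross-sectional area at peak systole (cm^2).
#' @return Energy loss coefficient (cm^2); strictly increasing in
#'   `eoa_av`.
#' @export
energy_loss_coefficient <- function(eoa_av, a_ao) {
  if (any(eoa_av <= 0) || any(eoa_av >= a_ao))
    stop("need 0 < eoa_av < a_ao: pressure recovery undefined")
  eoa_av * a_ao / (a_ao - eoa_av)
}

# 1 mmHg = 1333.22 barye; the convective term of the aortic valve
# gradient is dimensional in CGS (g/mL * (mL/s)^2 / cm^4 = barye).
.mmhg_per_barye <- 1 / 1333.22

#' Pressure gradient across the aortic valve (open state)
#'
#' The convective (Bernoulli-type) term uses the energy loss coefficient
#' to include pressure recovery; the acceleration term uses a generic
#' inertance.  The convective term is computed in CGS units and converted
#' to mmHg.
#'
#' @param Q Transvalvular flow (mL/s).
#' @param dQdt Flow rate of change (mL/s^2).
#' @param eoa_av,a_ao Valve / aortic areas (cm^2).
#' @param L_av Valve inertance (mmHg s^2/mL).
#' @param rho Blood density (g/mL).
#' @return Pressure gradient (mmHg).
#' @export
aortic_gradient <- function(Q, dQdt, eoa_av, a_ao, L_av, rho = 1.06) {
  elco <- energy_loss_coefficient(eoa_av, a_ao)
  rho * Q * abs(Q) / (2 * elco^2) * .mmhg_per_barye + L_av * dQdt
}

#' Simulate the full circulation model
#'
#' Integrates the circuit with a fixed-step backward-Euler scheme (Newton
#' iterations on each step; A-stable, suited to the stiff mix of small
#' inertances and compliances).  The simulation starts at the onset of
#' isovolumetric contraction with both valves closed, and runs long
#' enough (default 20 s) for the solution to settle onto a periodic
#' orbit.
#'
#' Valves are diodes: a closed valve opens when the upstream-downstream
#' pressure gradient becomes positive; an open valve carries flow
#' following its inertance equation and closes (flow clamped to zero)
#' when the flow crosses zero from above.
#'
#' @param p A `clpm_parameters` object (see [model_parameters()]).
#' @param duration Simulated time (s).
#' @param dt Solver step (s).
#' @param init Optional named initial state (see Details).  Defaults:
#'   chamber volumes 60/120 mL, arterial capacitor pressures at a mean
#'   arterial pressure scale (80 mmHg), pulmonary capacitor at `p_pu`,
#'   all flows zero.
#' @param p_ven Venous reference pressure at the Windkessel outlets
#'   (mmHg).
#' @param store_from Discard output before this time (s); the full state
#'   is still integrated from 0.
#' @param newton_iters Newton iterations per implicit step.
#' @return A `clpm_simulation`: a data.frame with time `t`, the 13 state
#'   variables, derived pressures `P_LA`, `P_LV`, `P_ao`, flows
#'   `F1`..`F5` (mitral, aortic valve, distal ascending aorta, aortic
#'   arch past the supra-aortic branch, abdominal aorta) and valve state
#'   indicators, plus attributes `dt` and `T`.
#' @examples
#' sim <- simulate_circulation(literature_parameters(), duration = 5)
#' range(sim$P_ao)
#' @export
simulate_circulation <- function(p, duration = 20, dt = 1e-3, init = NULL,
                                 p_ven = 0, store_from = 0,
                                 newton_iters = 4) {
  validate_parameters(p)
  pv <- as.numeric(p[.par_names])
  x0 <- c(V_LA = 60, V_LV = 120, Q_pv = 0, Q_mv = 0, Q_av = 0,
          Q_aa = 0, Q_da = 0,
          P_pvc = pv[[1]], P_caa = 80, P_cpsa = 80, P_cpia = 80,
          P_cda = 80, P_cpda = 80)
  if (!is.null(init)) {
    unknown <- setdiff(names(init), names(x0))
    if (length(unknown))
      stop("unknown state(s) in init: ", paste(unknown, collapse = ", "))
    x0[names(init)] <- as.numeric(init)
  }
  m <- cpp_simulate(pv, duration, dt, as.numeric(x0), p_ven, store_from,
                    as.integer(newton_iters))
  d <- as.data.frame(m)
  d$F1 <- d$Q_mv
  d$F2 <- d$Q_av
  d$F3 <- d$Q_aa
  d$F5 <- d$Q_da
  d <- d[c("t", "V_LA", "V_LV", "Q_pv", "Q_mv", "Q_av", "Q_aa", "Q_da",
           "P_pvc", "P_caa", "P_cpsa", "P_cpia", "P_cda", "P_cpda",
           "P_LA", "P_LV", "P_ao", "F1", "F2", "F3", "F4", "F5",
           "mv_open", "av_open")]
  structure(d, dt = dt, T = p[["t_cycle"]], p_ven = p_ven,
            class = c("clpm_simulation", "data.frame"))
}

#' Restrict a simulation to its final cycle
#'
#' Returns the window `[t_end - T, t_end]` with time re-origined to 0,
#' i.e. one converged cycle starting at the onset of isovolumetric
#' contraction.
#'
#' @param sim A `clpm_simulation`.
#' @param T Cycle length (s); defaults to the simulation's own.
#' @return A `clpm_simulation` covering one cycle.
#' @export
extract_last_cycle <- function(sim, T = attr(sim, "T")) {
  t_end <- sim$t[nrow(sim)]
  dtt <- attr(sim, "dt")
  if (is.null(dtt)) dtt <- 0
  if (t_end - sim$t[1] < 2 * T - 2 * dtt)
    stop("simulation shorter than two cycles; cannot extract a converged one")
  keep <- sim$t >= t_end - T - 1e-12
  out <- sim[keep, , drop = FALSE]
  out$t <- out$t - out$t[1]
  rownames(out) <- NULL
  structure(out, dt = attr(sim, "dt"), T = T, p_ven = attr(sim, "p_ven"),
            class = class(sim))
}

#' Left-ventricular pressure-volume loop and stroke work
#'
#' Stroke work is the signed area enclosed by the (V_LV, P_LV) loop over
#' one cycle, computed with the trapezoidal rule on the closed contour.
#'
#' @param cycle A one-cycle `clpm_simulation` (see
#'   [extract_last_cycle()]), or any data.frame with `V_LV` and `P_LV`.
#' @return List with `volume` (mL), `pressure` (mmHg) and `stroke_work`
#'   (mmHg mL, positive for the physiological counter-clockwise loop).
#' @export
pv_loop <- function(cycle) {
  V <- cycle$V_LV
  P <- cycle$P_LV
  Vc <- c(V, V[1])
  Pc <- c(P, P[1])
  # signed area of the closed contour; traversal with falling volume in
  # systole at high pressure gives positive work
  area <- -sum(0.5 * (Pc[-1] + Pc[-length(Pc)]) * diff(Vc))
  list(volume = V, pressure = P, stroke_work = area)
}

#' Model-based systolic and diastolic pressure
#'
#' The model counterparts of cuff SBP/DBP are the extrema of the aortic
#' root pressure waveform over one converged cycle.
#'
#' @param cycle A one-cycle `clpm_simulation` (or data.frame with
#'   `P_ao`).
#' @return Named vector `c(SBP = ..., DBP = ...)` in mmHg.
#' @export
pressure_summary <- function(cycle) {
  c(SBP = max(cycle$P_ao), DBP = min(cycle$P_ao))
}

#' Simulate an isolated three-element Windkessel
#'
#' Drives a proximal resistance `Rp` in series with the parallel
#' combination of compliance `Cp` and distal resistance `Rd` with a
#' prescribed inflow, using the same backward-Euler stepping as the full
#' model.  Mainly used to verify the integrator against the closed-form
#' solution (steady pressure `Q0 (Rp + Rd)`, relaxation time `Rd Cp`).
#'
#' @param Rp,Rd Proximal / distal resistance (mmHg s/mL).
#' @param Cp Compliance (mL/mmHg).
#' @param inflow Function of time returning inflow (mL/s), or a single
#'   number for constant inflow.
#' @param duration,dt Simulated time and step (s).
#' @param P0 Initial capacitor pressure (mmHg).
#' @return data.frame with `t`, `P` (inlet pressure) and `Pc` (capacitor
#'   pressure).
#' @export
simulate_windkessel <- function(Rp, Rd, Cp, inflow, duration = 10,
                                dt = 1e-3, P0 = 0) {
  stopifnot(Rp > 0, Rd > 0, Cp > 0)
  qfun <- if (is.function(inflow)) inflow else function(t) inflow
  n <- round(duration / dt)
  t <- seq(0, duration, by = dt)
  Pc <- numeric(n + 1)
  Pc[1] <- P0
  a <- dt / (Rd * Cp)
  for (k in seq_len(n)) {
    # backward Euler on Cp dPc/dt = Q(t) - Pc/Rd
    Pc[k + 1] <- (Pc[k] + dt * qfun(t[k + 1]) / Cp) / (1 + a)
  }
  q <- vapply(t, qfun, numeric(1))
  data.frame(t = t, P = Pc + Rp * q, Pc = Pc)
}
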
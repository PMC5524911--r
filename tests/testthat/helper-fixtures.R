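# Shared fixtures and independent oracles.  Expensive objects (20 s
# simulations, fits) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# final converged cycle of the literature parameter set
lit_cycle <- function() cached("lit_cycle", {
  p <- literature_parameters()
  sim <- simulate_circulation(p, duration = 20, dt = 1e-3, store_from = 16)
  extract_last_cycle(sim)
})

# a cycle whose window is aligned to the cycle boundary (R-wave at t=0)
aligned_cycle <- function(p, horizon = 20, dt = 1e-3) {
  T <- p[["t_cycle"]]
  dur <- T * floor(horizon / T)
  sim <- simulate_circulation(p, duration = dur, dt = dt,
                              store_from = dur - 2 * T)
  extract_last_cycle(sim, T = T)
}

fixture_subject <- function(seed, noise_sd) {
  key <- paste0("subj_", seed, "_", noise_sd)
  cached(key, virtual_subject(seed, noise_sd = noise_sd))
}

# closure targets consistent with a ground-truth network: exact DC
# resistance and exact total compliance (used by the synthetic recovery
# experiments, where the closure must not bias the optimum away from
# the truth)
true_targets <- function(p) {
  svr <- p[["r_aa"]] +
    1 / (1 / (p[["r_psa"]] + p[["r_dsa"]]) +
         1 / (p[["r_pia"]] + p[["r_dia"]]) +
         1 / (p[["r_da"]] + p[["r_pda"]] + p[["r_dda"]]))
  ctot <- p[["c_psa"]] + p[["c_pia"]] + p[["c_pda"]] +
    p[["c_aa"]] + p[["c_da"]]
  list(SVR = svr, c_tot = ctot)
}

# the parameters the reference identifiability analysis classifies as
# identifiable (used in recovery and profile-likelihood experiments)
identifiable_params <- c("e_min_lv", "m1_lv", "m2_lv", "alpha1_lv",
                         "alpha2_lv", "c_aa", "c_da", "c_psa",
                         "onset_lv", "p_pu", "e_min_la", "e_max_la")

structural_params <- c("ks_la", "r_visc_la", "ks_lv", "r_visc_lv",
                       "r_aav", "r_dav")

# --- independent oracles ---------------------------------------------

# dense-grid evaluation of the double-Hill elastance: the closed form
# with the scaling factor found by brute force on n points
oracle_elastance <- function(t, e_min, e_max, m1, m2, a1, a2,
                             onset, T, n = 1e6) {
  g <- function(s) {
    x1 <- (s / a1)^m1
    x2 <- (s / a2)^m2
    (x1 / (1 + x1)) / (1 + x2)
  }
  s_grid <- seq(1 / n, 1 - 1 / n, length.out = n)
  gmax <- max(g(s_grid))
  s <- ((t - onset) / T) %% 1
  ifelse(s <= 0, e_min, (e_max - e_min) * g(s) / gmax + e_min)
}

# shoelace signed area of a closed polygon (V, P): positive for the
# physiological counter-clockwise traversal (isovolumic pressure rise,
# ejection leftward at high pressure, relaxation, filling rightward)
oracle_shoelace <- function(V, P) {
  n <- length(V)
  j <- c(2:n, 1)
  0.5 * sum(V * P[j] - V[j] * P)
}

# trapezoid with periodic wrap (independent re-implementation)
oracle_net_volume <- function(t, q, period) {
  v <- sum(diff(t) * (head(q, -1) + tail(q, -1)) / 2)
  v + (period - t[length(t)] + t[1]) * (q[length(q)] + q[1]) / 2
}

# mean of a periodically wrapped waveform
oracle_mean_flow <- function(t, q, period) oracle_net_volume(t, q, period) / period

# draw a random valid chamber parameter set
random_chamber <- function() {
  e_min <- runif(1, 0.05, 0.3)
  list(e_min = e_min,
       e_max = e_min + runif(1, 0.1, 3),
       m1 = runif(1, 0.8, 2.5),
       m2 = runif(1, 5, 35),
       a1 = runif(1, 0.08, 0.45),
       a2 = runif(1, 0.15, 0.7),
       onset = runif(1, -0.1, 0.9),
       T = runif(1, 0.7, 1.1))
}
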
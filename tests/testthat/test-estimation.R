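test_that("optimization bounds follow the per-class interval rules", {
  p0 <- model_parameters(c(r_aa = 0.04, l_aa = 5e-4, e_max_lv = 2.0))
  b <- make_bounds(p0)
  row <- function(nm) b[b$name == nm, ]
  expect_equal(unlist(row("r_aa")[c("lo", "hi")], use.names = FALSE),
               c(0.02, 0.08))
  expect_equal(unlist(row("l_aa")[c("lo", "hi")], use.names = FALSE),
               c(1e-4, 2.5e-3))
  # narrow parameters move only +/- 10%
  expect_equal(unlist(row("e_max_lv")[c("lo", "hi")], use.names = FALSE),
               c(1.8, 2.2))
  # chamber parameters use the [p0/2, 2 p0] interval
  expect_equal(unlist(row("m2_lv")[c("lo", "hi")], use.names = FALSE),
               c(27.4 / 2, 54.8))
  # onsets get additive intervals and may span zero
  expect_equal(unlist(row("onset_lv")[c("lo", "hi")], use.names = FALSE),
               c(-0.135, 0.135))
  # fixed and closure parameters are not optimized
  expect_false(any(c("t_cycle", "rho", "eoa_av", "r_dda", "c_pda")
                   %in% b$name))
  expect_equal(nrow(b), 36)
})

test_that("closure keeps SVR and total compliance on target", {
  vs <- fixture_subject(7, noise_sd = 0)
  tg <- true_targets(vs$truth)
  # perturb the free resistances; closure must restore the DC resistance
  p <- vs$truth
  p[["r_aa"]] <- p[["r_aa"]] * 1.4
  p[["c_psa"]] <- p[["c_psa"]] * 1.3
  p2 <- apply_closure(p, tg)
  expect_equal(true_targets(p2)$SVR, tg$SVR, tolerance = 1e-12)
  expect_equal(p2[["c_psa"]] + p2[["c_pia"]] + p2[["c_pda"]] +
                 p2[["c_aa"]] + p2[["c_da"]], tg$c_tot,
               tolerance = 1e-12)
  # at the truth itself, closure returns the truth values
  pc <- apply_closure(vs$truth, tg)
  expect_equal(pc[["r_dda"]], vs$truth[["r_dda"]], tolerance = 1e-12)
  expect_equal(pc[["c_pda"]], vs$truth[["c_pda"]], tolerance = 1e-12)
})

test_that("residuals vanish on self-generated data and scale with sigma", {
  vs <- fixture_subject(7, noise_sd = 0)
  cfg <- fit_config()                      # duration 20, sigma 1
  r <- residual_vector(vs$truth, vs$meas, cfg)
  expect_length(r, 5 * 40)
  expect_false(attr(r, "penalized"))
  expect_lt(sum(r^2), 1e-4 * length(r))    # noise-free self-fit
  # sigma = 2 halves the residuals, quarters the cost
  r2 <- residual_vector(vs$truth, vs$meas, fit_config(sigma = 2))
  expect_equal(sum(r2^2), sum(r^2) / 4, tolerance = 1e-8)
})

test_that("a constant offset on one waveform adds N * delta^2 to the cost", {
  vs <- fixture_subject(7, noise_sd = 0)
  cfg <- fit_config()
  J0 <- sum(residual_vector(vs$truth, vs$meas, cfg)^2)
  m2 <- vs$meas
  delta <- 2
  m2$waveforms$F3$q <- m2$waveforms$F3$q + delta
  J1 <- sum(residual_vector(vs$truth, m2, cfg)^2)
  expect_equal(J1 - J0, 40 * delta^2, tolerance = 0.02)
})

test_that("fitting from the generating truth terminates immediately", {
  # at the full horizon the noise-free self-residual is numerically
  # zero, so the 0.1% rule fires without productive iterations
  vs <- fixture_subject(7, noise_sd = 0)
  fit <- fit_model(vs$meas, vs$truth, cfg = fit_config(),
                   targets = true_targets(vs$truth))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2)
  expect_lte(fit$cost, fit$cost_initial + 1e-9)
})

test_that("a small perturbation is recovered and the cost is monotone", {
  vs <- fixture_subject(7, noise_sd = 0)
  tg <- true_targets(vs$truth)
  p0 <- vs$truth
  pert <- c("e_max_la", "c_psa")
  for (nm in pert) p0[[nm]] <- p0[[nm]] * 1.2
  fit <- fit_model(vs$meas, p0, cfg = fit_config(duration = 12),
                   opt_names = pert, targets = tg)
  expect_lt(fit$cost, 0.01 * fit$cost_initial)   # >= 99% reduction
  for (nm in pert)
    expect_lt(abs(fit$params[[nm]] - vs$truth[[nm]]) / vs$truth[[nm]],
              0.05)
  # accepted-step cost sequence never increases
  expect_true(all(diff(fit$cost_history) <= 1e-9))
  # estimates respect their bounds
  b <- fit$bounds
  v <- fit$estimates[b$name[b$name %in% names(fit$estimates)]]
  expect_true(all(v >= b$lo[match(names(v), b$name)] - 1e-12))
  expect_true(all(v <= b$hi[match(names(v), b$name)] + 1e-12))
})

test_that("divergent simulations yield penalty residuals, not errors", {
  vs <- fixture_subject(7, noise_sd = 0)
  # an unsimulatable parameter set: absurd inertance ratio provokes the
  # divergence guard rather than an R-level error
  p_bad <- vs$truth
  p_bad[["l_av"]] <- 1e-12
  p_bad[["l_mv"]] <- 1e-12
  r <- residual_vector(p_bad, vs$meas, fit_config(duration = 6))
  expect_length(r, 200)
  if (attr(r, "penalized")) expect_true(all(r == fit_config()$penalty))
})

test_that("residual smoothing is cost-preserving at a perfect fit", {
  r <- rep(0, 200)
  expect_equal(cardiolpm:::smooth_residual(r, rep(40L, 5), 9), r)
  set.seed(1)
  r2 <- rnorm(200)
  s <- cardiolpm:::smooth_residual(r2, rep(40L, 5), 5)
  # smoothing is averaging: never increases the sum of squares
  expect_lte(sum(s^2), sum(r2^2))
  # width 1 is the identity
  expect_identical(cardiolpm:::smooth_residual(r2, rep(40L, 5), 1), r2)
})
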
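test_that("elastance matches the closed form and its normalization", {
  # reference left-ventricular shape constants
  e <- elastance(0.25, 0.08, 3, 1.32, 27.4, 0.269, 0.452, 0, 0.9)
  oracle <- oracle_elastance(0.25, 0.08, 3, 1.32, 27.4, 0.269, 0.452,
                             0, 0.9)
  expect_equal(e, oracle, tolerance = 1e-8)

  # value at contraction onset is e_min, maximum is e_max
  expect_equal(elastance(0, 0.08, 3, 1.32, 27.4, 0.269, 0.452, 0, 0.9),
               0.08)
  tt <- seq(0, 0.9, length.out = 1e5)
  expect_equal(max(elastance(tt, 0.08, 3, 1.32, 27.4, 0.269, 0.452,
                             0, 0.9)),
               3, tolerance = 1e-6)

  # negative onset shifts activation earlier: E(t) = E_shifted(t + onset)
  e1 <- elastance(0.2, 0.08, 3, 1.32, 27.4, 0.269, 0.452, -0.04, 0.9)
  e2 <- elastance(0.24, 0.08, 3, 1.32, 27.4, 0.269, 0.452, 0, 0.9)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("chamber pressure follows the flow-dependent elastance relation", {
  expect_equal(chamber_pressure(110, 500, 3, 10, 4e-9), 299.9994)
  expect_equal(chamber_pressure(50, 123, 2.5, 50, 1e-8), 0)   # V = V0
  expect_equal(chamber_pressure(80, 0, 1.5, 20), 90)          # q = 0
})

test_that("mitral valve gradient is resistive plus inertial", {
  expect_equal(mitral_gradient(0, 0, 3.75e-3, 2e-4), 0)
  expect_equal(mitral_gradient(200, 0, 3.75e-3, 2e-4), 0.75)
  expect_equal(mitral_gradient(0, 1000, 3.75e-3, 2e-4), 0.2)
})

test_that("energy loss coefficient behaves per the pressure-recovery formula", {
  expect_equal(energy_loss_coefficient(1.69, 5), 2.552870,
               tolerance = 1e-6)
  expect_equal(energy_loss_coefficient(2.5, 5), 5)     # EOA = A/2 -> A
  # strictly increasing in EOA, vanishing limit
  eoas <- seq(0.2, 4.5, by = 0.1)
  expect_true(all(diff(energy_loss_coefficient(eoas, 5)) > 0))
  expect_lt(energy_loss_coefficient(1e-6, 5), 1e-5)
  expect_error(energy_loss_coefficient(5, 5), "pressure recovery")
  expect_error(energy_loss_coefficient(6, 5), "pressure recovery")
})

test_that("aortic valve gradient: convective term in CGS, quadratic in flow", {
  g <- aortic_gradient(500, 0, 1.69, 5, 4e-4, rho = 1.06)
  expect_equal(g, 15.249, tolerance = 1e-4)
  expect_equal(aortic_gradient(0, 0, 1.69, 5, 4e-4), 0)
  # doubling flow quadruples the steady term
  expect_equal(aortic_gradient(1000, 0, 1.69, 5, 4e-4) / g, 4,
               tolerance = 1e-12)
  # inertial term is linear and additive
  expect_equal(aortic_gradient(500, 2000, 1.69, 5, 4e-4) - g, 4e-4 * 2000,
               tolerance = 1e-9)
})

test_that("pv_loop area: rectangle and shoelace oracle", {
  # rectangular loop traversed like a cardiac cycle (V falls at high P)
  V <- c(140, 140, 60, 60)
  P <- c(10, 110, 110, 10)
  expect_equal(pv_loop(data.frame(V_LV = V, P_LV = P))$stroke_work, 8000)

  cyc <- lit_cycle()
  sw <- pv_loop(cyc)$stroke_work
  expect_equal(sw, oracle_shoelace(cyc$V_LV, cyc$P_LV), tolerance = 1e-8)
  expect_gt(sw, 0)
})

test_that("pressure summary is the extrema of aortic root pressure", {
  t <- seq(0, 1, length.out = 400)
  expect_equal(pressure_summary(data.frame(P_ao = rep(90, 10))),
               c(SBP = 90, DBP = 90))
  expect_equal(pressure_summary(data.frame(P_ao = 100 + 20 * sin(2 * pi * t))),
               c(SBP = 120, DBP = 80), tolerance = 1e-3)
})

test_that("simulation of the literature set is periodic and conservative", {
  cyc <- lit_cycle()
  dtt <- attr(cyc, "dt")
  # physiological pressures and positive volumes
  ps <- pressure_summary(cyc)
  expect_gt(ps[["SBP"]], 70); expect_lt(ps[["SBP"]], 140)
  expect_gt(ps[["DBP"]], 40); expect_lt(ps[["DBP"]], ps[["SBP"]])
  expect_true(all(cyc$V_LV > 0) && all(cyc$V_LA > 0))
  # valve flows: zero when closed, never negative
  expect_true(all(cyc$F1[cyc$mv_open == 0] == 0))
  expect_true(all(cyc$F2[cyc$av_open == 0] == 0))
  expect_true(all(cyc$F1 >= 0) && all(cyc$F2 >= 0))
  # mass conservation over the converged cycle
  sv <- sum(cyc$F2) * dtt
  expect_lt(abs(sum(cyc$F1) * dtt - sv), 0.01 * sv)
})

test_that("population-center parameter set sits in the cuff pressure range", {
  p <- model_parameters(c(p_pu = 10.8))
  cyc <- aligned_cycle(p)
  ps <- pressure_summary(cyc)
  expect_gt(ps[["SBP"]], 90); expect_lt(ps[["SBP"]], 140)
  expect_gt(ps[["DBP"]], 45); expect_lt(ps[["DBP"]], 90)
})

test_that("no pressure generation means no sustained ejection", {
  # flat elastances and a (numerically) zero pulmonary source: after
  # the stored charge drains passively, no flow can be sustained
  p <- model_parameters(c(e_max_lv = 0.08, e_min_lv = 0.08,
                          e_max_la = 0.08, e_min_la = 0.08,
                          p_pu = 1e-6), validate = TRUE)
  # the stored charge drains passively with a long time constant, so
  # the statement to check is the absence of pulsatile pumping: the
  # transvalvular flow is a small monotonically decaying trickle, never
  # a systolic pulse
  sim <- simulate_circulation(p, duration = 30, store_from = 10)
  expect_lt(max(sim$F2), 10)
  early <- sim$t >= 10 & sim$t <= 12
  late <- sim$t >= 28
  expect_lt(max(sim$F2[late]), 0.6 * max(sim$F2[early]))
  expect_lt(max(sim$F2[late]), 2)
})

test_that("last two cycles agree pointwise (periodic convergence)", {
  p <- literature_parameters()
  sim <- simulate_circulation(p, duration = 20, store_from = 18)
  n <- round(p[["t_cycle"]] / 1e-3)
  v <- sim$V_LV
  m <- length(v)
  a <- v[(m - n + 1):m]
  b <- v[(m - 2 * n + 1):(m - n)]
  expect_lt(max(abs(a - b)) / mean(a), 0.005)
})

test_that("extract_last_cycle windows and re-origins correctly", {
  p <- literature_parameters()
  sim <- simulate_circulation(p, duration = 20, store_from = 16)
  cyc <- extract_last_cycle(sim)
  expect_equal(cyc$t[1], 0)
  expect_equal(max(cyc$t), 0.9, tolerance = 2e-3)
  expect_equal(nrow(cyc), 901)
  expect_error(extract_last_cycle(sim[sim$t > 19.5, ]), "two cycles")
  # a constant trajectory stays constant
  const <- sim
  const$V_LV <- 100
  expect_true(all(extract_last_cycle(const)$V_LV == 100))
})

test_that("solution is insensitive to the initial state after 20 s", {
  p <- literature_parameters()
  c1 <- aligned_cycle(p)
  T <- p[["t_cycle"]]
  dur <- T * floor(20 / T)
  s2 <- simulate_circulation(p, duration = dur, store_from = dur - 2 * T,
                             init = c(V_LA = 90, V_LV = 160, P_caa = 50))
  c2 <- extract_last_cycle(s2, T = T)
  expect_equal(pressure_summary(c1), pressure_summary(c2),
               tolerance = 1e-3)
})

test_that("halving the step changes the converged flows by < 0.5% RMS", {
  p <- literature_parameters()
  c1 <- aligned_cycle(p, dt = 1e-3)
  c2 <- aligned_cycle(p, dt = 5e-4)
  tf <- seq(0, p[["t_cycle"]] * 0.999, length.out = 80)
  for (l in c("F1", "F2", "F3", "F4", "F5")) {
    q1 <- approx(c1$t, c1[[l]], xout = tf, rule = 2)$y
    q2 <- approx(c2$t, c2[[l]], xout = tf, rule = 2)$y
    rel <- sqrt(mean((q1 - q2)^2)) / sqrt(mean(q2^2))
    expect_lt(rel, 0.005)
  }
})

test_that("isolated Windkessel matches its closed-form behaviour", {
  Rp <- 0.05; Rd <- 3.9; Cp <- 0.6; Q0 <- 20
  wk <- simulate_windkessel(Rp, Rd, Cp, inflow = Q0, duration = 40)
  expect_equal(wk$P[nrow(wk)], Q0 * (Rp + Rd), tolerance = 0.005)
  # relaxation: step inflow to zero, fit the exponential decay rate
  wk2 <- simulate_windkessel(Rp, Rd, Cp, inflow = function(t) 0,
                             duration = 4, P0 = 60)
  sel <- wk2$t > 0.2 & wk2$t < 2
  tau_fit <- -1 / coef(lm(log(wk2$Pc[sel]) ~ wk2$t[sel]))[[2]]
  expect_equal(tau_fit, Rd * Cp, tolerance = 0.02)
})
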
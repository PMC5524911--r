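test_that("virtual parameter draws are deterministic and centered", {
  p1 <- sample_parameters(11)
  p2 <- sample_parameters(11)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_false(identical(as.numeric(p1), as.numeric(sample_parameters(12))))
  # jitter = 0 returns the population center (literature values with
  # the cohort-scale pulmonary pressure), up to the drawn cycle length
  # and its onset scaling
  p0 <- sample_parameters(11, jitter = 0)
  lit <- literature_parameters()
  skip_names <- c("onset_la", "onset_lv", "t_cycle", "p_pu")
  for (nm in setdiff(par_names(), skip_names))
    expect_equal(p0[[nm]], lit[[nm]])
  expect_equal(p0[["p_pu"]], 10.8)
  # cycle length spans the cohort heart-rate range
  Ts <- vapply(1:25, function(s) sample_parameters(s)[["t_cycle"]],
               numeric(1))
  expect_true(all(Ts >= 0.73 & Ts <= 1.09))
  # jittered draws stay within +/- 15% of their centers
  expect_true(all(abs(p1[["e_max_lv"]] / 3 - 1) <= 0.15))
  expect_true(all(abs(p1[["c_pia"]] / 0.93 - 1) <= 0.15))
})

test_that("generated measurements are reproducible and self-consistent", {
  vs <- fixture_subject(7, noise_sd = 0)
  m <- vs$meas
  expect_length(m$waveforms$F1$q, 40)
  # bit-exact reproducibility
  m2 <- generate_measurements(vs$truth, noise_sd = 0, n_frames = 40,
                              seed = vs$seed + 10007L)
  expect_identical(m2$waveforms$F4$q, m$waveforms$F4$q)
  expect_identical(m2$SBP, m$SBP)
  # cuff pressures and ESV match the underlying converged cycle
  cyc <- aligned_cycle(vs$truth)
  expect_equal(m$SBP, max(cyc$P_ao))
  expect_equal(m$DBP, min(cyc$P_ao))
  expect_equal(m$ESV, min(cyc$V_LV))
  # noise-free bundle has (numerically) zero residual at the truth
  r <- residual_vector(vs$truth, m, fit_config())
  expect_lt(sum(r^2), 1e-8)
  # noisy bundle differs from the clean one by the requested noise scale
  vsn <- fixture_subject(7, noise_sd = 1)
  d <- vsn$meas$waveforms$F1$q - m$waveforms$F1$q
  expect_equal(sd(d), 1, tolerance = 0.35)
})

test_that("cuff rounding flag produces integer readouts", {
  vs <- fixture_subject(7, noise_sd = 0)
  m <- generate_measurements(vs$truth, noise_sd = 0, seed = 1,
                             round_cuff = TRUE)
  expect_equal(m$SBP, round(m$SBP))
  expect_equal(m$DBP, round(m$DBP))
})

test_that("synthetic velocity planes reproduce the analytic flows", {
  # uniform profile, total area normalized to 1 cm^2 -> flow = peak
  pl <- make_velocity_plane("uniform", peak_v = 100, radius_px = 20,
                            pixel_area = 1)
  area1 <- 1 / sum(pl$mask)
  expect_equal(plane_flow(pl$v_perp, pl$mask, area1), 100)
  # parabolic (Poiseuille) profile carries half the uniform flow
  pp <- make_velocity_plane("parabolic", peak_v = 100, radius_px = 30,
                            pixel_area = 1)
  f30 <- plane_flow(pp$v_perp, pp$mask, 1 / sum(pp$mask))
  expect_equal(f30, 50, tolerance = 0.04)
  # grid refinement shrinks the discretization error
  p10 <- make_velocity_plane("parabolic", peak_v = 100, radius_px = 10,
                             pixel_area = 1)
  f10 <- plane_flow(p10$v_perp, p10$mask, 1 / sum(p10$mask))
  expect_lt(abs(f30 - 50), abs(f10 - 50) + 1e-9)
})

test_that("sampled subjects stay in a physiological pressure range", {
  # measured span of the generator (seeds 1-20): SBP 86-143, DBP 50-88;
  # most subjects fall in the cohort band 90-140 / 45-90
  ps <- t(vapply(1:20, function(s) {
    pressure_summary(aligned_cycle(sample_parameters(s)))
  }, c(SBP = 0, DBP = 0)))
  expect_true(all(ps[, "SBP"] > 80 & ps[, "SBP"] < 145))
  expect_true(all(ps[, "DBP"] > 40 & ps[, "DBP"] < 95))
  in_band <- ps[, "SBP"] > 90 & ps[, "SBP"] < 140 &
    ps[, "DBP"] > 45 & ps[, "DBP"] < 90
  expect_gte(mean(in_band), 0.8)
})
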
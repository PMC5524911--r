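make_wf <- function(loc, q, T = 0.9, n = length(q)) {
  flow_waveform(loc, seq(0, T, length.out = n + 1)[1:n], q, period = T)
}

test_that("plane flow sums velocity times pixel area over the mask", {
  # 2.8 mm isotropic pixels: 0.28 cm x 0.28 cm = 0.0784 cm^2
  v <- matrix(100, 5, 5)
  mask <- matrix(FALSE, 5, 5)
  mask[1:2, 1:5] <- TRUE           # 10 pixels
  expect_equal(plane_flow(v, mask, 0.0784), 78.4)
  # antisymmetry and linearity
  v2 <- v; v2[1, ] <- -100; v2[2, ] <- 100
  mask2 <- mask; mask2[3:5, ] <- FALSE
  expect_equal(plane_flow(v2, mask2, 0.0784), 0)
  expect_equal(plane_flow(2 * v, mask, 0.0784),
               2 * plane_flow(v, mask, 0.0784))
  # additivity over disjoint masks
  m1 <- mask; m1[2, ] <- FALSE
  m2 <- mask; m2[1, ] <- FALSE
  expect_equal(plane_flow(v, m1, 0.0784) + plane_flow(v, m2, 0.0784),
               plane_flow(v, mask, 0.0784))
  expect_warning(res <- plane_flow(v, matrix(FALSE, 5, 5), 0.0784),
                 "empty")
  expect_equal(res, 0)
})

test_that("net volume integrates one cycle with periodic wrap", {
  w <- make_wf("F2", rep(100, 40))
  expect_equal(net_volume(w), 90)
  # full-period sinusoid integrates to zero
  t <- seq(0, 0.9, length.out = 41)[1:40]
  ws <- flow_waveform("F2", t, 50 * sin(2 * pi * t / 0.9), period = 0.9)
  expect_equal(net_volume(ws), 0, tolerance = 1e-9)
  # dense-sampled analytic pulse vs closed form
  tt <- seq(0, 0.9, length.out = 2001)[1:2000]
  q <- ifelse(tt < 0.3, 400 * sin(pi * tt / 0.3)^2, 0)
  wp <- flow_waveform("F2", tt, q, period = 0.9)
  expect_equal(net_volume(wp), 400 * 0.3 / 2, tolerance = 1e-3 * 60)
  expect_equal(net_volume(wp), oracle_net_volume(tt, q, 0.9))
})

test_that("continuity equation for the effective orifice area", {
  expect_equal(eoa_continuity(80, 20), 4)
  expect_equal(eoa_continuity(0, 20), 0)
  expect_equal(eoa_continuity(160, 40), eoa_continuity(80, 20))
  expect_error(eoa_continuity(80, 0), "VTI")
})

test_that("MAP formula is HR-corrected and monotone", {
  expect_equal(map_from_cuff(120, 60, 60), 84.32)
  expect_equal(map_from_cuff(120, 120, 70), 120)
  expect_equal(map_from_cuff(120, 60, 0), 60 + 60 / 3)
  expect_error(map_from_cuff(60, 120, 60), "SBP")
  grid <- expand.grid(SBP = c(100, 120), DBP = c(50, 70), HR = c(50, 90))
  m <- with(grid, map_from_cuff(SBP, DBP, HR))
  expect_true(all(m >= grid$DBP) && all(m <= grid$SBP))
  expect_gt(map_from_cuff(121, 60, 60), map_from_cuff(120, 60, 60))
  expect_gt(map_from_cuff(120, 61, 60), map_from_cuff(120, 60, 60))
  expect_gt(map_from_cuff(120, 60, 61), map_from_cuff(120, 60, 60))
})

test_that("end-systolic pressure estimate applies the 0.9 factor", {
  expect_equal(pes_lv(120, 0), 108)
  expect_equal(pes_lv(120, 10), 117)
  expect_equal(pes_lv(137, 8.3) / (137 + 8.3), 0.9)
})

test_that("branch mean flows come from plane-to-plane differences", {
  F3 <- make_wf("F3", rep(90, 40))
  F4 <- make_wf("F4", rep(60, 40))
  F5 <- make_wf("F5", rep(40, 40))
  expect_equal(branch_mean_flows(F3, F4, F5),
               c(sa = 30, ia = 20, da = 40))
  expect_error(branch_mean_flows(F3, F3, F5), "sa")
})

test_that("measurement bundle validates its inputs", {
  wfs <- list(F1 = make_wf("F1", rep(50, 40)),
              F2 = make_wf("F2", rep(80, 40)),
              F3 = make_wf("F3", rep(70, 40)),
              F4 = make_wf("F4", rep(50, 40)),
              F5 = make_wf("F5", rep(30, 40)))
  m <- subject_measurements(wfs, SBP = 120, DBP = 70, T = 0.9, ESV = 60,
                            A_ao = 5, VTI_av = 20)
  expect_equal(m$HR, 60 / 0.9)
  expect_error(subject_measurements(wfs, SBP = 60, DBP = 70, T = 0.9,
                                    ESV = 60, A_ao = 5, VTI_av = 20),
               "SBP")
  expect_error(subject_measurements(wfs[-2], SBP = 120, DBP = 70, T = 0.9,
                                    ESV = 60, A_ao = 5, VTI_av = 20),
               "five")
  expect_error(subject_measurements(wfs, SBP = 120, DBP = 70, T = 1.2,
                                    ESV = 60, A_ao = 5, VTI_av = 20),
               "2%")
  expect_error(subject_measurements(wfs, SBP = 120, DBP = 70, T = 0.9,
                                    ESV = 60, A_ao = 5), "VTI")
})

test_that("clinical indices are internally consistent", {
  vs <- fixture_subject(7, noise_sd = 0)
  idx <- clinical_indices(vs$meas)
  expect_equal(idx$PP, vs$meas$SBP - vs$meas$DBP)
  expect_equal(idx$SV, net_volume(vs$meas$waveforms$F2))
  expect_equal(idx$CO, idx$SV / vs$meas$T)
  expect_equal(idx$SVR, idx$MAP / idx$CO)
  expect_gt(idx$EF, 0); expect_lt(idx$EF, 1)
  # SV definition: time integral of F2, shared with the continuity EOA
  expect_equal(idx$EOA_av, eoa_continuity(idx$SV, vs$meas$VTI_av))
  # round trip: continuity EOA returns the truth's orifice area
  expect_equal(idx$EOA_av, vs$truth[["eoa_av"]], tolerance = 1e-6)
})

test_that("subject bundle round-trips through disk", {
  vs <- fixture_subject(7, noise_sd = 0)
  d <- tempfile("subj")
  write_subject(vs$meas, d)
  m2 <- read_subject(d)
  expect_equal(m2$SBP, vs$meas$SBP)
  expect_equal(m2$waveforms$F3$q, vs$meas$waveforms$F3$q)
  expect_equal(attr(m2$waveforms$F5, "period"), vs$meas$T)
  # missing waveform file gives a clean error naming the location
  unlink(file.path(d, "f3.csv"))
  expect_error(read_subject(d), "F3")
  unlink(d, recursive = TRUE)
})
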
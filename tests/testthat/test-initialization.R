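test_that("initial maximal LV elastance follows the end-systolic relation", {
  expect_equal(emax_lv_initial(90, 60, 10), 1.8)
  expect_equal(emax_lv_initial(90, 60, 0), 1.5)
  expect_error(emax_lv_initial(90, 60, 60), "ESV")
})

test_that("distal resistances from MAP and branch flows; SVR closure exact", {
  idx <- structure(list(MAP = 90, CO = 90 / 1.0, SVR = 1.0, PP = 50,
                        SV = 80), class = "clpm_indices")
  bm <- c(sa = 18, ia = 12, da = 60)
  segs <- literature_parameters()
  res <- systemic_resistances(idx, bm, segments = segs)
  expect_equal(res[["r_dsa"]],
               90 / 18 - sqrt(segs[["l_aa"]] / segs[["c_aa"]]))
  # characteristic impedance of the feeding segment
  expect_equal(res[["r_psa"]], sqrt(segs[["l_aa"]] / segs[["c_aa"]]))
  expect_equal(res[["r_pda"]], sqrt(segs[["l_da"]] / segs[["c_da"]]))
  # after closure the network DC resistance equals the target SVR
  r_net <- segs[["r_aa"]] +
    1 / (1 / (res[["r_psa"]] + res[["r_dsa"]]) +
         1 / (res[["r_pia"]] + res[["r_dia"]]) +
         1 / (segs[["r_da"]] + res[["r_pda"]] + res[["r_dda"]]))
  expect_equal(r_net, idx$SVR, tolerance = 1e-9)
  expect_error(closure_r_dda(0.02, r_aa = 0.04, r_da = 0.04,
                             r_psa = 0.05, r_dsa = 4, r_pia = 0.05,
                             r_dia = 3, r_pda = 0.05),
               "infeasible")
})

test_that("hand-arithmetic example: MAP 90, mean branch flow 18, Rp 0.05", {
  expect_equal(90 / 18 - 0.05, 4.95)
  idx <- structure(list(MAP = 90, CO = 90, SVR = 1, PP = 50, SV = 80),
                   class = "clpm_indices")
  segs <- model_parameters(c(l_aa = 2.5e-4, c_aa = 0.1))  # sqrt(L/C)=0.05
  res <- systemic_resistances(idx, c(sa = 18, ia = 12, da = 60),
                              segments = segs)
  expect_equal(res[["r_dsa"]], 4.95)
})

test_that("peripheral compliances apportion SV/PP by branch flow", {
  idx <- structure(list(MAP = 90, CO = 90, SVR = 1, PP = 54, SV = 81),
                   class = "clpm_indices")
  bm <- c(sa = 18, ia = 12, da = 60)
  com <- peripheral_compliances(idx, bm, c_aa = 0.1, c_da = 0.1)
  expect_equal(com[["c_tot"]], 1.5)
  # closure: compliances sum to the target when the floor is inactive
  expect_equal(com[["c_psa"]] + com[["c_pia"]] + com[["c_pda"]] +
                 0.1 + 0.1, com[["c_tot"]])
  # doubling PP halves the total
  idx2 <- idx; idx2$PP <- 108
  expect_equal(peripheral_compliances(idx2, bm)[["c_tot"]], 0.75)
  # floor engages instead of producing a non-positive compliance
  expect_equal(closure_c_pda(1, 0.6, 0.5, 0.1, 0.1), 0.1)
})

test_that("single-beat V0 estimate degrades gracefully in this world", {
  # the human-calibrated single-beat regression underestimates Ees for
  # these high-EF virtual subjects, so the clamp engages and is flagged
  vs <- fixture_subject(7, noise_sd = 0)
  sb <- v0_lv_single_beat(vs$meas)
  expect_true(is.finite(sb$ees) && sb$ees > 0)
  expect_gte(sb$v0_lv, 1)
  expect_lte(sb$v0_lv, vs$meas$ESV / 2)
  expect_gt(sb$tNd, 0); expect_lt(sb$tNd, 0.5)
})

test_that("full initialization is complete, deterministic and in-bounds", {
  vs <- fixture_subject(7, noise_sd = 0)
  init <- build_initial_parameters(vs$meas)
  expect_s3_class(init$params0, "clpm_parameters")
  # deterministic and idempotent
  init2 <- build_initial_parameters(vs$meas)
  expect_identical(as.numeric(init$params0), as.numeric(init2$params0))
  # every parameter has a provenance tag
  expect_setequal(names(init$provenance), par_names())
  expect_equal(unname(init$provenance[c("r_dda", "c_pda")]),
               c("closure", "closure"))
  # measured values land where they should
  expect_equal(init$params0[["t_cycle"]], vs$meas$T)
  expect_equal(init$params0[["a_ao"]], vs$meas$A_ao)
  expect_equal(init$params0[["eoa_av"]], vs$truth[["eoa_av"]],
               tolerance = 1e-6)
  # pulmonary segment pinned to literature
  lit <- literature_parameters()
  for (nm in c("r_pu", "r_pv", "l_pv", "r_pvc", "c_pvc"))
    expect_equal(init$params0[[nm]], lit[[nm]])
  expect_equal(init$params0[["rho"]], 1.06)
  # E_max initialization in the physiological band
  expect_gt(init$params0[["e_max_lv"]], 1)
  expect_lt(init$params0[["e_max_lv"]], 3.5)
  # the initial guess sits inside its own optimization bounds
  b <- make_bounds(init$params0)
  v <- as.numeric(init$params0[b$name])
  expect_true(all(v >= b$lo & v <= b$hi))
})

test_that("initial model reproduces the cuff MAP within 15%", {
  vs <- fixture_subject(7, noise_sd = 0)
  init <- build_initial_parameters(vs$meas)
  cyc <- aligned_cycle(init$params0)
  map_model <- mean(cyc$P_ao)
  map_cuff <- init$indices$MAP
  expect_lt(abs(map_model - map_cuff) / map_cuff, 0.15)
})
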
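# Virtual-subject generator: ground-truth parameter sets and the
# synthetic measurement bundles the personalization pipeline consumes.

# Run `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a ground-truth parameter set for a virtual subject
#'
#' Non-fixed parameters are drawn log-uniformly within `+/- jitter` of
#' their population center; the fixed set stays at the literature
#' values.  The cycle length is drawn uniformly over 0.73-1.09 s (heart
#' rates 55-82 bpm, the span of the emulated cohort).  Two centers
#' deviate from the plain literature column: the pulmonary source
#' pressure is centered at the cohort-scale 10.8 mmHg (the generic 7.4
#' under-fills the heart and produces hypotensive subjects), and the
#' contraction onsets are drawn on cycle-length-proportional scales (LV
#' onset uniform in -0.06..-0.02 s, atrial onset at 93-95% of the
#' cycle) so both can be recovered multiplicatively.
#'
#' @param seed Integer seed; the draw is deterministic per seed.
#' @param jitter Relative half-width of the log-uniform draws
#'   (default 0.15).
#' @return A `clpm_parameters` object.
#' @export
sample_parameters <- function(seed, jitter = 0.15) {
  stopifnot(jitter >= 0, jitter < 1)
  with_seed(seed, {
    lit <- literature_parameters()
    roles <- attr(lit, "roles")
    center <- as.numeric(lit[par_names()])
    names(center) <- par_names()
    center["p_pu"] <- 10.8
    T <- runif(1, 0.73, 1.09)
    vals <- center
    vals["t_cycle"] <- T
    jit <- function(x, n = length(x))
      x * exp(runif(n, log(1 - jitter), log(1 + jitter)))
    vary <- names(roles)[roles != "fixed"]
    vary <- setdiff(vary, c("onset_la", "onset_lv"))
    vals[vary] <- jit(center[vary])
    vals["onset_la"] <- runif(1, 0.93, 0.95) * T
    vals["onset_lv"] <- runif(1, -0.06, -0.02)
    if (jitter == 0) {
      vals[vary] <- center[vary]
      vals["onset_la"] <- 0.94 * T
      vals["onset_lv"] <- -0.04
    }
    model_parameters(vals)
  })
}

#' Generate a synthetic measurement bundle from a ground truth
#'
#' Simulates the truth to its periodic regime, samples the five model
#' flow waveforms at `n_frames` uniform times over the final cycle
#' (emulating retrospectively gated reconstruction), adds i.i.d.
#' Gaussian noise of SD `noise_sd` to the flows, and reads the remaining
#' measurements off the simulation: cuff SBP/DBP as the extrema of the
#' aortic root pressure (optionally rounded to integer mmHg to emulate a
#' cuff readout), ESV as the minimum LV volume, and an aortic-valve VTI
#' consistent with the continuity equation given the truth's orifice
#' area and the noise-free sampled stroke volume.
#'
#' @param truth A `clpm_parameters` ground truth.
#' @param noise_sd Flow noise SD (mL/s).
#' @param n_frames Frames per cycle (default 40).
#' @param seed Integer seed for the noise draws.
#' @param round_cuff Round SBP/DBP to whole mmHg.
#' @param duration,dt Simulation settings (s).
#' @return A `clpm_measurements` bundle.
#' @export
generate_measurements <- function(truth, noise_sd = 1, n_frames = 40,
                                  seed = 1, round_cuff = FALSE,
                                  duration = 20, dt = 1e-3) {
  T <- truth[["t_cycle"]]
  # whole number of cycles: the final-cycle window then starts at the
  # R-wave, which is where frame 1 of a gated reconstruction sits
  duration <- T * floor(duration / T)
  sim <- simulate_circulation(truth, duration = duration, dt = dt,
                              store_from = duration - 2 * T)
  cyc <- extract_last_cycle(sim, T = T)
  # periodicity guard: the net LV volume change over the cycle must be
  # a small fraction of the stroke volume
  sv_model <- sum(cyc$F2) * dt
  dv <- abs(cyc$V_LV[nrow(cyc)] - cyc$V_LV[1])
  if (dv > 0.02 * sv_model)
    stop("simulation not periodic at the end of the run (|dV| = ",
         signif(dv, 3), " mL)")
  tf <- seq(0, T, length.out = n_frames + 1)[seq_len(n_frames)]
  clean <- lapply(c("F1", "F2", "F3", "F4", "F5"), function(l)
    approx(cyc$t, cyc[[l]], xout = tf, rule = 2)$y)
  names(clean) <- c("F1", "F2", "F3", "F4", "F5")
  noisy <- with_seed(seed, lapply(clean, function(q)
    q + rnorm(length(q), 0, noise_sd)))
  wfs <- lapply(names(noisy), function(l)
    flow_waveform(l, tf, noisy[[l]], period = T))
  names(wfs) <- names(noisy)
  ps <- pressure_summary(cyc)
  sbp <- ps[["SBP"]]; dbp <- ps[["DBP"]]
  if (round_cuff) { sbp <- round(sbp); dbp <- round(dbp) }
  # stroke volume of the noise-free sampled waveform, with periodic wrap
  f2c <- clean$F2
  sv <- sum(0.5 * (f2c[-1] + f2c[-n_frames]) * diff(tf)) +
    0.5 * (f2c[n_frames] + f2c[1]) * (T - tf[n_frames])
  subject_measurements(wfs, SBP = sbp, DBP = dbp, T = T,
                       ESV = min(cyc$V_LV), A_ao = truth[["a_ao"]],
                       VTI_av = sv / truth[["eoa_av"]])
}

#' Create a complete virtual subject
#'
#' Convenience wrapper: draws a ground truth ([sample_parameters()]) and
#' generates its measurement bundle ([generate_measurements()]).  The
#' measurement noise seed is derived deterministically from `seed`.
#'
#' @param seed Integer seed.
#' @param jitter Parameter jitter of the truth draw.
#' @param noise_sd Flow noise SD (mL/s).
#' @param n_frames Frames per cycle.
#' @param round_cuff Round the cuff pressures to whole mmHg.
#' @return List of class `clpm_subject` with `truth`, `meas`,
#'   `noise_sd`, `n_frames`, `seed`.
#' @export
virtual_subject <- function(seed, jitter = 0.15, noise_sd = 1,
                            n_frames = 40, round_cuff = FALSE) {
  truth <- sample_parameters(seed, jitter = jitter)
  meas <- generate_measurements(truth, noise_sd = noise_sd,
                                n_frames = n_frames,
                                seed = seed + 10007L,
                                round_cuff = round_cuff)
  structure(list(truth = truth, meas = meas, noise_sd = noise_sd,
                 n_frames = n_frames, seed = seed),
            class = "clpm_subject")
}

#' Synthetic through-plane velocity grid
#'
#' Builds a circular vessel cross-section on a pixel grid with a uniform
#' or parabolic (Poiseuille) velocity profile, as a fixture for the
#' plane-flow quantification: the continuum parabolic profile carries
#' half the flow of a uniform one at the same peak velocity.
#'
#' @param profile `"uniform"` or `"parabolic"`.
#' @param peak_v Peak velocity (cm/s).
#' @param radius_px Vessel radius in pixels (>= 1).
#' @param pixel_area Pixel area (cm^2).
#' @return List with `v_perp` (matrix, cm/s), `mask` (logical matrix)
#'   and `pixel_area`.
#' @export
make_velocity_plane <- function(profile = c("uniform", "parabolic"),
                                peak_v, radius_px, pixel_area) {
  profile <- match.arg(profile)
  stopifnot(radius_px >= 1, pixel_area > 0)
  n <- 2 * ceiling(radius_px) + 3
  ctr <- (n + 1) / 2
  ix <- matrix(rep(seq_len(n), each = n), n)
  iy <- matrix(rep(seq_len(n), times = n), n)
  r2 <- ((ix - ctr)^2 + (iy - ctr)^2) / radius_px^2
  mask <- r2 <= 1
  v <- if (profile == "uniform") peak_v * mask
       else peak_v * pmax(0, 1 - r2) * mask
  list(v_perp = v, mask = mask, pixel_area = pixel_area)
}
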
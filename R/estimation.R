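# Stage-two estimation: weighted least squares on the five flow
# waveforms with a bounds-respecting Levenberg-Marquardt optimizer.

#' Configuration for the waveform fit
#'
#' @param bounds_factors Per-class multiplicative bound factors around
#'   the initial value: resistances and chamber parameters `[1/2, 2]`,
#'   inertances `[1/5, 5]`, compliances `[1/6, 6]`, narrow parameters
#'   `[0.9, 1.1]`.  Onset parameters use additive bounds of
#'   `+/- onset_halfwidth * T` instead.
#' @param termination_rel_change Stop when every parameter changes by
#'   less than this relative amount between consecutive accepted
#'   iterations (default 0.1%).
#' @param max_iterations Cap on accepted LM iterations.
#' @param sigma Measurement noise SD (mL/s) weighting the residuals.
#' @param dt,duration Inner simulation settings (s).
#' @param onset_halfwidth Half-width of onset bounds, as a fraction of
#'   the cycle length.
#' @param penalty Residual value substituted when an inner simulation
#'   diverges (keeps the optimizer alive instead of erroring).
#' @param jac_step Forward-difference step in the transformed
#'   (unbounded) parameter space.  Deliberately coarse (1e-2): valve
#'   events quantize on the solver grid, so tiny steps measure grid
#'   noise instead of the derivative.
#' @param smooth_stages Optional graduated-smoothing continuation (see
#'   [fit_config_robust()]): moving-average window widths (frames),
#'   widest first, applied to the residuals in preliminary LM stages.
#'   Empty (default) runs the plain single LM solve.
#' @param stage_max_iterations,stage_term_rel Iteration cap and
#'   termination for each smoothing stage.
#' @param restarts Maximum number of LM passes on the raw cost; passes
#'   stop early when the cost improves by less than 2%.
#' @param seed Optional integer recorded with the fit.
#' @return List of class `clpm_fit_config`.
#' @export
fit_config <- function(bounds_factors = list(resistance = c(0.5, 2),
                                             inertance = c(0.2, 5),
                                             compliance = c(1 / 6, 6),
                                             heart = c(0.5, 2),
                                             narrow = c(0.9, 1.1)),
                       termination_rel_change = 1e-3,
                       max_iterations = 40,
                       sigma = 1,
                       dt = 1e-3, duration = 20,
                       onset_halfwidth = 0.15,
                       penalty = 1e6,
                       jac_step = 1e-2,
                       smooth_stages = integer(0),
                       stage_max_iterations = 20,
                       stage_term_rel = 1e-4,
                       restarts = 1,
                       seed = NULL) {
  stopifnot(termination_rel_change > 0, sigma > 0, dt > 0, duration > 0,
            restarts >= 1)
  for (f in bounds_factors) stopifnot(f[1] < 1, f[2] > 1)
  structure(list(bounds_factors = bounds_factors,
                 termination_rel_change = termination_rel_change,
                 max_iterations = max_iterations, sigma = sigma,
                 dt = dt, duration = duration,
                 onset_halfwidth = onset_halfwidth,
                 penalty = penalty, jac_step = jac_step,
                 smooth_stages = smooth_stages,
                 stage_max_iterations = stage_max_iterations,
                 stage_term_rel = stage_term_rel,
                 restarts = restarts, seed = seed),
            class = "clpm_fit_config")
}

#' Robust fit configuration (graduated smoothing continuation)
#'
#' The waveform cost is multi-modal in the timing parameters: when the
#' starting point is far from the optimum (e.g. a strongly perturbed
#' initial guess), plain Levenberg-Marquardt phase-locks the sharp
#' mitral E-wave onto the wrong feature and stalls in a local minimum.
#' This preset runs a continuation: the residuals are smoothed with a
#' circular moving average (identically on data and model, so the
#' optimum is unchanged for a perfect fit) with successively narrower
#' windows, each stage warm-starting the next, before the untouched
#' cost is polished with restart-to-plateau LM passes.
#'
#' @param smooth_stages Moving-average window widths in frames, widest
#'   first.
#' @param duration Inner simulation horizon (s); 12 s keeps the
#'   periodicity error of the final cycle negligible at roughly half
#'   the cost of the full 20 s.
#' @param restarts Maximum raw-cost LM passes.
#' @param ... Passed to [fit_config()].
#' @return A `clpm_fit_config`.
#' @export
fit_config_robust <- function(smooth_stages = c(15, 9, 5, 3),
                              duration = 12, restarts = 6, ...) {
  fit_config(smooth_stages = smooth_stages, duration = duration,
             restarts = restarts, ...)
}

#' Optimization bounds around an initial parameter set
#'
#' Class-based intervals around the stage-one values: see
#' [fit_config()].  Fixed and closure parameters get no bounds (they are
#' not optimized).
#'
#' @param p0 A `clpm_parameters` object (with role tags).
#' @param cfg A `clpm_fit_config`.
#' @return data.frame with columns `name`, `lo`, `hi`, rows covering the
#'   optimized (free + narrow) parameters.
#' @export
make_bounds <- function(p0, cfg = fit_config()) {
  roles <- attr(p0, "roles")
  cls <- par_classes()
  opt <- names(roles)[roles %in% c("free", "narrow")]
  lo <- hi <- setNames(numeric(length(opt)), opt)
  T <- p0[["t_cycle"]]
  for (nm in opt) {
    v <- p0[[nm]]
    if (cls[[nm]] == "onset") {
      w <- cfg$onset_halfwidth * T
      lo[nm] <- v - w; hi[nm] <- v + w
    } else {
      f <- if (roles[[nm]] == "narrow") cfg$bounds_factors$narrow
           else cfg$bounds_factors[[cls[[nm]]]]
      if (is.null(f)) stop("no bound factors for class ", cls[[nm]])
      if (v <= 0)
        stop("parameter ", nm, " must be > 0 to build multiplicative bounds")
      lo[nm] <- v * f[1]; hi[nm] <- v * f[2]
    }
  }
  data.frame(name = opt, lo = unname(lo), hi = unname(hi),
             stringsAsFactors = FALSE)
}

#' Re-impose the closure constraints on a parameter set
#'
#' `r_dda` is recomputed so the network DC resistance equals the target
#' SVR, and `c_pda` so the total arterial compliance equals the target;
#' called at every cost evaluation so the closure parameters track the
#' optimized ones.
#'
#' @param p A `clpm_parameters` object.
#' @param targets List with `SVR` and `c_tot` (from
#'   [build_initial_parameters()]).
#' @return `p` with updated `r_dda`, `c_pda`.
#' @export
apply_closure <- function(p, targets) {
  p[["r_dda"]] <- closure_r_dda(targets$SVR,
                                r_aa = p[["r_aa"]], r_da = p[["r_da"]],
                                r_psa = p[["r_psa"]], r_dsa = p[["r_dsa"]],
                                r_pia = p[["r_pia"]], r_dia = p[["r_dia"]],
                                r_pda = p[["r_pda"]])
  p[["c_pda"]] <- closure_c_pda(targets$c_tot, p[["c_psa"]], p[["c_pia"]],
                                p[["c_aa"]], p[["c_da"]])
  p
}

#' Weighted residual vector of a parameter set against measurements
#'
#' Simulates the model, extracts the final (converged) cycle,
#' interpolates the model flows F1-F5 onto the measurement time grid and
#' returns `(Q_meas - Q_model) / sigma` stacked over the five locations.
#' If the simulation diverges the residuals are replaced by a large
#' penalty value and flagged, so an outer optimizer can back off rather
#' than abort.
#'
#' @param p A `clpm_parameters` object.
#' @param meas A `clpm_measurements` bundle.
#' @param cfg A `clpm_fit_config`.
#' @return Numeric vector of length `5 N` with attribute `penalized`.
#'   The sum of squares of this vector is the fit cost J.
#' @export
residual_vector <- function(p, meas, cfg = fit_config()) {
  # integrate a whole number of cycles so the final-cycle window starts
  # at the R-wave (t = 0 mod T), matching the frame convention of the
  # measured waveforms
  T <- p[["t_cycle"]]
  dur <- T * floor(cfg$duration / T)
  sim <- tryCatch(
    simulate_circulation(p, duration = dur, dt = cfg$dt,
                         store_from = dur - 2 * T),
    error = function(e) NULL)
  n <- sum(vapply(meas$waveforms, nrow, integer(1)))
  if (is.null(sim)) {
    r <- rep(cfg$penalty, n)
    attr(r, "penalized") <- TRUE
    return(r)
  }
  cyc <- extract_last_cycle(sim, T = p[["t_cycle"]])
  out <- numeric(0)
  for (l in c("F1", "F2", "F3", "F4", "F5")) {
    w <- meas$waveforms[[l]]
    qm <- approx(cyc$t, cyc[[l]], xout = w$t, rule = 2)$y
    out <- c(out, (w$q - qm) / cfg$sigma)
  }
  attr(out, "penalized") <- FALSE
  out
}

# Circular moving average of width k applied per waveform block of a
# stacked residual vector.  Applying the same linear smoother to data
# and model (equivalently, to their difference) leaves a perfect fit at
# zero cost while widening the basins of the sharp flow features.
smooth_residual <- function(r, block_len, k) {
  if (k <= 1) return(r)
  att <- attr(r, "penalized")
  out <- r
  off <- 0L
  for (n in block_len) {
    q <- r[(off + 1):(off + n)]
    idx <- outer(seq_len(n) - (k %/% 2) - 1L, 0:(k - 1L), `+`) %% n + 1L
    out[(off + 1):(off + n)] <- rowMeans(matrix(q[idx], nrow = n))
    off <- off + n
  }
  attr(out, "penalized") <- att
  out
}

# --- bounded Levenberg-Marquardt -------------------------------------

# sine transform between the bounded parameter space and an unbounded
# internal space: p = lo + (hi - lo) (sin u + 1) / 2
.to_internal <- function(p, lo, hi) {
  z <- 2 * (p - lo) / (hi - lo) - 1
  asin(pmin(1, pmax(-1, z)))
}
.to_external <- function(u, lo, hi) lo + (hi - lo) * (sin(u) + 1) / 2

# Generic damped least squares in the transformed space.  `resid_fun`
# maps a named external parameter vector to a residual vector.
lm_bounded <- function(resid_fun, p0, lo, hi, max_iter = 40,
                       term_rel = 1e-3, jac_step = 1e-4,
                       lambda0 = 1e-3, scale_ref = NULL,
                       step_max = 0.5) {
  nm <- names(p0)
  u <- .to_internal(p0, lo, hi)
  p <- .to_external(u, lo, hi)
  r <- resid_fun(p)
  J <- sum(r^2)
  lambda <- lambda0
  n_iter <- 0L
  converged <- FALSE
  cost_hist <- J
  if (is.null(scale_ref)) scale_ref <- pmax(abs(p0), 1e-12)
  while (n_iter < max_iter) {
    # forward-difference Jacobian in u-space
    A <- matrix(0, length(r), length(u))
    for (j in seq_along(u)) {
      uj <- u
      uj[j] <- uj[j] + jac_step
      rj <- resid_fun(.to_external(uj, lo, hi))
      A[, j] <- (rj - r) / jac_step
    }
    H <- crossprod(A)
    g <- crossprod(A, r)
    dH <- pmax(diag(H), 1e-10 * max(diag(H), 1e-300))
    accepted <- FALSE
    rel_attempt <- Inf
    while (lambda < 1e12) {
      step <- tryCatch(
        solve(H + lambda * diag(dH, nrow = length(dH)), -g),
        error = function(e) NULL)
      # trust-region safeguard: the waveform cost is multi-modal in the
      # timing parameters, and structurally flat parameters make the
      # Gauss-Newton step unbounded along their directions, so each
      # component is clamped to +/- step_max in the transformed space
      if (!is.null(step))
        step <- pmin(pmax(as.numeric(step), -step_max), step_max)
      if (!is.null(step)) {
        u_new <- u + as.numeric(step)
        p_new <- .to_external(u_new, lo, hi)
        r_new <- resid_fun(p_new)
        J_new <- sum(r_new^2)
        rel_attempt <- min(rel_attempt, max(abs(p_new - p) / scale_ref))
        if (is.finite(J_new) && J_new < J) {
          rel <- max(abs(p_new - p) / scale_ref)
          u <- u_new
          r <- r_new
          J <- J_new
          p <- p_new
          accepted <- TRUE
          n_iter <- n_iter + 1L
          cost_hist <- c(cost_hist, J)
          # a sub-0.1% step only signals convergence when taken under
          # weak damping: heavily damped steps are small because they
          # are cautious, not because the optimum is reached
          if (rel < term_rel && lambda <= 1) converged <- TRUE
          lambda <- max(lambda / 3, 1e-12)
          break
        }
      }
      lambda <- lambda * 4
    }
    if (!accepted) {
      # no acceptable step at any damping; if even the attempted steps
      # were below the termination size we are at a local optimum to
      # within the termination precision
      if (rel_attempt < term_rel) converged <- TRUE
      break
    }
    if (converged) break
  }
  list(par = setNames(p, nm), cost = J, n_iter = n_iter,
       converged = converged, cost_history = cost_hist, residual = r)
}

#' Fit the model to a subject's flow waveforms
#'
#' Stage two of the personalization: bounded Levenberg-Marquardt
#' minimization of the weighted sum of squared differences between the
#' measured and model flow waveforms at F1-F5, over the free parameters
#' (class bounds) and the narrow parameters (+/- 10%).  The closure
#' parameters `r_dda`, `c_pda` are recomputed from their constraints at
#' every cost evaluation; fixed parameters never move.  Iteration stops
#' when all parameters change by less than 0.1% between consecutive
#' accepted steps (or `max_iterations`).
#'
#' @param meas A `clpm_measurements` bundle.
#' @param init A `clpm_init` report (see [build_initial_parameters()]),
#'   or a `clpm_parameters` object plus explicit `targets`.
#' @param cfg A `clpm_fit_config`.
#' @param opt_names Optional subset of parameters to optimize (defaults
#'   to all free + narrow); others stay at their `init` values.
#' @param start Optional named vector of starting values overriding
#'   `init` for the optimized parameters.
#' @param bounds Optional bounds data.frame (as from [make_bounds()]);
#'   defaults to bounds built around `init`.
#' @param targets Closure targets; defaults to `init$targets`.
#' @param max_iterations Optional override of `cfg$max_iterations`.
#' @return An object of class `clpm_fit`: list with `params`
#'   (full `clpm_parameters` after closure), `estimates` (optimized
#'   subset), `cost` (final J), `cost_initial`, `n_iter`, `converged`,
#'   `cost_history`, `bounds`, `active_bounds` (parameters within 0.1%
#'   of a bound).
#' @export
fit_model <- function(meas, init, cfg = fit_config(), opt_names = NULL,
                      start = NULL, bounds = NULL, targets = NULL,
                      max_iterations = NULL) {
  p_full <- if (inherits(init, "clpm_init")) init$params0 else init
  if (is.null(targets))
    targets <- if (inherits(init, "clpm_init")) init$targets
               else stop("targets required when init is a bare parameter set")
  roles <- attr(p_full, "roles")
  if (is.null(opt_names))
    opt_names <- names(roles)[roles %in% c("free", "narrow")]
  if (is.null(bounds)) bounds <- make_bounds(p_full, cfg)
  bounds <- bounds[bounds$name %in% opt_names, , drop = FALSE]
  if (!all(opt_names %in% bounds$name))
    stop("bounds missing for: ",
         paste(setdiff(opt_names, bounds$name), collapse = ", "))
  lo <- setNames(bounds$lo, bounds$name)[opt_names]
  hi <- setNames(bounds$hi, bounds$name)[opt_names]
  p0 <- setNames(as.numeric(p_full[opt_names]), opt_names)
  if (!is.null(start)) p0[names(start)] <- pmin(pmax(start, lo[names(start)]),
                                                hi[names(start)])
  T <- p_full[["t_cycle"]]
  scale_ref <- pmax(abs(p0), ifelse(par_classes()[opt_names] == "onset",
                                    T, 0))
  resid_fun <- function(pv) {
    p <- p_full
    p[names(pv)] <- pv
    p <- apply_closure(p, targets)
    residual_vector(p, meas, cfg)
  }
  block_len <- vapply(meas$waveforms, nrow, integer(1))
  r0 <- resid_fun(p0)
  pv <- p0
  # graduated-smoothing continuation stages (see fit_config_robust)
  for (k in cfg$smooth_stages) {
    rf_k <- function(pvec) smooth_residual(resid_fun(pvec), block_len, k)
    st <- lm_bounded(rf_k, pv, lo, hi,
                     max_iter = cfg$stage_max_iterations,
                     term_rel = cfg$stage_term_rel,
                     jac_step = cfg$jac_step, scale_ref = scale_ref)
    pv <- st$par
  }
  # raw-cost LM passes, restarted (fresh Jacobian and damping) until the
  # improvement stalls
  J_prev <- Inf
  res <- NULL
  n_iter_total <- 0L
  cost_hist <- numeric(0)
  for (rs in seq_len(cfg$restarts)) {
    res <- lm_bounded(resid_fun, pv, lo, hi,
                      max_iter = if (is.null(max_iterations))
                        cfg$max_iterations else max_iterations,
                      term_rel = cfg$termination_rel_change,
                      jac_step = cfg$jac_step, scale_ref = scale_ref)
    pv <- res$par
    n_iter_total <- n_iter_total + res$n_iter
    cost_hist <- c(cost_hist, if (length(cost_hist))
      res$cost_history[-1] else res$cost_history)
    if (res$cost > 0.98 * J_prev) break
    J_prev <- res$cost
  }
  res$n_iter <- n_iter_total
  res$cost_history <- cost_hist
  p_hat <- p_full
  p_hat[names(res$par)] <- res$par
  p_hat <- apply_closure(p_hat, targets)
  width <- hi - lo
  at_bound <- names(res$par)[res$par - lo < 1e-3 * width |
                             hi - res$par < 1e-3 * width]
  structure(list(params = p_hat, estimates = res$par,
                 cost = res$cost, cost_initial = sum(r0^2),
                 n_iter = res$n_iter, converged = res$converged,
                 cost_history = res$cost_history,
                 bounds = bounds, targets = targets,
                 active_bounds = at_bound, config = cfg),
            class = "clpm_fit")
}

#' @export
print.clpm_fit <- function(x, ...) {
  cat(sprintf(
    "Waveform fit: J = %.4g (initial %.4g), %d accepted iterations%s\n",
    x$cost, x$cost_initial, x$n_iter,
    if (x$converged) ", converged" else ""))
  if (length(x$active_bounds))
    cat("  at bounds:", paste(x$active_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' Write a fit report to JSON
#'
#' @param fit A `clpm_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  obj <- list(schema = "cardiolpm-fit-1",
              params = as.list(setNames(as.numeric(fit$params[par_names()]),
                                        par_names())),
              estimates = as.list(fit$estimates),
              cost = fit$cost, cost_initial = fit$cost_initial,
              n_iter = fit$n_iter, converged = fit$converged,
              active_bounds = fit$active_bounds,
              bounds = fit$bounds, targets = fit$targets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
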
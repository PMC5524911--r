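# Profile-likelihood identifiability analysis: walk each parameter away
# from its optimum, re-optimizing all others, and classify from the
# shape of the profile.

#' Profile-likelihood configuration
#'
#' @param confidence Confidence level of the interval (default 0.95).
#' @param dj_step_frac Target increase in J per walk step, as a fraction
#'   of the threshold (adaptive step control).
#' @param max_steps Maximum steps per direction.
#' @param range_factor The walk may leave the optimization interval by
#'   this factor on either side, so confidence boundaries just outside
#'   the optimization range are detectable; profiles that stay below
#'   the threshold over the whole extended range are reported as
#'   boundless in that direction.  The reference method walks within
#'   the optimization boundaries, so the default extends them only
#'   moderately.
#' @param min_step_rel,max_step_rel Step-size limits relative to the
#'   parameter scale.
#' @param reopt_max_iter Levenberg-Marquardt iterations allowed per
#'   re-optimization (warm-started from the neighbouring grid point).
#' @param flat_tol_rel Flatness tolerance: a profile whose total
#'   variation is below `flat_tol_rel * max(1, J_min)` is flat, i.e.
#'   structurally non-identifiable.
#' @return List of class `clpm_pl_config`.
#' @export
pl_config <- function(confidence = 0.95, dj_step_frac = 0.1,
                      max_steps = 50, range_factor = 1.5,
                      min_step_rel = 1e-3, max_step_rel = 10,
                      reopt_max_iter = 5, flat_tol_rel = 1e-2) {
  stopifnot(confidence > 0, confidence < 1, dj_step_frac > 0,
            max_steps >= 1, range_factor >= 1)
  structure(list(confidence = confidence, dj_step_frac = dj_step_frac,
                 max_steps = max_steps, range_factor = range_factor,
                 min_step_rel = min_step_rel, max_step_rel = max_step_rel,
                 reopt_max_iter = reopt_max_iter,
                 flat_tol_rel = flat_tol_rel),
            class = "clpm_pl_config")
}

#' Profile-likelihood threshold
#'
#' The pointwise confidence boundary sits where the profiled cost
#' exceeds its minimum by the chi-square quantile with one degree of
#' freedom: `qchisq(confidence, df = 1)` (3.841 at 95%).
#'
#' @param confidence Confidence level in (0, 1).
#' @return Cost increase threshold (dimensionless, for sigma-weighted
#'   squared residuals).
#' @export
pl_threshold <- function(confidence = 0.95) {
  stopifnot(confidence > 0, confidence < 1)
  qchisq(confidence, df = 1)
}

# Walk one direction from the optimum.  `evalJ(theta, state)` returns
# list(J=, state=) where `state` carries warm-start information.
walk_direction <- function(evalJ, theta_opt, J_min, threshold, dir,
                           lo_walk, hi_walk, cfg) {
  scale <- max(abs(theta_opt), 1e-12)
  target <- cfg$dj_step_frac * threshold
  step <- max(cfg$min_step_rel * scale,
              min(cfg$max_step_rel * scale,
                  (hi_walk - lo_walk) / (2 * cfg$max_steps)))
  theta <- theta_opt
  J_prev <- J_min
  grid <- numeric(0)
  Js <- numeric(0)
  state <- NULL
  crossing <- NA_real_
  hit_limit <- FALSE
  for (k in seq_len(cfg$max_steps)) {
    theta_new <- theta + dir * step
    clipped <- FALSE
    if (theta_new < lo_walk) { theta_new <- lo_walk; clipped <- TRUE }
    if (theta_new > hi_walk) { theta_new <- hi_walk; clipped <- TRUE }
    if (dir * (theta_new - theta) <= 0) { hit_limit <- TRUE; break }
    ev <- evalJ(theta_new, state)
    state <- ev$state
    grid <- c(grid, theta_new)
    Js <- c(Js, ev$J)
    if (is.finite(ev$J) && ev$J >= J_min + threshold) {
      # linear interpolation of the crossing between the last two points
      th0 <- if (length(grid) >= 2) grid[length(grid) - 1] else theta_opt
      J0 <- if (length(grid) >= 2) Js[length(Js) - 1] else J_min
      f <- (J_min + threshold - J0) / (ev$J - J0)
      crossing <- th0 + f * (theta_new - th0)
      break
    }
    dJ <- abs(ev$J - J_prev)
    fac <- if (is.finite(dJ) && dJ > 1e-12) target / dJ else 3
    step <- step * min(3, max(0.3, fac))
    step <- min(max(step, cfg$min_step_rel * scale),
                cfg$max_step_rel * scale)
    theta <- theta_new
    J_prev <- ev$J
    if (clipped) { hit_limit <- TRUE; break }
  }
  list(grid = grid, J = Js, crossing = crossing,
       hit_limit = hit_limit || is.na(crossing))
}

#' Profile a single direction of a generic objective
#'
#' The engine behind [profile_parameter()], exposed so that it can be
#' validated on objectives with known profiles (e.g. quadratic costs).
#' `evalJ(theta, state)` must return `list(J = , state = )`, where
#' `state` is passed along the walk for warm starting.
#'
#' @param evalJ Profiled objective (all other parameters re-optimized
#'   inside).
#' @param theta_opt,J_min Optimum and its cost.
#' @param opt_lo,opt_hi Optimization interval of the parameter.
#' @param cfg A `clpm_pl_config`.
#' @param lo_walk,hi_walk Walk range; defaults to the optimization
#'   interval extended by `cfg$range_factor`.
#' @return An object of class `clpm_profile`: list with `grid`, `J`
#'   (including the optimum point), `J_min`, `threshold`, `ci_lo`,
#'   `ci_hi` (NA when no crossing was found in that direction),
#'   `bounded_lo`, `bounded_hi`, and the ranges.
#' @export
profile_likelihood_curve <- function(evalJ, theta_opt, J_min,
                                     opt_lo, opt_hi, cfg = pl_config(),
                                     lo_walk = NULL, hi_walk = NULL) {
  threshold <- pl_threshold(cfg$confidence)
  span_lo <- theta_opt - opt_lo
  span_hi <- opt_hi - theta_opt
  if (is.null(lo_walk)) lo_walk <- theta_opt - cfg$range_factor * span_lo
  if (is.null(hi_walk)) hi_walk <- theta_opt + cfg$range_factor * span_hi
  up <- walk_direction(evalJ, theta_opt, J_min, threshold, +1,
                       lo_walk, hi_walk, cfg)
  dn <- walk_direction(evalJ, theta_opt, J_min, threshold, -1,
                       lo_walk, hi_walk, cfg)
  grid <- c(rev(dn$grid), theta_opt, up$grid)
  J <- c(rev(dn$J), J_min, up$J)
  structure(list(grid = grid, J = J, J_min = J_min,
                 threshold = threshold,
                 ci_lo = dn$crossing, ci_hi = up$crossing,
                 bounded_lo = !dn$hit_limit, bounded_hi = !up$hit_limit,
                 opt = theta_opt, opt_lo = opt_lo, opt_hi = opt_hi,
                 lo_walk = lo_walk, hi_walk = hi_walk),
            class = "clpm_profile")
}

#' Classify a profile-likelihood curve
#'
#' Applies the three-way classification in order of precedence:
#' a flat profile (total variation below the flatness tolerance) is
#' structurally non-identifiable; a profile with no threshold crossing
#' in at least one direction is practically non-identifiable; a profile
#' whose crossings exist but fall outside the optimization interval is
#' also practically non-identifiable; otherwise the parameter is
#' identifiable.
#'
#' @param curve A `clpm_profile`.
#' @param cfg A `clpm_pl_config` (for the flatness tolerance).
#' @return One of `"identifiable"`, `"practically_nonidentifiable"`,
#'   `"structurally_nonidentifiable"`.
#' @export
classify_profile <- function(curve, cfg = pl_config()) {
  tv <- max(curve$J, na.rm = TRUE) - min(curve$J, na.rm = TRUE)
  if (tv < cfg$flat_tol_rel * max(1, curve$J_min))
    return("structurally_nonidentifiable")
  if (is.na(curve$ci_lo) || is.na(curve$ci_hi))
    return("practically_nonidentifiable")
  if (curve$ci_lo < curve$opt_lo || curve$ci_hi > curve$opt_hi)
    return("practically_nonidentifiable")
  "identifiable"
}

#' Profile likelihood of one model parameter
#'
#' Walks the parameter up and down from its fitted optimum with
#' adaptive steps, re-optimizing all other non-fixed parameters at each
#' grid point (warm-started from the neighbouring point, a limited
#' number of LM iterations per point).  The walk stops at a threshold
#' crossing, the walk-range limit, or `max_steps`.
#'
#' @param name Parameter name (must be among the optimized parameters).
#' @param fit A `clpm_fit` from [fit_model()].
#' @param meas The `clpm_measurements` bundle that produced the fit.
#' @param cfg A `clpm_pl_config`.
#' @param fit_cfg The `clpm_fit_config` used for re-optimization
#'   (defaults to the fit's own).
#' @return A `clpm_profile` (see [profile_likelihood_curve()]), with the
#'   parameter name attached.
#' @export
profile_parameter <- function(name, fit, meas, cfg = pl_config(),
                              fit_cfg = fit$config) {
  b <- fit$bounds
  if (!name %in% b$name)
    stop("parameter ", name, " is not among the optimized parameters")
  opt_lo <- b$lo[b$name == name]
  opt_hi <- b$hi[b$name == name]
  others <- setdiff(b$name, name)
  p_hat <- fit$params
  thr <- pl_threshold(cfg$confidence)
  evalJ <- function(theta, state) {
    start <- if (is.null(state)) setNames(as.numeric(p_hat[others]), others)
             else state
    p_base <- p_hat
    p_base[[name]] <- theta
    refit_once <- function(st, iters) tryCatch(
      fit_model(meas, structure(p_base, roles = attr(p_hat, "roles"),
                                class = "clpm_parameters"),
                cfg = fit_cfg, opt_names = others, start = st,
                bounds = b, targets = fit$targets,
                max_iterations = iters),
      error = function(e) NULL)
    refit <- refit_once(start, cfg$reopt_max_iter)
    if (is.null(refit)) return(list(J = NA_real_, state = state))
    # adaptive escalation: a point that lands in the decision band just
    # above the optimum gets extra re-optimization effort - deeper
    # warm-started rounds plus a fresh start from the central optimum -
    # so apparent small rises are either optimized away (flat
    # direction) or confirmed as genuine
    if (refit$cost > fit$cost + 0.25 * thr &&
        refit$cost - fit$cost < 10 * thr) {
      center <- refit_once(setNames(as.numeric(p_hat[others]), others),
                           2 * cfg$reopt_max_iter)
      if (!is.null(center) && center$cost < refit$cost) refit <- center
      tries <- 0
      while (refit$cost > fit$cost + 0.25 * thr &&
             refit$cost - fit$cost < 10 * thr && tries < 3) {
        deeper <- refit_once(refit$estimates, 3 * cfg$reopt_max_iter)
        if (is.null(deeper)) break
        improved <- deeper$cost < refit$cost - 0.02 * thr
        if (deeper$cost < refit$cost) refit <- deeper
        if (!improved) break
        tries <- tries + 1
      }
    }
    list(J = refit$cost, state = refit$estimates)
  }
  # walk range: the optimization interval widened by range_factor, kept
  # positive for multiplicative-bound parameters
  if (par_classes()[[name]] == "onset") {
    lo_walk <- p_hat[[name]] - cfg$range_factor * (p_hat[[name]] - opt_lo)
    hi_walk <- p_hat[[name]] + cfg$range_factor * (opt_hi - p_hat[[name]])
  } else {
    lo_walk <- opt_lo / cfg$range_factor
    hi_walk <- opt_hi * cfg$range_factor
  }
  curve <- profile_likelihood_curve(evalJ, p_hat[[name]], fit$cost,
                                    opt_lo, opt_hi, cfg,
                                    lo_walk = lo_walk, hi_walk = hi_walk)
  curve$name <- name
  curve
}

#' Identifiability analysis over a set of parameters
#'
#' Profiles each requested parameter and classifies it.  The result is
#' a per-parameter table of estimates, 95% confidence bounds (NA when
#' no crossing was found in that direction) and identifiability class.
#'
#' @param fit A `clpm_fit`.
#' @param meas The measurement bundle behind the fit.
#' @param params `"all"` or a character vector of parameter names.
#' @param cfg A `clpm_pl_config`.
#' @param fit_cfg Re-optimization settings (defaults to the fit's).
#' @param verbose Print one line per parameter as it completes.
#' @return An object of class `clpm_identifiability`: list with `table`
#'   (data.frame: `name`, `estimate`, `ci_lo`, `ci_hi`, `class`) and
#'   `curves` (named list of `clpm_profile`).
#' @export
run_identifiability <- function(fit, meas, params = "all",
                                cfg = pl_config(), fit_cfg = fit$config,
                                verbose = FALSE) {
  nm <- if (identical(params, "all")) fit$bounds$name else params
  curves <- list()
  rows <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    cur <- profile_parameter(nm[i], fit, meas, cfg, fit_cfg)
    cls <- classify_profile(cur, cfg)
    curves[[nm[i]]] <- cur
    rows[[i]] <- data.frame(name = nm[i], estimate = fit$params[[nm[i]]],
                            ci_lo = cur$ci_lo, ci_hi = cur$ci_hi,
                            class = cls, stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("%-12s %s  [%s, %s]", nm[i], cls,
                      signif(cur$ci_lo, 4), signif(cur$ci_hi, 4)))
  }
  structure(list(table = do.call(rbind, rows), curves = curves),
            class = "clpm_identifiability")
}

#' @export
print.clpm_identifiability <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write an identifiability report
#'
#' Writes the classification table as CSV (estimate, confidence bounds,
#' class) and, optionally, the full profile curves as JSON.
#'
#' @param ident A `clpm_identifiability`.
#' @param csv_path Path of the CSV table.
#' @param json_path Optional path for the profile curves.
#' @return `csv_path`, invisibly.
#' @export
write_identifiability_report <- function(ident, csv_path,
                                         json_path = NULL) {
  write.csv(ident$table, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    curves <- lapply(ident$curves, function(cu)
      list(grid = cu$grid, J = cu$J, J_min = cu$J_min,
           threshold = cu$threshold, ci_lo = cu$ci_lo, ci_hi = cu$ci_hi))
    jsonlite::write_json(list(schema = "cardiolpm-pl-1", curves = curves),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(csv_path)
}
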
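#' @useDynLib cardiolpm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx optimize qchisq runif rnorm setNames quantile median
#' @importFrom utils read.csv write.csv modifyList
NULL

# Canonical parameter ordering.  Must mirror the ParIdx enum in
# src/simulate.cpp.
.par_names <- c(
  # pulmonary venous system
  "p_pu", "r_pu", "r_pv", "l_pv", "r_pvc", "c_pvc",
  # left atrium
  "ks_la", "e_min_la", "e_max_la", "v0_la", "m1_la", "m2_la",
  "alpha1_la", "alpha2_la", "r_visc_la", "onset_la",
  # left ventricle
  "ks_lv", "e_min_lv", "e_max_lv", "v0_lv", "m1_lv", "m2_lv",
  "alpha1_lv", "alpha2_lv", "r_visc_lv", "onset_lv",
  # mitral valve
  "r_mv", "l_mv",
  # aortic valve
  "eoa_av", "a_ao", "l_av",
  # ascending aorta segment
  "r_aa", "l_aa", "r_aav", "c_aa",
  # supra-aortic Windkessel
  "r_psa", "r_dsa", "c_psa",
  # intercostal Windkessel
  "r_pia", "c_pia", "r_dia",
  # descending/abdominal aorta segment
  "r_da", "l_da", "r_dav", "c_da",
  # abdominal terminal Windkessel
  "r_pda", "r_dda", "c_pda",
  # globals
  "t_cycle", "rho")

# Bound classes drive the optimization intervals: resistances [p0/2, 2p0],
# inertances [p0/5, 5p0], compliances [p0/6, 6p0], chamber ("heart")
# parameters [p0/2, 2p0].  Contraction onsets can be zero or negative, so
# they get additive intervals of +/- 0.15 T instead.
.par_class <- c(
  p_pu = "heart", r_pu = "resistance", r_pv = "resistance",
  l_pv = "inertance", r_pvc = "resistance", c_pvc = "compliance",
  ks_la = "heart", e_min_la = "heart", e_max_la = "heart", v0_la = "heart",
  m1_la = "heart", m2_la = "heart", alpha1_la = "heart", alpha2_la = "heart",
  r_visc_la = "heart", onset_la = "onset",
  ks_lv = "heart", e_min_lv = "heart", e_max_lv = "heart", v0_lv = "heart",
  m1_lv = "heart", m2_lv = "heart", alpha1_lv = "heart", alpha2_lv = "heart",
  r_visc_lv = "heart", onset_lv = "onset",
  r_mv = "resistance", l_mv = "inertance",
  eoa_av = "area", a_ao = "area", l_av = "inertance",
  r_aa = "resistance", l_aa = "inertance", r_aav = "resistance",
  c_aa = "compliance",
  r_psa = "resistance", r_dsa = "resistance", c_psa = "compliance",
  r_pia = "resistance", c_pia = "compliance", r_dia = "resistance",
  r_da = "resistance", l_da = "inertance", r_dav = "resistance",
  c_da = "compliance",
  r_pda = "resistance", r_dda = "resistance", c_pda = "compliance",
  t_cycle = "time", rho = "density")

# Role partition used by the two-stage estimation:
#   fixed   - measured or literature-assigned, never optimized
#   closure - recomputed from constraints at every cost evaluation
#   narrow  - optimized within +/- 10%
#   free    - optimized within the class interval
.par_roles_default <- local({
  roles <- setNames(rep("free", length(.par_names)), .par_names)
  roles[c("eoa_av", "a_ao", "r_psa", "r_pia", "r_pda", "t_cycle", "rho",
          "r_pu", "r_pv", "l_pv", "r_pvc", "c_pvc")] <- "fixed"
  roles[c("r_dda", "c_pda")] <- "closure"
  roles[c("e_max_lv", "v0_lv", "r_dia", "r_dsa")] <- "narrow"
  roles
})

# Population reference values for a healthy adult; where the literature
# offers several, the value from the original lumped model formulation is
# used.  Proximal Windkessel resistances have no published reference and
# default to the characteristic impedance scale of the feeding segment.
.par_literature <- c(
  p_pu = 7.4, r_pu = 0.01, r_pv = 2e-3, l_pv = 5e-4, r_pvc = 0.01, c_pvc = 4,
  ks_la = 10e-9, e_min_la = 0.08, e_max_la = 0.17, v0_la = 3,
  m1_la = 1.32, m2_la = 13.1, alpha1_la = 0.11, alpha2_la = 0.18,
  r_visc_la = 1e-4, onset_la = 0.85,
  ks_lv = 4e-9, e_min_lv = 0.08, e_max_lv = 3, v0_lv = 10,
  m1_lv = 1.32, m2_lv = 27.4, alpha1_lv = 0.269, alpha2_lv = 0.452,
  r_visc_lv = 1e-4, onset_lv = 0,
  r_mv = 3.75e-3, l_mv = 2e-4,
  eoa_av = 1.69, a_ao = 5, l_av = 4e-4,
  r_aa = 0.04, l_aa = 5e-4, r_aav = 0.01, c_aa = 0.1,
  r_psa = 0.05, r_dsa = 3.9, c_psa = 0.6,
  r_pia = 0.05, c_pia = 0.93, r_dia = 3,
  r_da = 0.04, l_da = 5e-4, r_dav = 0.01, c_da = 0.1,
  r_pda = 0.05, r_dda = 1.2, c_pda = 2,
  t_cycle = 0.9, rho = 1.06)

#' Canonical parameter names of the circulation model
#'
#' The model has 50 parameters: 6 for the pulmonary venous system, 10 for
#' each heart chamber, 2 for the mitral valve, 3 for the aortic valve, 17
#' for the systemic arterial system, plus the cardiac cycle length
#' `t_cycle` and the blood density `rho`.
#'
#' @return Character vector of length 50, in canonical order.
#' @export
par_names <- function() .par_names

#' Bound class of each model parameter
#'
#' Classes determine the optimization intervals around an initial value
#' p0: `resistance` \[p0/2, 2 p0\], `inertance` \[p0/5, 5 p0\],
#' `compliance` \[p0/6, 6 p0\], `heart` \[p0/2, 2 p0\], `onset`
#' p0 +/- 0.15 T.  `area`, `time` and `density` parameters are never
#' optimized.
#'
#' @return Named character vector over [par_names()].
#' @export
par_classes <- function() .par_class

#' Default estimation role of each parameter
#'
#' @return Named character vector with values in
#'   `c("fixed", "closure", "narrow", "free")`.
#' @export
par_roles <- function() .par_roles_default

#' Construct a full model parameter set
#'
#' @param values Named numeric vector or list; any subset of
#'   [par_names()].  Unspecified parameters take their literature default.
#' @param roles Optional named character vector overriding the default
#'   role partition (see [par_roles()]).
#' @param validate Check invariants (positivity, `eoa_av < a_ao`, ...).
#' @return An object of class `clpm_parameters`: a named numeric vector of
#'   length 50 with a `roles` attribute.
#' @examples
#' p <- model_parameters()
#' p["e_max_lv"]
#' @export
model_parameters <- function(values = NULL, roles = NULL, validate = TRUE) {
  p <- .par_literature
  if (!is.null(values)) {
    values <- unlist(values)
    unknown <- setdiff(names(values), .par_names)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(values)] <- as.numeric(values)
  }
  r <- .par_roles_default
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), .par_names)
    if (length(unknown))
      stop("unknown parameter(s) in roles: ", paste(unknown, collapse = ", "))
    r[names(roles)] <- roles
  }
  obj <- structure(p, roles = r, class = "clpm_parameters")
  if (validate) validate_parameters(obj)
  obj
}

#' Literature (population) parameter set
#'
#' @return A `clpm_parameters` object at the healthy-adult reference
#'   values.
#' @export
literature_parameters <- function() model_parameters()

#' Validate a parameter set
#'
#' Checks positivity of all resistances, inertances, compliances and
#' elastances, the elastance ordering `e_max >= e_min`, the Hill shape
#' constraints `0 < alpha < 1`, and the aortic valve geometry
#' `0 < eoa_av < a_ao`.  Contraction onsets may be negative (they are
#' interpreted modulo the cycle length).
#'
#' @param p A `clpm_parameters` object or named numeric vector.
#' @return Invisibly `p`; errors on violation.
#' @export
validate_parameters <- function(p) {
  stopifnot(all(.par_names %in% names(p)))
  v <- as.numeric(p[.par_names])
  names(v) <- .par_names
  if (any(!is.finite(v))) stop("non-finite parameter value")
  pos <- setdiff(.par_names, c("onset_la", "onset_lv", "ks_la", "ks_lv",
                               "v0_la", "v0_lv"))
  bad <- pos[v[pos] <= 0]
  if (length(bad))
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  if (v["ks_la"] < 0 || v["ks_lv"] < 0) stop("ks coefficients must be >= 0")
  if (v["v0_la"] < 0 || v["v0_lv"] < 0)
    stop("unstressed volumes must be >= 0")
  for (ch in c("la", "lv")) {
    if (v[paste0("e_max_", ch)] < v[paste0("e_min_", ch)])
      stop("e_max_", ch, " must be >= e_min_", ch)
    for (a in c("alpha1_", "alpha2_"))
      if (v[paste0(a, ch)] >= 1)
        stop(a, ch, " must be in (0, 1)")
  }
  if (v["eoa_av"] >= v["a_ao"])
    stop("eoa_av must be < a_ao (pressure recovery undefined otherwise)")
  invisible(p)
}

#' @export
print.clpm_parameters <- function(x, ...) {
  roles <- attr(x, "roles")
  cat("Lumped-parameter circulation model: 50 parameters\n")
  cat(sprintf("  cycle length T = %.3f s, rho = %.2f g/mL\n",
              x[["t_cycle"]], x[["rho"]]))
  tab <- table(roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Read / write parameter sets as JSON
#'
#' The JSON layout has one key per parameter (snake_case, units as in the
#' model description) plus a parallel `"roles"` map.
#'
#' @param p A `clpm_parameters` object.
#' @param path File path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a `clpm_parameters` object.
#' @export
write_parameters <- function(p, path) {
  obj <- as.list(setNames(as.numeric(p[.par_names]), .par_names))
  obj$roles <- as.list(attr(p, "roles"))
  obj$schema <- "cardiolpm-parameters-1"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- NULL
  if (!is.null(obj$roles)) roles <- unlist(obj$roles)
  vals <- unlist(obj[intersect(names(obj), .par_names)])
  model_parameters(vals, roles = roles)
}
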
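# Measurement-side data model: flow waveforms, the non-invasive subject
# bundle, and the clinical index calculators.

#' Construct a single-cycle flow waveform
#'
#' @param location One of `"F1"` (mitral valve), `"F2"` (aortic valve),
#'   `"F3"` (distal ascending aorta), `"F4"` (aortic arch) or `"F5"`
#'   (abdominal aorta).
#' @param t Frame times (s), strictly increasing, spanning one cycle
#'   starting at the R-wave (`t[1] >= 0`, `t[n] < period`).
#' @param q Volumetric flow (mL/s).
#' @param period Cycle length (s).
#' @return A `clpm_waveform` data.frame with columns `t`, `q` and
#'   attributes `location` and `period`.
#' @export
flow_waveform <- function(location, t, q, period) {
  location <- match.arg(location, c("F1", "F2", "F3", "F4", "F5"))
  stopifnot(length(t) == length(q), length(t) >= 4)
  if (any(!is.finite(t)) || any(!is.finite(q)))
    stop("non-finite waveform values")
  if (any(diff(t) <= 0)) stop("waveform times must be strictly increasing")
  if (t[1] < 0 || t[length(t)] >= period)
    stop("waveform must span exactly one cycle: 0 <= t < period")
  structure(data.frame(t = t, q = q),
            location = location, period = period,
            class = c("clpm_waveform", "data.frame"))
}

#' Volumetric flow through a segmented analysis plane
#'
#' Sums through-plane velocity times pixel area over the segmented
#' pixels, the discrete flow quantification used on phase-contrast
#' velocity data (cm/s times cm^2 = cm^3/s = mL/s).
#'
#' @param v_perp Matrix of through-plane velocities (cm/s).
#' @param mask Logical matrix, same shape: pixels inside the vessel
#'   contour.
#' @param pixel_area Area of one pixel (cm^2).
#' @return Flow (mL/s).  An empty mask returns 0 with a warning.
#' @export
plane_flow <- function(v_perp, mask, pixel_area) {
  stopifnot(identical(dim(v_perp), dim(mask)), pixel_area > 0)
  if (!any(mask)) {
    warning("empty segmentation mask; returning zero flow")
    return(0)
  }
  sum(v_perp[mask]) * pixel_area
}

#' Net volume through a waveform over one cycle
#'
#' Trapezoidal integral of `q` over the cycle, with periodic wrap of the
#' final interval (frame times from retrospective gating span exactly one
#' cycle, so the last sample connects back to the first).
#'
#' @param w A `clpm_waveform`.
#' @return Volume (mL).
#' @export
net_volume <- function(w) {
  t <- w$t
  q <- w$q
  if (any(diff(t) <= 0)) stop("waveform times must be strictly increasing")
  period <- attr(w, "period")
  v <- sum(0.5 * (q[-1] + q[-length(q)]) * diff(t))
  # wrap: last frame -> first frame of the next cycle
  v + 0.5 * (q[length(q)] + q[1]) * (period - t[length(t)] + t[1])
}

#' Time-averaged flow of a waveform
#'
#' @param w A `clpm_waveform`.
#' @return Mean flow (mL/s) over the cycle.
#' @export
mean_flow <- function(w) net_volume(w) / attr(w, "period")

#' Effective orifice area by the continuity equation
#'
#' `EOA = SV / VTI`: stroke volume over the velocity-time integral at the
#' valve (mL/cm = cm^2).
#'
#' @param SV Stroke volume (mL), the time integral of aortic-valve flow.
#' @param VTI_av Velocity-time integral (cm).
#' @return Effective orifice area (cm^2).
#' @export
eoa_continuity <- function(SV, VTI_av) {
  if (VTI_av <= 0) stop("VTI_av must be > 0")
  if (SV < 0) stop("SV must be >= 0")
  SV / VTI_av
}

#' Mean arterial pressure from cuff pressures
#'
#' Heart-rate-corrected estimate
#' `MAP = DBP + (1/3 + HR * 0.0012) (SBP - DBP)`; at HR = 0 this reduces
#' to the classic DBP + PP/3 rule.
#'
#' @param SBP,DBP Systolic / diastolic cuff pressure (mmHg).
#' @param HR Heart rate (bpm).
#' @return MAP (mmHg).
#' @export
map_from_cuff <- function(SBP, DBP, HR) {
  if (any(SBP < DBP)) stop("SBP must be >= DBP")
  DBP + (1 / 3 + HR * 0.0012) * (SBP - DBP)
}

#' End-systolic left-ventricular pressure estimate
#'
#' `P_es,LV = 0.9 (SBP + dPav_max)`: the LV systolic pressure is the cuff
#' systolic pressure plus the peak transvalvular gradient, and
#' end-systolic pressure is taken as 90% of systolic.
#'
#' @param SBP Systolic cuff pressure (mmHg).
#' @param dPav_max Peak systolic aortic-valve gradient (mmHg).
#' @return P_es,LV (mmHg).
#' @export
pes_lv <- function(SBP, dPav_max = 0) {
  stopifnot(SBP >= 0, dPav_max >= 0)
  0.9 * (SBP + dPav_max)
}

#' Mean outlet flows of the three arterial branches
#'
#' Mass conservation between the measurement planes gives the
#' time-averaged flow leaving through the supra-aortic vessels
#' (`mean F3 - mean F4`), the intercostal arteries
#' (`mean F4 - mean F5`), and the abdominal terminal bed (`mean F5`).
#'
#' @param F3,F4,F5 `clpm_waveform` objects.
#' @return Named vector `c(sa = , ia = , da = )` (mL/s), all positive.
#' @export
branch_mean_flows <- function(F3, F4, F5) {
  m3 <- mean_flow(F3); m4 <- mean_flow(F4); m5 <- mean_flow(F5)
  out <- c(sa = m3 - m4, ia = m4 - m5, da = m5)
  if (any(out <= 0))
    stop("non-positive branch mean flow (",
         paste(names(out)[out <= 0], collapse = ", "),
         "): inconsistent flow measurements")
  out
}

#' Assemble a subject measurement bundle
#'
#' The non-invasive inputs the personalization consumes: five one-cycle
#' flow waveforms, brachial cuff pressures, cycle length, LV end-systolic
#' volume and aortic valve/root geometry.  Either `VTI_av` or `EOA_av`
#' must be given.
#'
#' @param waveforms Named list with elements `F1`..`F5`
#'   (`clpm_waveform`).
#' @param SBP,DBP Cuff pressures (mmHg), `SBP > DBP > 0`.
#' @param T Cardiac cycle length (s).
#' @param ESV LV end-systolic volume (mL).
#' @param A_ao Aortic cross-sectional area at peak systole (cm^2).
#' @param VTI_av Aortic-valve velocity-time integral (cm); optional if
#'   `EOA_av` given.
#' @param EOA_av Effective orifice area (cm^2); optional if `VTI_av`
#'   given.
#' @return A `clpm_measurements` list, with `HR = 60/T` added.
#' @export
subject_measurements <- function(waveforms, SBP, DBP, T, ESV, A_ao,
                                 VTI_av = NULL, EOA_av = NULL) {
  locs <- c("F1", "F2", "F3", "F4", "F5")
  if (!all(locs %in% names(waveforms)))
    stop("waveforms must contain all five locations F1..F5")
  if (!(SBP > DBP && DBP > 0)) stop("need SBP > DBP > 0")
  stopifnot(T > 0, ESV > 0, A_ao > 0)
  for (l in locs) {
    per <- attr(waveforms[[l]], "period")
    if (abs(per - T) > 0.02 * T)
      stop("waveform ", l, " cycle length differs from T by more than 2%")
  }
  if (is.null(VTI_av) && is.null(EOA_av))
    stop("one of VTI_av or EOA_av is required")
  structure(list(waveforms = waveforms[locs], SBP = SBP, DBP = DBP, T = T,
                 ESV = ESV, A_ao = A_ao, VTI_av = VTI_av, EOA_av = EOA_av,
                 HR = 60 / T),
            class = "clpm_measurements")
}

#' Clinical indices derived from a measurement bundle
#'
#' Computes the index set the initialization consumes: stroke volume (time
#' integral of aortic-valve flow), cardiac output, ejection fraction, mean
#' arterial pressure, pulse pressure, systemic vascular resistance
#' (MAP/CO), the peak aortic-valve gradient (convective term at the
#' measured F2 peak), and the end-systolic LV pressure.
#'
#' @param meas A `clpm_measurements` bundle.
#' @param rho Blood density (g/mL), for the valve gradient.
#' @return List of class `clpm_indices` with elements `MAP`, `PP`, `SV`,
#'   `CO` (mL/s), `EF`, `SVR`, `EOA_av`, `dPav_max`, `Pes_LV`.
#' @export
clinical_indices <- function(meas, rho = 1.06) {
  SV <- net_volume(meas$waveforms$F2)
  CO <- SV / meas$T
  EDV <- meas$ESV + SV
  EF <- SV / EDV
  eoa <- if (!is.null(meas$EOA_av)) meas$EOA_av
         else eoa_continuity(SV, meas$VTI_av)
  qpk <- max(meas$waveforms$F2$q)
  dPav_max <- aortic_gradient(qpk, 0, eoa, meas$A_ao, L_av = 1e-4, rho = rho)
  MAP <- map_from_cuff(meas$SBP, meas$DBP, meas$HR)
  structure(list(MAP = MAP, PP = meas$SBP - meas$DBP, SV = SV, CO = CO,
                 EF = EF, SVR = MAP / CO, EOA_av = eoa,
                 dPav_max = dPav_max, Pes_LV = pes_lv(meas$SBP, dPav_max)),
            class = "clpm_indices")
}

#' Read / write a subject bundle on disk
#'
#' The on-disk layout is one CSV per waveform (columns `t_s`, `q_ml_s`)
#' plus `subject.json` carrying the scalar measurements and relative file
#' paths.
#'
#' @param meas A `clpm_measurements` bundle.
#' @param dir Directory to write into (created if missing).
#' @return `write_subject` returns `dir` invisibly; `read_subject`
#'   returns a `clpm_measurements` bundle.
#' @export
write_subject <- function(meas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (l in names(meas$waveforms)) {
    f <- paste0(tolower(l), ".csv")
    w <- meas$waveforms[[l]]
    write.csv(data.frame(t_s = w$t, q_ml_s = w$q),
              file.path(dir, f), row.names = FALSE)
    files[[l]] <- f
  }
  obj <- list(schema = "cardiolpm-subject-1",
              SBP = meas$SBP, DBP = meas$DBP, T = meas$T, ESV = meas$ESV,
              A_ao = meas$A_ao, VTI_av = meas$VTI_av, EOA_av = meas$EOA_av,
              waveform_files = files)
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))],
                       file.path(dir, "subject.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_subject
#' @export
read_subject <- function(dir) {
  js <- file.path(dir, "subject.json")
  if (!file.exists(js)) stop("no subject.json in ", dir)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  wfs <- list()
  for (l in c("F1", "F2", "F3", "F4", "F5")) {
    f <- obj$waveform_files[[l]]
    if (is.null(f) || !file.exists(file.path(dir, f)))
      stop("missing waveform file for location ", l)
    d <- read.csv(file.path(dir, f))
    wfs[[l]] <- flow_waveform(l, d$t_s, d$q_ml_s, period = obj$T)
  }
  subject_measurements(wfs, SBP = obj$SBP, DBP = obj$DBP, T = obj$T,
                       ESV = obj$ESV, A_ao = obj$A_ao,
                       VTI_av = obj$VTI_av, EOA_av = obj$EOA_av)
}
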
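# Orchestration: configuration, the end-to-end pipeline, and a small
# command-line surface (see inst/cli/cardiolpm).

#' Pipeline run configuration
#'
#' Defaults reproduce the reference computational setup: 1 ms solver
#' step, 20 s horizon, unit measurement-noise weighting, 95%
#' profile-likelihood confidence.
#'
#' @param subject_dir Directory with a subject bundle (see
#'   [read_subject()]); `NULL` to generate a virtual subject.
#' @param out_dir Output directory for reports.
#' @param seed Integer seed governing all randomness of the run.
#' @param synth Options for virtual-subject generation (list with
#'   `jitter`, `noise_sd`, `n_frames`, `round_cuff`).
#' @param fit A `clpm_fit_config`.
#' @param pl A `clpm_pl_config`, or `NULL` to skip identifiability.
#' @param pl_params Parameters to profile (`"all"` or names).
#' @param verbose Emit progress messages.
#' @return List of class `clpm_run_config`.
#' @export
run_config <- function(subject_dir = NULL, out_dir = "cardiolpm_out",
                       seed = 1, synth = list(), fit = fit_config(),
                       pl = NULL, pl_params = "all", verbose = TRUE) {
  synth_def <- list(jitter = 0.15, noise_sd = 1, n_frames = 40,
                    round_cuff = FALSE)
  synth <- modifyList(synth_def, synth)
  structure(list(subject_dir = subject_dir, out_dir = out_dir,
                 seed = as.integer(seed), synth = synth, fit = fit,
                 pl = pl, pl_params = pl_params, verbose = verbose),
            class = "clpm_run_config")
}

#' Run the personalization pipeline
#'
#' Loads (or synthesizes) a subject bundle, builds the stage-one
#' initialization, runs the stage-two waveform fit, writes the fitted
#' final-cycle traces, pressure summary and fit report, and optionally
#' the profile-likelihood identifiability table.  Deterministic given
#' the configuration seed.
#'
#' @param config A `clpm_run_config`.
#' @return Invisibly, a list with `meas`, `init`, `fit`, `summary`, and
#'   (if requested) `identifiability`; all reports are also written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  say <- function(...) if (config$verbose) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "load-subject"
  result <- tryCatch({
    if (is.null(config$subject_dir)) {
      say("synthesizing virtual subject (seed ", config$seed, ")")
      vs <- virtual_subject(config$seed,
                            jitter = config$synth$jitter,
                            noise_sd = config$synth$noise_sd,
                            n_frames = config$synth$n_frames,
                            round_cuff = config$synth$round_cuff)
      meas <- vs$meas
      write_subject(meas, file.path(config$out_dir, "subject"))
      write_parameters(vs$truth, file.path(config$out_dir, "truth.json"))
    } else {
      meas <- read_subject(config$subject_dir)
      vs <- NULL
    }

    stage <- "initialization"
    say("stage one: initialization")
    init <- build_initial_parameters(meas)
    write_init_report(init, file.path(config$out_dir, "init.json"))

    stage <- "fit"
    say("stage two: waveform fit")
    fit <- fit_model(meas, init, cfg = config$fit)
    write_fit_report(fit, file.path(config$out_dir, "fit.json"))

    stage <- "report"
    sim <- simulate_circulation(fit$params, duration = config$fit$duration,
                                dt = config$fit$dt)
    cyc <- extract_last_cycle(sim)
    write.csv(data.frame(t_s = cyc$t, P_LA = cyc$P_LA, P_LV = cyc$P_LV,
                         P_ao = cyc$P_ao, V_LV = cyc$V_LV, F1 = cyc$F1,
                         F2 = cyc$F2, F3 = cyc$F3, F4 = cyc$F4,
                         F5 = cyc$F5),
              file.path(config$out_dir, "cycle.csv"), row.names = FALSE)
    ps <- pressure_summary(cyc)
    loop <- pv_loop(cyc)
    summ <- list(schema = "cardiolpm-summary-1", seed = config$seed,
                 SBP_model = ps[["SBP"]], DBP_model = ps[["DBP"]],
                 SBP_cuff = meas$SBP, DBP_cuff = meas$DBP,
                 stroke_volume = net_volume(meas$waveforms$F2),
                 stroke_work = loop$stroke_work,
                 cost = fit$cost, n_iter = fit$n_iter)
    jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    ident <- NULL
    if (!is.null(config$pl)) {
      stage <- "identifiability"
      say("profile-likelihood analysis")
      ident <- run_identifiability(fit, meas, params = config$pl_params,
                                   cfg = config$pl,
                                   verbose = config$verbose)
      write_identifiability_report(
        ident, file.path(config$out_dir, "identifiability.csv"),
        file.path(config$out_dir, "identifiability.json"))
    }
    list(meas = meas, init = init, fit = fit, summary = summ,
         identifiability = ident, truth = if (!is.null(vs)) vs$truth)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# --- command-line entry ----------------------------------------------

cli_usage <- function() {
  cat("usage: cardiolpm <command> [options]\n",
      "commands:\n",
      "  synth    --seed N --out DIR [--noise-sd X --n-frames N",
      " --jitter X --with-truth]\n",
      "  simulate --params FILE --out DIR [--duration S --dt S]\n",
      "  fit      --subject DIR --out DIR [--duration S --dt S",
      " --sigma X --max-iter N]\n",
      "  pipeline --out DIR [--subject DIR --seed N --profile]\n",
      sep = "")
}

cli_opts <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      out[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `cardiolpm` command-line script
#' (`inst/cli/cardiolpm`): `synth` writes a virtual-subject bundle,
#' `simulate` runs the model from a parameter file, `fit` personalizes
#' against a subject bundle, `pipeline` runs everything.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(1L)) }
  cmd <- args[1]
  o <- cli_opts(args[-1])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  status <- 0L
  switch(cmd,
    synth = {
      seed <- as.integer(num(o$seed, 1))
      vs <- virtual_subject(seed,
                            jitter = num(o$jitter, 0.15),
                            noise_sd = num(o[["noise-sd"]], 1),
                            n_frames = as.integer(num(o[["n-frames"]], 40)))
      dir <- if (is.null(o$out)) "subject" else o$out
      write_subject(vs$meas, dir)
      if (isTRUE(o[["with-truth"]]))
        write_parameters(vs$truth, file.path(dir, "truth.json"))
      message("wrote subject bundle to ", dir)
    },
    simulate = {
      p <- if (is.null(o$params)) literature_parameters()
           else read_parameters(o$params)
      sim <- simulate_circulation(p, duration = num(o$duration, 20),
                                  dt = num(o$dt, 1e-3))
      cyc <- extract_last_cycle(sim)
      dir <- if (is.null(o$out)) "." else o$out
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(data.frame(t_s = cyc$t, P_LA = cyc$P_LA, P_LV = cyc$P_LV,
                           P_ao = cyc$P_ao, V_LV = cyc$V_LV, F1 = cyc$F1,
                           F2 = cyc$F2, F3 = cyc$F3, F4 = cyc$F4,
                           F5 = cyc$F5),
                file.path(dir, "cycle.csv"), row.names = FALSE)
      ps <- pressure_summary(cyc)
      jsonlite::write_json(
        list(SBP_model = ps[["SBP"]], DBP_model = ps[["DBP"]],
             stroke_volume = sum(cyc$F2) * attr(cyc, "dt"),
             stroke_work = pv_loop(cyc)$stroke_work),
        file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      message("wrote simulation output to ", dir)
    },
    fit = {
      if (is.null(o$subject)) stop("fit requires --subject DIR")
      cfg <- run_config(subject_dir = o$subject,
                        out_dir = if (is.null(o$out)) "fit_out" else o$out,
                        fit = fit_config(duration = num(o$duration, 20),
                                         dt = num(o$dt, 1e-3),
                                         sigma = num(o$sigma, 1),
                                         max_iterations =
                                           as.integer(num(o[["max-iter"]],
                                                          40))))
      run_pipeline(cfg)
    },
    pipeline = {
      cfg <- run_config(subject_dir = o$subject,
                        out_dir = if (is.null(o$out)) "pipeline_out"
                                  else o$out,
                        seed = as.integer(num(o$seed, 1)),
                        pl = if (isTRUE(o$profile)) pl_config() else NULL)
      run_pipeline(cfg)
    },
    { cli_usage(); status <- 1L })
  invisible(status)
}
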
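# End-to-end pipeline wiring: events -> reverse correlation -> filter ->
# nonlinearity fit -> prediction -> validation, with stage-named
# diagnostics and plain-text artifacts.

#' Build and validate a pipeline configuration
#'
#' @param stimulus path to the stimulus CSV.
#' @param tracks path to the tracks CSV.
#' @param out_dir directory for artifacts (created if needed).
#' @param validation_stimulus optional path to a second stimulus CSV; if
#'   given, the fitted model's predicted response to it is written too.
#' @param dt expected sample interval (s).
#' @param window filter window (s).
#' @param trial_duration trial duration (s, default 1200).
#' @param n_bins drive bins for the nonlinearity fit.
#' @param alpha significance threshold.
#' @param seed integer seed recorded in provenance (the estimation chain
#'   itself is deterministic).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(stimulus, tracks, out_dir,
                       validation_stimulus = NULL,
                       dt = 0.25, window = 4, trial_duration = 1200,
                       n_bins = 20, alpha = 0.05, seed = 1) {
  for (nm in c("dt", "window", "trial_duration")) {
    check_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (!(alpha > 0 && alpha < 1)) stop_invalid("`alpha` must be in (0, 1)")
  if (n_bins < 3) stop_invalid("`n_bins` must be >= 3")
  structure(
    list(stimulus = stimulus, tracks = tracks, out_dir = out_dir,
         validation_stimulus = validation_stimulus, dt = dt,
         window = window, trial_duration = trial_duration,
         n_bins = n_bins, alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full estimation pipeline
#'
#' Executes, in order: input validation, event extraction, triggered
#' averages and filters for both transition kinds, static-nonlinearity
#' fits, model assembly, prediction (on the validation stimulus when
#' configured, otherwise on the estimation stimulus), and writes every
#' artifact under `config$out_dir`: `events.csv`,
#' `ta_run_to_turn.csv` / `ta_turn_to_run.csv`, `model.json`,
#' `prediction.csv` and `report.json` (stage log, counts of used and
#' excluded events, provenance).  Any stage failure aborts with a
#' stage-named diagnostic.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the fitted `model`, the `report`
#'   list, and paths of all written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stop_invalid("`config` must be a run_config")
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stim <- .stage("read-stimulus", read_stimulus_csv(config$stimulus))
  tracks <- .stage("read-tracks", read_tracks_csv(config$tracks))
  .stage("validate", {
    if (abs(stim$dt - config$dt) > 1e-9) {
      stop_invalid("stimulus dt ", stim$dt, " != configured dt ", config$dt)
    }
    for (tr in tracks) {
      if (abs(tr$dt - stim$dt) > 1e-9) {
        stop_invalid("track ", tr$animal_id, " dt ", tr$dt,
                     " != stimulus dt ", stim$dt)
      }
    }
  })
  say(sprintf("inputs: %d stimulus samples, %d tracks",
              length(stim$values), length(tracks)))

  events <- .stage("events", extract_transitions(tracks))
  ev_path <- file.path(config$out_dir, "events.csv")
  write_events_csv(events, ev_path)
  say(sprintf("events: %d transitions exhibited by %d animals",
              nrow(events), length(unique(events$animal_id))))

  ta_paths <- character()
  tas <- list()
  for (k in .KINDS) {
    tas[[k]] <- .stage(paste0("revcorr-", tolower(k)),
                       triggered_average(events, stim, kind = k,
                                         window = config$window))
    p <- file.path(config$out_dir, sprintf("ta_%s.csv", tolower(k)))
    write_ta_csv(tas[[k]], p)
    ta_paths[k] <- p
    say(sprintf("revcorr %s: %d events used, %d excluded (truncated history)",
                k, tas[[k]]$n_events, tas[[k]]$n_excluded))
  }

  model <- .stage("fit", fit_ln_model(
    tracks, stim, window = config$window,
    trial_duration = config$trial_duration, n_bins = config$n_bins
  ))
  model_path <- file.path(config$out_dir, "model.json")
  write_model_json(model, model_path)
  say(sprintf("fit: R^2 = %.3f (run-to-turn), %.3f (turn-to-run)",
              model$provenance$r_squared$RUN_TO_TURN,
              model$provenance$r_squared$TURN_TO_RUN))

  pred_stim <- if (!is.null(config$validation_stimulus)) {
    .stage("read-validation-stimulus",
           read_stimulus_csv(config$validation_stimulus))
  } else {
    stim
  }
  pred <- .stage("predict", predict_response(model, pred_stim))
  pred_path <- file.path(config$out_dir, "prediction.csv")
  utils::write.csv(pred, pred_path, row.names = FALSE)

  report <- list(
    config = unclass(config),
    n_tracks = length(tracks),
    n_events = stats::setNames(
      lapply(.KINDS, function(k) list(used = tas[[k]]$n_events,
                                      excluded = tas[[k]]$n_excluded)),
      .KINDS),
    burn_in_bins = round(config$window / stim$dt),
    r_squared = model$provenance$r_squared,
    package_version = as.character(utils::packageVersion("optorc"))
  )
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("pipeline complete")

  invisible(list(model = model, report = report,
                 paths = c(events = ev_path, ta_paths, model = model_path,
                           prediction = pred_path, report = report_path)))
}

#' Simulate a demo dataset and run the pipeline on it
#'
#' Generates a Bernoulli stimulus, simulates a population from a named
#' ground truth, writes the input CSVs, and runs [run_pipeline()] over
#' them.  Used by the command-line `demo` subcommand and by the
#' end-to-end tests.
#'
#' @param dir working directory for all files.
#' @param seed integer seed.
#' @param kind ground-truth kind, see [default_ground_truth()].
#' @param n_animals population size.
#' @param duration trial duration in seconds.
#' @param quiet suppress progress messages.
#' @return The [run_pipeline()] result, invisibly.
#' @export
demo_pipeline <- function(dir, seed = 1, kind = "attractive-monophasic",
                          n_animals = 40, duration = 1200, quiet = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stim <- generate_bernoulli(duration, seed = seed)
  truth <- default_ground_truth(kind)
  tracks <- simulate_population(truth, stim, n_animals = n_animals,
                                seed = seed, speed_model = speed_model())
  stim_path <- file.path(dir, "stimulus.csv")
  tracks_path <- file.path(dir, "tracks.csv")
  write_stimulus_csv(stim, stim_path)
  write_tracks_csv(tracks, tracks_path)
  cfg <- run_config(stimulus = stim_path, tracks = tracks_path,
                    out_dir = file.path(dir, "out"), seed = seed)
  run_pipeline(cfg, quiet = quiet)
}
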
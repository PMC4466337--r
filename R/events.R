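# Transition-event extraction and crawling-speed analysis: standard
# scores relative to run-state speed, and deceleration-onset flagging
# before run-to-turn transitions.

#' Extract motor-state transition events from tracks
#'
#' One event per state change, timestamped at the first sample of the
#' new state.  Events of one animal strictly alternate in kind and
#' strictly increase in time.
#'
#' @param tracks a single [state_track()] or a list of them.
#' @return A data.frame with columns `animal_id`, `time_s`, `kind`
#'   (`"RUN_TO_TURN"` / `"TURN_TO_RUN"`).
#' @export
extract_transitions <- function(tracks) {
  if (inherits(tracks, "state_track")) tracks <- list(tracks)
  out <- lapply(tracks, function(tr) {
    if (length(tr$states) < 1L) stop_invalid("empty track")
    if (!all(tr$states %in% .STATES)) {
      stop_invalid("unknown state label in track ", tr$animal_id)
    }
    r <- rle(tr$states)
    if (length(r$lengths) < 2L) {
      return(data.frame(animal_id = character(), time_s = numeric(),
                        kind = character()))
    }
    idx <- cumsum(r$lengths)[-length(r$lengths)] + 1L # first sample of new state
    data.frame(
      animal_id = tr$animal_id,
      time_s = tr$t0 + (idx - 1L) * tr$dt,
      kind = ifelse(r$values[-length(r$values)] == "RUN", .KIND_RT, .KIND_TR)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Standard-score a speed trace
#'
#' Speed expressed in standard deviations away from the animal's mean
#' crawling speed during runs: `(speed - mean_RUN) / sd_RUN`, using the
#' population SD (divide by n) over RUN samples.  The convention is
#' fixed package-wide.
#'
#' @param track a [state_track()] with a speed trace.
#' @return Numeric vector, same length as the track.
#' @export
normalize_speed <- function(track) {
  if (!inherits(track, "state_track")) stop_invalid("`track` must be a state_track")
  if (is.null(track$speed)) stop_invalid("track has no speed trace")
  run <- track$states == "RUN"
  if (sum(run) < 2L) stop_invalid("need at least 2 RUN samples")
  mu <- mean(track$speed[run])
  sd_run <- pop_sd(track$speed[run])
  if (sd_run == 0) stop_degenerate("zero RUN-speed variance")
  (track$speed - mu) / sd_run
}

# centered moving average; width in samples is the nearest odd count
# covering `smooth` seconds
.smooth_speed <- function(x, smooth, dt) {
  hw <- max(1L, round(smooth / (2 * dt)))
  k <- 2L * hw + 1L
  pad <- c(rep(x[1L], hw), x, rep(x[length(x)], hw))
  as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))[(hw + 1L):(hw + length(x))]
}

#' Deceleration onset before a run-to-turn transition
#'
#' Flags when the animal started slowing down: the time, relative to
#' the transition, at which the derivative of the smoothed speed last
#' changed sign from nonnegative to negative and stayed nonpositive up
#' to the event.  The derivative is the first difference of a centered
#' moving average of width `smooth`.  If the speed decreases throughout
#' the window the window start is returned; if there is no negative-
#' derivative epoch at all, a not-found condition is signalled.
#'
#' @param track a [state_track()] with speed.
#' @param event_time time (s) of a RUN_TO_TURN event on the track grid
#'   (the first TURN sample).
#' @param window seconds of history searched before the event (default 2).
#' @param smooth smoothing width in seconds (default 0.5).
#' @return Scalar time offset in seconds, `<= 0`, relative to the event.
#' @export
deceleration_onset <- function(track, event_time, window = 2, smooth = 0.5) {
  if (!inherits(track, "state_track")) stop_invalid("`track` must be a state_track")
  if (is.null(track$speed)) stop_invalid("track has no speed trace")
  check_scalar_number(window, "window", positive = TRUE)
  e <- round((event_time - track$t0) / track$dt) + 1L
  n <- length(track$states)
  if (e < 2L || e > n || track$states[e] != "TURN" || track$states[e - 1L] != "RUN") {
    stop_invalid("`event_time` is not a RUN_TO_TURN transition on this track")
  }
  wn <- round(window / track$dt)
  i_lo <- max(2L, e - wn)
  sm <- .smooth_speed(track$speed, smooth, track$dt)
  d <- sm - c(NA, sm[-n]) # d[i] = sm[i] - sm[i-1]
  win <- i_lo:e
  dw <- d[win]
  if (all(dw >= 0, na.rm = TRUE)) stop_not_found("no deceleration in window")
  nonneg <- which(dw >= 0)
  if (length(nonneg) == 0L) {
    return((i_lo - e) * track$dt) # decreasing throughout: clamp to window start
  }
  cand <- max(nonneg) + 1L
  if (cand > length(win)) stop_not_found("no deceleration epoch reaching the event")
  (win[cand] - e) * track$dt
}

#' Deceleration onsets for every run-to-turn event in a population
#'
#' Applies [deceleration_onset()] to each RUN_TO_TURN event of each
#' track; events without a detectable onset yield `NA`.
#'
#' @inheritParams deceleration_onset
#' @param tracks a list of [state_track()]s with speed.
#' @return A data.frame `animal_id, time_s, onset_s`.
#' @export
deceleration_onsets <- function(tracks, window = 2, smooth = 0.5) {
  if (inherits(tracks, "state_track")) tracks <- list(tracks)
  ev <- extract_transitions(tracks)
  ev <- ev[ev$kind == .KIND_RT, , drop = FALSE]
  by_id <- stats::setNames(tracks, vapply(tracks, `[[`, "", "animal_id"))
  onset <- vapply(seq_len(nrow(ev)), function(i) {
    tryCatch(
      deceleration_onset(by_id[[ev$animal_id[i]]], ev$time_s[i],
                         window = window, smooth = smooth),
      optorc_error = function(e) NA_real_
    )
  }, numeric(1))
  data.frame(animal_id = ev$animal_id, time_s = ev$time_s, onset_s = onset)
}

#' Read and write event CSV files
#'
#' Columns `animal_id, time_s, kind`.
#'
#' @param events event data.frame from [extract_transitions()].
#' @param path file path.
#' @return `read_events_csv()` returns the event data.frame;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("animal_id", "time_s", "kind")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("animal_id", "time_s", "kind")
  if (!all(need %in% names(d))) {
    stop_invalid("events CSV needs columns ", paste(need, collapse = ", "))
  }
  if (!all(d$kind %in% .KINDS)) stop_invalid("unknown event kind in file")
  d
}
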
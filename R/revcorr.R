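# Reverse correlation: event-triggered stimulus averages and their
# conversion to linear filters by the average-event-rate scaling.

#' Event-triggered stimulus average
#'
#' Mean stimulus history preceding transitions of one kind: for each
#' usable event, the stimulus samples at lags `-W, ..., -dt, 0`
#' (inclusive; `W/dt + 1` samples) relative to the event are collected
#' and averaged across events.  The
#' stimulus sample containing the event time is lag 0.  Events whose
#' history window reaches back before the stimulus start (or whose time
#' falls off the stimulus) are excluded and counted.  Per-lag mean, SD
#' and SEM over events are retained so the average can later be compared
#' against a control with per-lag t-tests.
#'
#' @param events event data.frame (`animal_id, time_s, kind`), e.g. from
#'   [extract_transitions()].
#' @param stim the [stimulus_train()] the animals experienced.
#' @param kind transition kind to average.
#' @param window history length W in seconds (default 4); the lag grid
#'   runs from -W to 0 inclusive.
#' @param weighting `"pooled"` (default; every event counts once, the
#'   convention behind "N transitions exhibited by M larvae") or
#'   `"per_animal"` (each animal's mean history weighted equally, SEM
#'   across animals).
#' @return An object of class `triggered_average`: list with `lags`
#'   (negative, seconds), `mean`, `sd`, `sem`, `n_events`, `n_excluded`,
#'   `kind`, `dt`, `weighting`.
#' @export
triggered_average <- function(events, stim, kind, window = 4,
                              weighting = c("pooled", "per_animal")) {
  weighting <- match.arg(weighting)
  check_kind(kind)
  if (!inherits(stim, "stimulus_train")) stop_invalid("`stim` must be a stimulus_train")
  check_scalar_number(window, "window", positive = TRUE)
  if (window > stim_duration(stim)) {
    stop_invalid("`window` exceeds the stimulus duration")
  }
  dt <- stim$dt
  L <- round(window / dt) + 1L # lags -W ... 0 inclusive
  if (L < 2L) stop_invalid("`window` shorter than one sample")
  ev <- events[events$kind == kind, , drop = FALSE]
  if (nrow(ev) == 0L) stop_empty("no events of kind ", kind)

  n <- length(stim$values)
  i_ev <- round((ev$time_s - stim$t0) / dt) + 1L # sample containing the event
  usable <- i_ev >= L & i_ev <= n
  n_excl <- sum(!usable)
  ev <- ev[usable, , drop = FALSE]
  i_ev <- i_ev[usable]
  if (length(i_ev) == 0L) stop_empty("no usable events (all truncated)")

  # rows = events, cols = lags -(L-1)dt ... 0
  idx <- outer(i_ev, (-(L - 1L)):0L, `+`)
  M <- matrix(stim$values[idx], nrow = length(i_ev))

  if (weighting == "pooled") {
    m <- colMeans(M)
    s <- apply(M, 2L, stats::sd)
    n_eff <- nrow(M)
  } else {
    by_animal <- rowsum(M, ev$animal_id) / as.vector(table(ev$animal_id)[
      sort(unique(ev$animal_id))])
    m <- colMeans(by_animal)
    s <- apply(by_animal, 2L, stats::sd)
    n_eff <- nrow(by_animal)
  }
  s[is.na(s)] <- 0 # single event: SD undefined, report 0

  structure(
    list(lags = (-(L - 1L):0L) * dt, mean = m, sd = s,
         sem = s / sqrt(n_eff), n = n_eff, n_events = nrow(M),
         n_excluded = n_excl, kind = kind, dt = dt, weighting = weighting),
    class = "triggered_average"
  )
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf(
    "<triggered_average> %s, %d events (%d excluded), %d lags over [%g, 0] s\n",
    x$kind, x$n_events, x$n_excluded, length(x$lags), min(x$lags)
  ))
  invisible(x)
}

#' Convert an event-triggered average to a linear filter
#'
#' The filter is the time-reversed triggered average scaled by the mean
#' event rate: `h(tau) = (n_bar / T) * C(-tau)`, where `n_bar` is the
#' average number of events in one trial and `T` the trial duration
#' (default 1200 s, a 20-minute trial).
#'
#' @param ta a [triggered_average()].
#' @param mean_events_per_trial average number of events per trial.
#' @param trial_duration trial duration in seconds (default 1200).
#' @return A [linear_filter()] with `taus` running 0 ... W - dt.
#' @export
filter_from_ta <- function(ta, mean_events_per_trial, trial_duration = 1200) {
  if (!inherits(ta, "triggered_average")) stop_invalid("`ta` must be a triggered_average")
  check_scalar_number(mean_events_per_trial, "mean_events_per_trial")
  if (!(is.numeric(trial_duration) && length(trial_duration) == 1L &&
        is.finite(trial_duration) && trial_duration > 0)) {
    stop_invalid("`trial_duration` must be > 0")
  }
  h <- (mean_events_per_trial / trial_duration) * rev(ta$mean)
  linear_filter(h, dt = ta$dt, kind = ta$kind)
}

#' Read and write triggered-average CSV files
#'
#' Columns `lag_s, mean, sd, sem, n, n_events, kind`; `sd` and `n` are
#' retained so per-lag t-tests against a control remain possible after a
#' round trip.
#'
#' @param ta a [triggered_average()].
#' @param path file path.
#' @return `read_ta_csv()` returns a [triggered_average()];
#'   `write_ta_csv()` returns `path` invisibly.
#' @export
write_ta_csv <- function(ta, path) {
  utils::write.csv(
    data.frame(lag_s = ta$lags, mean = ta$mean, sd = ta$sd, sem = ta$sem,
               n = ta$n, n_events = ta$n_events, kind = ta$kind),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_ta_csv
#' @export
read_ta_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("lag_s", "mean", "sd", "sem", "n", "n_events", "kind")
  if (!all(need %in% names(d))) {
    stop_invalid("TA CSV needs columns ", paste(need, collapse = ", "))
  }
  dt <- if (nrow(d) > 1L) stats::median(diff(d$lag_s)) else 0.25
  structure(
    list(lags = d$lag_s, mean = d$mean, sd = d$sd, sem = d$sem,
         n = d$n[1L], n_events = d$n_events[1L], n_excluded = NA_integer_,
         kind = d$kind[1L], dt = dt, weighting = "pooled"),
    class = "triggered_average"
  )
}

#' Read and write linear-filter JSON files
#'
#' @param filter a [linear_filter()].
#' @param path file path.
#' @param provenance optional list stored alongside the taps.
#' @return `read_filter_json()` returns a [linear_filter()];
#'   `write_filter_json()` returns `path` invisibly.
#' @export
write_filter_json <- function(filter, path, provenance = list()) {
  jsonlite::write_json(
    list(taus = filter$taus, h = filter$h, dt = filter$dt,
         kind = filter$kind, provenance = provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_filter_json
#' @export
read_filter_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_filter(obj$h, dt = obj$dt, kind = obj$kind)
}
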
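# Stimulus waveforms: Bernoulli white noise for estimation, steps and
# pulse trains for validation.  The canonical coding is -1 (lights OFF)
# and +1 (lights ON) on a uniform clock, 4 Hz by default.

#' Construct a stimulus train
#'
#' A `stimulus_train` is a uniformly sampled sequence over \{-1, +1\}
#' (-1 = lights OFF, +1 = lights ON) on a fixed clock.  It is the binary
#' white-noise (or designed) input \eqn{s(t)} to every other stage.
#'
#' @param values numeric vector; every element must be exactly -1 or +1.
#' @param dt sample interval in seconds (default 0.25, i.e. 4 Hz).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `stimulus_train` with fields `values`,
#'   `dt`, `t0`.
#' @seealso [generate_bernoulli()], [make_step()], [make_pulse_train()]
#' @export
stimulus_train <- function(values, dt = 0.25, t0 = 0) {
  check_scalar_number(dt, "dt", positive = TRUE)
  check_scalar_number(t0, "t0")
  if (length(values) < 1L) stop_invalid("a stimulus needs at least one sample")
  if (!all(values %in% c(-1, 1))) {
    stop_invalid("stimulus values must all be exactly -1 or +1")
  }
  structure(
    list(values = as.numeric(values), dt = dt, t0 = t0),
    class = "stimulus_train"
  )
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf(
    "<stimulus_train> %d samples, dt = %g s, duration = %g s, mean = %.4f\n",
    length(x$values), x$dt, stim_duration(x), mean(x$values)
  ))
  invisible(x)
}

#' Times and duration of a stimulus train
#'
#' @param stim a [stimulus_train()].
#' @return `stim_times()`: vector of sample times (s); `stim_duration()`:
#'   total duration `n * dt` (s).
#' @export
stim_times <- function(stim) stim$t0 + (seq_along(stim$values) - 1L) * stim$dt

#' @rdname stim_times
#' @export
stim_duration <- function(stim) length(stim$values) * stim$dt

#' Generate a Bernoulli white-noise stimulus
#'
#' Each sample is independently +1 (ON) with probability `p_on` and -1
#' (OFF) otherwise.  A balanced (`p_on = 0.5`) train has zero mean and a
#' delta-function autocorrelation in expectation, which is what makes the
#' event-triggered average an unbiased estimate of the linear filter.
#'
#' @param duration total duration in seconds.
#' @param dt sample interval in seconds (default 0.25 s, 4 Hz).
#' @param p_on probability of the ON state per sample.
#' @param seed integer seed; the call is reproducible given the seed.
#' @return A [stimulus_train()].
#' @examples
#' s <- generate_bernoulli(60, seed = 1)
#' mean(s$values)
#' @export
generate_bernoulli <- function(duration, dt = 0.25, p_on = 0.5, seed = NULL) {
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(dt, "dt", positive = TRUE)
  check_scalar_number(p_on, "p_on")
  if (p_on < 0 || p_on > 1) stop_invalid("`p_on` must lie in [0, 1]")
  n <- round(duration / dt)
  if (n < 1L) stop_invalid("duration shorter than one sample")
  if (!is.null(seed)) set.seed(seed)
  values <- ifelse(stats::runif(n) < p_on, 1, -1)
  stimulus_train(values, dt = dt)
}

# snap a time to the nearest sample boundary, ties toward the earlier
# sample (round-half-down); returns a 0-based sample index
.snap_index <- function(t, dt) as.integer(ceiling(t / dt - 0.5))

#' Build a step stimulus
#'
#' Piecewise-constant +/-1 sequence that toggles at each switch time.
#' Switch times are snapped to the nearest sample boundary; exact
#' half-sample ties go to the earlier sample.
#'
#' @param duration total duration (s).
#' @param dt sample interval (s).
#' @param switch_times strictly increasing times in `[0, duration)` at
#'   which the level toggles.
#' @param initial starting level, -1 or +1.
#' @return A [stimulus_train()].
#' @export
make_step <- function(duration, dt = 0.25, switch_times = numeric(),
                      initial = -1) {
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(dt, "dt", positive = TRUE)
  if (!(length(initial) == 1L && initial %in% c(-1, 1))) {
    stop_invalid("`initial` must be -1 or +1")
  }
  if (length(switch_times)) {
    if (any(diff(switch_times) <= 0)) {
      stop_invalid("switch times must be strictly increasing")
    }
    if (any(switch_times < 0 | switch_times >= duration)) {
      stop_invalid("switch times must lie in [0, duration)")
    }
  }
  n <- round(duration / dt)
  values <- rep(initial, n)
  for (ts in switch_times) {
    i <- .snap_index(ts, dt) # 0-based
    if (i < n) values[(i + 1L):n] <- -values[(i + 1L):n]
  }
  stimulus_train(values, dt = dt)
}

#' Build a pulse-train stimulus
#'
#' Alternating ON pulses and OFF gaps starting at time zero:
#' `pulse_widths[1]` seconds ON, `gaps[1]` seconds OFF, `pulse_widths[2]`
#' ON, and so on; any remainder of the duration is OFF.  This is the
#' "defined flicker" waveform used to validate LN predictions.
#'
#' @param duration total duration (s).
#' @param dt sample interval (s).
#' @param pulse_widths positive pulse widths (s).
#' @param gaps positive gap widths (s); one fewer than, or as many as,
#'   the pulses.
#' @return A [stimulus_train()].
#' @export
make_pulse_train <- function(duration, dt = 0.25, pulse_widths, gaps = numeric()) {
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(dt, "dt", positive = TRUE)
  if (length(pulse_widths) < 1L) stop_invalid("need at least one pulse")
  if (any(pulse_widths <= 0) || any(gaps <= 0)) {
    stop_invalid("pulse widths and gaps must be positive")
  }
  if (!(length(gaps) %in% c(length(pulse_widths) - 1L, length(pulse_widths)))) {
    stop_invalid("`gaps` must have one fewer element than, or as many as, ",
                 "`pulse_widths`")
  }
  if (sum(pulse_widths) + sum(gaps) > duration + 1e-9) {
    stop_invalid("pulses and gaps do not fit in `duration`")
  }
  n <- round(duration / dt)
  values <- rep(-1, n)
  pos <- 0L
  for (i in seq_along(pulse_widths)) {
    np <- round(pulse_widths[i] / dt)
    if (np > 0L) values[(pos + 1L):min(n, pos + np)] <- 1
    pos <- pos + np
    if (i <= length(gaps)) pos <- pos + round(gaps[i] / dt)
    if (pos >= n) break
  }
  stimulus_train(values, dt = dt)
}

#' Sample autocorrelation of a stimulus train
#'
#' Biased sample autocorrelation of the mean-removed sequence,
#' normalized to 1 at lag zero.  For a Bernoulli train this should be
#' indistinguishable from a delta function: every nonzero lag within the
#' +/- 3/sqrt(n) sampling band.
#'
#' @param train a [stimulus_train()].
#' @param max_lag largest lag to report, in seconds (must be smaller
#'   than the duration).
#' @return A data.frame with columns `lag_s` and `value`.
#' @export
stim_autocorrelation <- function(train, max_lag) {
  if (!inherits(train, "stimulus_train")) stop_invalid("`train` must be a stimulus_train")
  check_scalar_number(max_lag, "max_lag", positive = TRUE)
  if (max_lag >= stim_duration(train)) {
    stop_invalid("`max_lag` must be smaller than the train duration")
  }
  x <- train$values
  if (stats::var(x) == 0) {
    stop_degenerate("autocorrelation undefined for a constant train")
  }
  k <- floor(max_lag / train$dt)
  a <- stats::acf(x, lag.max = k, plot = FALSE, demean = TRUE)
  data.frame(lag_s = (0:k) * train$dt, value = as.numeric(a$acf))
}

#' Read and write stimulus CSV files
#'
#' The on-disk format has columns `time_s, value` with one row per
#' sample.  Values may be coded -1/+1 (canonical) or 0/1; the 0/1 coding
#' is recoded to -1/+1 on read with a notice.
#'
#' @param path file path.
#' @param stim a [stimulus_train()] (for writing).
#' @return `read_stimulus_csv()` returns a [stimulus_train()];
#'   `write_stimulus_csv()` returns `path` invisibly.
#' @export
read_stimulus_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d))) {
    stop_invalid("stimulus CSV needs columns time_s, value")
  }
  if (nrow(d) < 1L) stop_invalid("empty stimulus CSV")
  v <- d$value
  if (all(v %in% c(0, 1))) {
    message("stimulus file uses 0/1 coding; recoding to -1/+1")
    v <- ifelse(v == 1, 1, -1)
  }
  dt <- if (nrow(d) > 1L) stats::median(diff(d$time_s)) else 0.25
  stimulus_train(v, dt = dt, t0 = d$time_s[1L])
}

#' @rdname read_stimulus_csv
#' @export
write_stimulus_csv <- function(stim, path) {
  utils::write.csv(
    data.frame(time_s = stim_times(stim), value = stim$values),
    path, row.names = FALSE
  )
  invisible(path)
}
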
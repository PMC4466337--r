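# Linear-nonlinear machinery: causal convolution of a filter with the
# stimulus, static-nonlinearity estimation, and prediction of per-bin
# transition probabilities for arbitrary waveforms.

#' Construct a linear filter
#'
#' A causal discrete kernel \eqn{h(\tau)} for one transition kind.
#' `taus` run from 0 upward in steps of `dt`; `h[k]` weights the
#' stimulus sample `tau_k` seconds before the current bin, so the
#' convolution `sum_k h(tau_k) s(t - tau_k) dt` is the linearly
#' predicted transition rate at `t`.
#'
#' @param h numeric kernel values (rate contribution per unit stimulus
#'   per second).
#' @param dt sample interval (s).
#' @param kind transition kind, `"RUN_TO_TURN"` or `"TURN_TO_RUN"`.
#' @return An object of class `linear_filter`.
#' @export
linear_filter <- function(h, dt = 0.25, kind = "RUN_TO_TURN") {
  check_scalar_number(dt, "dt", positive = TRUE)
  check_kind(kind)
  if (length(h) < 1L || !all(is.finite(h))) {
    stop_invalid("filter values must be a non-empty finite vector")
  }
  structure(
    list(taus = (seq_along(h) - 1L) * dt, h = as.numeric(h), dt = dt,
         kind = kind),
    class = "linear_filter"
  )
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf("<linear_filter> %s, %d taps, dt = %g s, history %g s\n",
              x$kind, length(x$h), x$dt, (length(x$h) - 1L) * x$dt))
  invisible(x)
}

#' Construct a static nonlinearity
#'
#' The memoryless function that rescales the linear drive into a
#' nonnegative transition rate (events/s).  Two forms are supported:
#' `sigmoid` with parameters `floor`, `amplitude`, `slope`, `midpoint`
#' evaluating to `floor + amplitude / (1 + exp(-slope (x - midpoint)))`,
#' and `linear` with `intercept`, `gain`.  Evaluated output is clipped
#' at zero since rates cannot be negative.
#'
#' @param form `"sigmoid"` or `"linear"`.
#' @param params named list of parameters for the chosen form.
#' @param r_squared goodness of fit when estimated from data.
#' @return An object of class `static_nonlinearity`.
#' @export
static_nonlinearity <- function(form = c("sigmoid", "linear"), params,
                                r_squared = NA_real_) {
  form <- match.arg(form)
  need <- if (form == "sigmoid") {
    c("floor", "amplitude", "slope", "midpoint")
  } else {
    c("intercept", "gain")
  }
  if (!all(need %in% names(params))) {
    stop_invalid("params for a ", form, " nonlinearity must include ",
                 paste(need, collapse = ", "))
  }
  params <- lapply(params[need], as.numeric)
  if (form == "sigmoid" && params$amplitude < 0) {
    stop_invalid("sigmoid amplitude must be >= 0")
  }
  structure(list(form = form, params = params, r_squared = r_squared),
            class = "static_nonlinearity")
}

#' Evaluate a static nonlinearity
#'
#' @param nl a [static_nonlinearity()].
#' @param x numeric vector of linear-drive values.
#' @return Nonnegative rates (events/s), clipped at zero.
#' @export
eval_nonlinearity <- function(nl, x) {
  if (!inherits(nl, "static_nonlinearity")) {
    stop_invalid("`nl` must be a static_nonlinearity")
  }
  p <- nl$params
  y <- switch(nl$form,
    sigmoid = p$floor + p$amplitude / (1 + exp(-p$slope * (x - p$midpoint))),
    linear = p$intercept + p$gain * x
  )
  pmax(y, 0)
}

#' @export
print.static_nonlinearity <- function(x, ...) {
  cat(sprintf("<static_nonlinearity> %s [%s]%s\n", x$form,
              paste(sprintf("%s=%.4g", names(x$params), unlist(x$params)),
                    collapse = ", "),
              if (is.finite(x$r_squared)) sprintf(", R^2 = %.3f", x$r_squared)
              else ""))
  invisible(x)
}

#' Assemble an LN model
#'
#' A pair of linear filters plus a pair of static nonlinearities, one
#' per transition direction.  The same container holds ground-truth
#' generative models (see [default_ground_truth()]) and models fitted
#' from data (see [fit_ln_model()]).
#'
#' @param filter_rt,filter_tr [linear_filter()]s for the run-to-turn and
#'   turn-to-run transitions.
#' @param nonlin_rt,nonlin_tr [static_nonlinearity()]s mapping linear
#'   drive to rate for each transition.
#' @param provenance optional list recorded with the model (window, dt,
#'   event counts, fit seeds ...).
#' @return An object of class `ln_model` with elements `filters` and
#'   `nonlins`, each a list keyed by transition kind.
#' @export
ln_model <- function(filter_rt, filter_tr, nonlin_rt, nonlin_tr,
                     provenance = list()) {
  for (f in list(filter_rt, filter_tr)) {
    if (!inherits(f, "linear_filter")) stop_invalid("filters must be linear_filter objects")
  }
  for (nl in list(nonlin_rt, nonlin_tr)) {
    if (!inherits(nl, "static_nonlinearity")) {
      stop_invalid("nonlinearities must be static_nonlinearity objects")
    }
  }
  if (filter_rt$dt != filter_tr$dt) stop_invalid("filter dt mismatch")
  filters <- list(filter_rt, filter_tr)
  names(filters) <- .KINDS
  nonlins <- list(nonlin_rt, nonlin_tr)
  names(nonlins) <- .KINDS
  structure(list(filters = filters, nonlins = nonlins, dt = filter_rt$dt,
                 provenance = provenance),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat("<ln_model>\n")
  for (k in .KINDS) {
    cat(sprintf("  %s: %d-tap filter, %s nonlinearity\n",
                k, length(x$filters[[k]]$h), x$nonlins[[k]]$form))
  }
  invisible(x)
}

#' Linear prediction by causal convolution
#'
#' Computes the discrete causal convolution
#' \eqn{r(t) = \sum_k h(\tau_k)\, s(t - \tau_k)\, dt} of a filter with a
#' stimulus.  Bins whose convolution window reaches back before the
#' start of the stimulus are computed with the missing history treated
#' as zero and flagged as burn-in; burn-in bins must not enter fits or
#' comparisons.
#'
#' @param filter a [linear_filter()]; its `dt` must equal the stimulus
#'   `dt`.
#' @param stim a [stimulus_train()].
#' @return An object of class `rate_trace`: list with `times`, `rate`
#'   (events/s), logical `burn_in`, `dt`, `kind`.
#' @export
linear_predict <- function(filter, stim) {
  if (!inherits(filter, "linear_filter")) stop_invalid("`filter` must be a linear_filter")
  if (!inherits(stim, "stimulus_train")) stop_invalid("`stim` must be a stimulus_train")
  if (abs(filter$dt - stim$dt) > 1e-9) {
    stop_invalid("filter dt (", filter$dt, ") does not match stimulus dt (",
                 stim$dt, ")")
  }
  h <- filter$h
  n <- length(stim$values)
  L <- length(h)
  if (L > n) stop_invalid("filter longer than stimulus")
  # zero-pad the pre-start history so burn-in bins are defined
  x <- c(rep(0, L - 1L), stim$values)
  r <- stats::filter(x, h, method = "convolution", sides = 1) * stim$dt
  r <- as.numeric(r)[L:(L + n - 1L)]
  burn <- seq_len(n) <= min(L, n)
  structure(list(times = stim_times(stim), rate = r, burn_in = burn,
                 dt = stim$dt, kind = filter$kind),
            class = "rate_trace")
}

# ---- static-nonlinearity estimation -----------------------------------

# least-squares sigmoid fit with quantile-based initialization and an
# optim fallback; x are bin centers, y empirical rates.  The drive axis
# is standardized internally so the optimizer sees O(1) parameters
# whatever the filter scaling, and the parameters are mapped back.
.fit_sigmoid <- function(x, y) {
  if (length(unique(x)) < 4L) {
    stop_fit_failure("need at least 4 distinct drive bins for a sigmoid fit")
  }
  mx <- mean(x)
  sx <- max(stats::sd(x), 1e-12)
  z <- (x - mx) / sx
  rng <- max(y) - min(y)
  start <- list(floor = min(y), amplitude = max(rng, 1e-6),
                slope = 2, midpoint = stats::median(z))
  d <- data.frame(z = z, y = y)
  fit <- tryCatch(
    suppressWarnings(stats::nls(
      y ~ floor + amplitude / (1 + exp(-slope * (z - midpoint))),
      data = d, start = start, algorithm = "port",
      lower = c(floor = 0, amplitude = 0, slope = 1e-6, midpoint = -50),
      upper = c(floor = max(y), amplitude = 20 * max(rng, 1e-6),
                slope = 500, midpoint = 50),
      control = stats::nls.control(maxiter = 500, warnOnly = TRUE)
    )),
    error = function(e) NULL
  )
  sse <- function(th) {
    f <- th[1] + th[2] / (1 + exp(-th[3] * (z - th[4])))
    sum((y - f)^2)
  }
  p <- if (!is.null(fit)) as.list(stats::coef(fit)) else start
  # polish (or rescue) with a derivative-free pass on the same objective
  o <- stats::optim(unlist(p), sse, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  if (o$value < sse(unlist(p))) {
    p <- as.list(o$par)
    names(p) <- c("floor", "amplitude", "slope", "midpoint")
  }
  list(floor = max(p$floor, 0), amplitude = max(p$amplitude, 0),
       slope = p$slope / sx, midpoint = mx + p$midpoint * sx)
}

#' Estimate a static nonlinearity from simulated or recorded tracks
#'
#' Implements the comparison of the linear prediction with the
#' measurements that generated it.  All time bins in which an animal
#' occupies the at-risk state for `kind` are pooled, binned by the value
#' of the linear drive into `n_bins` equal-count bins, and the empirical
#' transition rate per bin is regressed on the bin-mean drive with the
#' chosen functional form by least squares.
#'
#' The per-bin empirical rate is, by default, the discrete-hazard
#' estimate `-log(1 - k/n) / dt`, which is the exact inverse of the
#' hazard-to-probability map `p = 1 - exp(-r dt)` used both by the
#' simulator and by [predict_response()]; `rate_method = "naive"` gives
#' the raw `k / (n dt)` (transitions per unit at-risk time), which is
#' biased downward by about `r dt / 2` at high rates.
#'
#' @param drive a `rate_trace` from [linear_predict()], aligned to the
#'   clock of `tracks`.
#' @param tracks a list of [state_track()]s simulated/recorded under the
#'   stimulus that produced `drive`.
#' @param kind transition kind.
#' @param n_bins number of equal-count drive bins (>= 3, default 20).
#' @param form `"sigmoid"`, `"linear"`, or `"auto"` (chooses by adjusted
#'   R-squared).
#' @param rate_method `"hazard"` (default) or `"naive"`, see Details.
#' @param burn_in seconds discarded from the start of every track, over
#'   and above the convolution burn-in, to erase the initial-condition
#'   artifact (all simulated animals start in RUN).
#' @return A [static_nonlinearity()] with `r_squared` filled in, and
#'   attribute `binned` (data.frame of bin centers, rates and counts).
#' @export
estimate_nonlinearity <- function(drive, tracks, kind, n_bins = 20,
                                  form = c("sigmoid", "linear", "auto"),
                                  rate_method = c("hazard", "naive"),
                                  burn_in = 10) {
  form <- match.arg(form)
  rate_method <- match.arg(rate_method)
  check_kind(kind)
  if (!inherits(drive, "rate_trace")) stop_invalid("`drive` must be a rate_trace")
  if (n_bins < 3L) stop_invalid("`n_bins` must be >= 3")
  if (inherits(tracks, "state_track")) tracks <- list(tracks)

  src <- source_state(kind)
  skip <- max(which(drive$burn_in), round(burn_in / drive$dt))
  xs <- vector("list", length(tracks))
  ys <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (abs(tr$dt - drive$dt) > 1e-9) stop_invalid("track dt does not match drive dt")
    n <- min(length(tr$states), length(drive$rate))
    t_idx <- seq.int(skip + 1L, n) # candidate transition bins
    t_idx <- t_idx[t_idx >= 2L]
    at_risk <- tr$states[t_idx - 1L] == src
    xs[[i]] <- drive$rate[t_idx[at_risk]]
    ys[[i]] <- as.numeric(tr$states[t_idx[at_risk]] != src)
  }
  x <- unlist(xs)
  y <- unlist(ys)
  if (length(x) < n_bins) stop_fit_failure("not enough at-risk bins")
  if (stats::sd(x) == 0) {
    stop_degenerate("linear drive is constant; nonlinearity unidentifiable")
  }

  grp <- cut(rank(x, ties.method = "first"), breaks = n_bins, labels = FALSE)
  centers <- tapply(x, grp, mean)
  p_hat <- tapply(y, grp, mean)
  n_per <- tapply(y, grp, length)
  ok <- is.finite(centers) & is.finite(p_hat) & p_hat < 1
  centers <- as.numeric(centers[ok]); p_hat <- as.numeric(p_hat[ok])
  n_per <- as.numeric(n_per[ok])
  rate <- if (rate_method == "hazard") {
    -log(1 - p_hat) / drive$dt
  } else {
    p_hat / drive$dt
  }
  binned <- data.frame(drive = centers, rate = rate, p = p_hat, n = n_per)

  fit_one <- function(fm) {
    if (fm == "linear") {
      co <- stats::coef(stats::lm(rate ~ centers))
      params <- list(intercept = unname(co[1]), gain = unname(co[2]))
      k <- 2L
    } else {
      params <- .fit_sigmoid(centers, rate)
      k <- 4L
    }
    nl <- static_nonlinearity(fm, params)
    pred <- eval_nonlinearity(nl, centers)
    ss_res <- sum((rate - pred)^2)
    ss_tot <- sum((rate - mean(rate))^2)
    r2 <- 1 - ss_res / ss_tot
    n_b <- length(centers)
    adj <- 1 - (1 - r2) * (n_b - 1) / max(n_b - k, 1)
    nl$r_squared <- r2
    list(nl = nl, adj = adj)
  }

  if (length(centers) < 3L) stop_fit_failure("fewer nonempty bins than parameters")
  res <- if (form == "auto") {
    cand <- lapply(c("sigmoid", "linear"), fit_one)
    cand[[which.max(vapply(cand, `[[`, numeric(1), "adj"))]]
  } else {
    if (form == "sigmoid" && length(centers) < 5L) {
      stop_fit_failure("fewer nonempty bins than sigmoid parameters")
    }
    fit_one(form)
  }
  out <- res$nl
  attr(out, "binned") <- binned
  attr(out, "n_at_risk") <- length(x)
  out
}

#' Predict transition-probability dynamics for a stimulus
#'
#' Full LN prediction: the stimulus is convolved with the linear filter,
#' the result is passed through the static nonlinearity, and the rate is
#' converted to a per-bin transition probability
#' \eqn{p(t) = 1 - \exp(-N(h * s)(t)\, dt)}.
#'
#' @param model an [ln_model()].
#' @param stim a [stimulus_train()].
#' @param kind transition kind(s) to predict (default both).
#' @return A data.frame of class `prediction_trace` with columns
#'   `time_s`, `p`, `kind`, `burn_in`.
#' @export
predict_response <- function(model, stim, kind = .KINDS) {
  if (!inherits(model, "ln_model")) stop_invalid("`model` must be an ln_model")
  out <- lapply(kind, function(k) {
    check_kind(k)
    tr <- linear_predict(model$filters[[k]], stim)
    r <- eval_nonlinearity(model$nonlins[[k]], tr$rate)
    data.frame(time_s = tr$times, p = 1 - exp(-r * stim$dt), kind = k,
               burn_in = tr$burn_in)
  })
  out <- do.call(rbind, out)
  class(out) <- c("prediction_trace", "data.frame")
  out
}

#' Empirical peristimulus transition-probability histogram
#'
#' Pools state tracks across animals and across repeated alignment
#' times (e.g. the onsets of 30 identical light steps) and reports, per
#' relative-time bin, the fraction of at-risk animals that transitioned:
#' `p = transitions / at-risk`, with the at-risk count `n` kept for
#' downstream z-tests.  An animal is at risk for a transition of `kind`
#' in a bin when it occupied the source state in the previous bin.
#'
#' @param tracks list of [state_track()]s.
#' @param align_times alignment times (s) on the track clock.
#' @param window two numbers `c(before, after)`: relative-time window in
#'   seconds (e.g. `c(-5, 15)`).
#' @param kind transition kind.
#' @return A data.frame of class `empirical_psth` with columns `time_s`
#'   (relative), `p`, `k`, `n`, `kind`.
#' @export
empirical_psth <- function(tracks, align_times, window, kind) {
  check_kind(kind)
  if (inherits(tracks, "state_track")) tracks <- list(tracks)
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_invalid("`window` must be c(before, after) with before < after")
  }
  src <- source_state(kind)
  dt <- tracks[[1L]]$dt
  rel <- seq(round(window[1] / dt), round(window[2] / dt))
  k_cnt <- numeric(length(rel))
  n_cnt <- numeric(length(rel))
  for (tr in tracks) {
    if (abs(tr$dt - dt) > 1e-9) stop_invalid("tracks disagree on dt")
    n <- length(tr$states)
    is_src <- tr$states == src
    for (a in align_times) {
      i0 <- round((a - tr$t0) / dt) + 1L # bin containing the alignment time
      idx <- i0 + rel
      sel <- idx >= 2L & idx <= n
      if (!any(sel)) next
      at_risk <- sel
      at_risk[sel] <- is_src[idx[sel] - 1L]
      trans <- at_risk
      trans[at_risk] <- !is_src[idx[at_risk]]
      n_cnt <- n_cnt + at_risk
      k_cnt <- k_cnt + trans
    }
  }
  if (all(n_cnt == 0)) stop_empty("no animal was ever at risk in the window")
  out <- data.frame(time_s = rel * dt, p = ifelse(n_cnt > 0, k_cnt / n_cnt, NA),
                    k = k_cnt, n = n_cnt, kind = kind)
  class(out) <- c("empirical_psth", "data.frame")
  out
}

#' Fit a full LN model from tracks and the stimulus that drove them
#'
#' Convenience wrapper over the estimation chain: transition events are
#' extracted, event-triggered averages computed for both transition
#' kinds, converted to filters by the average-event-rate scaling, the
#' linear drives computed, and static nonlinearities fitted (sigmoid for
#' run-to-turn, line for turn-to-run by default).
#'
#' @param tracks list of [state_track()]s.
#' @param stim the [stimulus_train()] they were recorded under.
#' @param window filter window in seconds (history length; default 4).
#' @param trial_duration duration of one trial in seconds (default 1200,
#'   i.e. 20 min), used in the event-rate scaling of the filters.
#' @param forms named character vector giving the nonlinearity form per
#'   kind.
#' @param n_bins,rate_method,burn_in passed to [estimate_nonlinearity()].
#' @return A fitted [ln_model()]; provenance records the window, event
#'   counts and fit quality.
#' @export
fit_ln_model <- function(tracks, stim, window = 4, trial_duration = 1200,
                         forms = c(RUN_TO_TURN = "sigmoid",
                                   TURN_TO_RUN = "linear"),
                         n_bins = 20, rate_method = "hazard", burn_in = 10) {
  if (inherits(tracks, "state_track")) tracks <- list(tracks)
  events <- extract_transitions(tracks)
  parts <- list()
  for (k in .KINDS) {
    ta <- triggered_average(events, stim, kind = k, window = window)
    n_bar <- ta$n_events / length(tracks)
    f <- filter_from_ta(ta, mean_events_per_trial = n_bar,
                        trial_duration = trial_duration)
    drive <- linear_predict(f, stim)
    nl <- estimate_nonlinearity(drive, tracks, kind = k, n_bins = n_bins,
                                form = forms[[k]], rate_method = rate_method,
                                burn_in = burn_in)
    parts[[k]] <- list(filter = f, nonlin = nl, n_events = ta$n_events)
  }
  ln_model(
    parts[[.KIND_RT]]$filter, parts[[.KIND_TR]]$filter,
    parts[[.KIND_RT]]$nonlin, parts[[.KIND_TR]]$nonlin,
    provenance = list(
      window = window, dt = stim$dt, trial_duration = trial_duration,
      n_tracks = length(tracks),
      n_events = list(RUN_TO_TURN = parts[[.KIND_RT]]$n_events,
                      TURN_TO_RUN = parts[[.KIND_TR]]$n_events),
      r_squared = list(RUN_TO_TURN = parts[[.KIND_RT]]$nonlin$r_squared,
                       TURN_TO_RUN = parts[[.KIND_TR]]$nonlin$r_squared)
    )
  )
}

# ---- model JSON -------------------------------------------------------

#' Read and write LN model JSON files
#'
#' Models are serialized as plain JSON: one entry per transition kind
#' holding the filter taps and the nonlinearity parameters, plus a free
#' provenance block.
#'
#' @param model an [ln_model()].
#' @param path file path.
#' @return `read_model_json()` returns an [ln_model()];
#'   `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  if (!inherits(model, "ln_model")) stop_invalid("`model` must be an ln_model")
  obj <- list(
    dt = model$dt,
    filters = lapply(model$filters, function(f) {
      list(taus = f$taus, h = f$h, dt = f$dt, kind = f$kind)
    }),
    nonlinearities = lapply(model$nonlins, function(nl) {
      list(form = nl$form, params = nl$params, r_squared = nl$r_squared)
    }),
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- lapply(.KINDS, function(k) {
    fk <- obj$filters[[k]]
    linear_filter(fk$h, dt = fk$dt, kind = k)
  })
  nl <- lapply(.KINDS, function(k) {
    nk <- obj$nonlinearities[[k]]
    static_nonlinearity(nk$form, as.list(nk$params),
                        r_squared = nk$r_squared %||% NA_real_)
  })
  ln_model(f[[1]], f[[2]], nl[[1]], nl[[2]],
           provenance = as.list(obj$provenance %||% list()))
}
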
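# Significance machinery: pooled two-proportion z-tests of PSTH bins
# against baseline, and per-lag Welch t-tests of triggered averages
# against a control.

# vectorized pooled z; degenerate bins (pooled proportion 0 or 1) give NA
.ztest_vec <- function(k1, n1, k2, n2) {
  p_pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (k1 / n1 - k2 / n2) / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  valid <- pmin(n1 * p_pool, n1 * (1 - p_pool),
                n2 * p_pool, n2 * (1 - p_pool)) >= 5
  list(z = z, p_value = p, valid = valid & is.finite(z))
}

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic for comparing `k1/n1` with `k2/n2`,
#' with a two-sided normal p-value.  The normal approximation is
#' flagged invalid unless `n p >= 5` and `n (1 - p) >= 5` hold for both
#' groups at the pooled proportion.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with elements `z`, `p_value`, `valid`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2,
                                 alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  for (v in list(k1 = k1, n1 = n1, k2 = k2, n2 = n2)) {
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0)) {
      stop_invalid("counts must be single nonnegative numbers")
    }
  }
  if (n1 < 1 || n2 < 1) stop_invalid("group sizes must be >= 1")
  if (k1 > n1 || k2 > n2) stop_invalid("successes cannot exceed trials")
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1) {
    stop_degenerate("pooled proportion is 0 or 1; z undefined")
  }
  z <- (k1 / n1 - k2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    less = stats::pnorm(z),
    greater = stats::pnorm(-z)
  )
  valid <- min(n1 * p_pool, n1 * (1 - p_pool),
               n2 * p_pool, n2 * (1 - p_pool)) >= 5
  list(z = z, p_value = p, valid = valid)
}

#' Pool baseline counts from the pre-alignment part of a PSTH
#'
#' @param psth an [empirical_psth()].
#' @param interval optional `c(from, to)` in relative seconds; default
#'   is every bin before the alignment time (relative time < 0).
#' @return List with `k` and `n`, suitable for [psth_vs_baseline()].
#' @export
psth_baseline <- function(psth, interval = NULL) {
  sel <- if (is.null(interval)) {
    psth$time_s < 0
  } else {
    psth$time_s >= interval[1] & psth$time_s < interval[2]
  }
  if (!any(sel)) stop_invalid("baseline interval selects no bins")
  list(k = sum(psth$k[sel]), n = sum(psth$n[sel]))
}

#' Per-bin z-tests of a PSTH against a baseline
#'
#' Each relative-time bin of the PSTH is compared with the pooled
#' baseline counts by [two_proportion_ztest()].  Degenerate bins are
#' reported invalid, not failed.  Returned summaries flag the onset
#' (first bin at relative time >= 0 with `p < alpha`) and offset (last
#' such bin) of significance; only valid bins count.
#'
#' @param psth an [empirical_psth()].
#' @param baseline list or vector with baseline counts `k`, `n`, e.g.
#'   from [psth_baseline()].
#' @param alpha significance threshold (default 0.05).
#' @return An object of class `significance_trace`: data.frame
#'   `time_s, z, p_value, valid, significant` with attributes `onset`,
#'   `offset` (seconds, `NA` when never significant) and `alpha`.
#' @export
psth_vs_baseline <- function(psth, baseline, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop_invalid("`alpha` must be in (0, 1)")
  k0 <- baseline[["k"]]; n0 <- baseline[["n"]]
  if (n0 < 1) stop_invalid("baseline must contain at least one trial")
  zt <- .ztest_vec(psth$k, psth$n, k0, n0)
  sig <- zt$valid & !is.na(zt$p_value) & zt$p_value < alpha
  out <- data.frame(time_s = psth$time_s, z = zt$z, p_value = zt$p_value,
                    valid = zt$valid, significant = sig)
  post <- which(sig & psth$time_s >= 0)
  attr(out, "onset") <- if (length(post)) psth$time_s[min(post)] else NA_real_
  attr(out, "offset") <- if (length(post)) psth$time_s[max(post)] else NA_real_
  attr(out, "alpha") <- alpha
  class(out) <- c("significance_trace", "data.frame")
  out
}

#' Per-lag Welch t-tests of a triggered average against a control
#'
#' Every lag of a triggered average summarizes a distribution of
#' event-level stimulus values (mean, SD, n); each is compared with the
#' corresponding lag of a control average by a two-sample Welch t-test
#' computed from those summaries.  Lags with fewer than two events in
#' either group, or with zero variance in both, are marked invalid.
#'
#' @param ta a [triggered_average()].
#' @param control a [triggered_average()] on the same lag grid.
#' @return A data.frame `lag_s, t, df, p_value, valid`.
#' @export
ta_vs_control_ttest <- function(ta, control) {
  for (x in list(ta, control)) {
    if (!inherits(x, "triggered_average")) {
      stop_invalid("both arguments must be triggered_average objects")
    }
  }
  if (length(ta$lags) != length(control$lags) ||
      any(abs(ta$lags - control$lags) > 1e-9)) {
    stop_invalid("lag grids do not match")
  }
  n1 <- ta$n; n2 <- control$n
  v1 <- ta$sd^2 / n1
  v2 <- control$sd^2 / n2
  se <- sqrt(v1 + v2)
  t <- (ta$mean - control$mean) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  valid <- n1 >= 2 & n2 >= 2 & se > 0
  p <- ifelse(valid, 2 * stats::pt(-abs(t), df), NA_real_)
  # identical constant histories: no evidence of a difference
  p[n1 >= 2 & n2 >= 2 & se == 0 & ta$mean == control$mean] <- 1
  valid <- valid | (n1 >= 2 & n2 >= 2 & se == 0 & ta$mean == control$mean)
  data.frame(lag_s = ta$lags, t = ifelse(valid, t, NA_real_),
             df = ifelse(valid, df, NA_real_), p_value = p, valid = valid)
}
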
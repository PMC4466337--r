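test_that("linear prediction reduces to identity and zero kernels", {
  s <- generate_bernoulli(50, seed = 20)
  ident <- linear_filter(1 / s$dt, dt = s$dt)
  out <- linear_predict(ident, s)
  expect_equal(out$rate, s$values)
  expect_equal(sum(out$burn_in), 1)

  zero <- linear_filter(rep(0, 17), dt = s$dt)
  expect_true(all(linear_predict(zero, s)$rate == 0))

  bad <- linear_filter(1, dt = 0.5)
  expect_error(linear_predict(bad, s), class = "optorc_invalid_argument")
})

test_that("a boxcar filter turns a step into a linear ramp", {
  h <- rep(1, 4) # boxcar over [0, 1) s, area 1
  f <- linear_filter(h, dt = 0.25)
  s <- make_step(10, switch_times = 5, initial = -1)
  out <- linear_predict(f, s)
  # closed form: r = -1 before the step, ramps by 2/4 per sample, then +1
  i_step <- 21
  expect_equal(out$rate[i_step - 1], -1)
  expect_equal(out$rate[i_step:(i_step + 3)], c(-0.5, 0, 0.5, 1))
  expect_equal(out$rate[i_step + 4], 1)
})

test_that("nonlinearity evaluation is clipped, bounded and monotone", {
  sg <- static_nonlinearity("sigmoid", list(floor = 0.1, amplitude = 0.5,
                                            slope = 2, midpoint = 0))
  x <- seq(-10, 10, by = 0.1)
  y <- eval_nonlinearity(sg, x)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0.1 - 1e-12 & y <= 0.6 + 1e-12))

  ln <- static_nonlinearity("linear", list(intercept = 0.2, gain = 0.5))
  expect_true(all(eval_nonlinearity(ln, x) >= 0)) # clipped at zero
  expect_equal(eval_nonlinearity(ln, 1), 0.7)

  expect_error(static_nonlinearity("sigmoid", list(floor = 1)),
               class = "optorc_invalid_argument")
  expect_error(static_nonlinearity("sigmoid", list(floor = 0, amplitude = -1,
                                                   slope = 1, midpoint = 0)),
               class = "optorc_invalid_argument")
})

test_that("nonlinearity estimation recovers known ground truths", {
  truth <- fast_ground_truth()
  stim <- generate_bernoulli(1200, seed = 21)
  pop <- simulate_population(truth, stim, n_animals = 60, seed = 210)

  # sigmoid on the run-to-turn hazard, using the true drive
  drv <- linear_predict(truth$filters$RUN_TO_TURN, stim)
  nl <- estimate_nonlinearity(drv, pop, "RUN_TO_TURN", form = "sigmoid")
  tp <- truth$nonlins$RUN_TO_TURN$params
  expect_lt(abs(nl$params$amplitude - tp$amplitude) / tp$amplitude, 0.25)
  expect_lt(abs(nl$params$midpoint - tp$midpoint), 0.5 * 1) # drive-SD units
  expect_gt(nl$r_squared, 0.9)

  # line on the turn-to-run hazard
  drv2 <- linear_predict(truth$filters$TURN_TO_RUN, stim)
  nl2 <- estimate_nonlinearity(drv2, pop, "TURN_TO_RUN", form = "linear")
  expect_lt(abs(nl2$params$intercept - 0.5) / 0.5, 0.15)
  expect_lt(abs(nl2$params$gain - 0.2) / 0.2, 0.3)

  # auto selection picks a form and reports R^2
  nla <- estimate_nonlinearity(drv, pop, "RUN_TO_TURN", form = "auto")
  expect_true(nla$form %in% c("sigmoid", "linear"))
  expect_gt(nla$r_squared, 0.8)

  # degenerate drive: constant zero
  zero_drv <- linear_predict(linear_filter(rep(0, 17)), stim)
  expect_error(estimate_nonlinearity(zero_drv, pop, "RUN_TO_TURN"),
               class = "optorc_degenerate")
  expect_error(estimate_nonlinearity(drv, pop, "RUN_TO_TURN", n_bins = 2),
               class = "optorc_invalid_argument")
})

test_that("predict_response with a constant nonlinearity ignores the stimulus", {
  m <- constant_hazard_model(0.3, 0.4)
  s <- generate_bernoulli(60, seed = 22)
  pred <- predict_response(m, s)
  rt <- pred[pred$kind == "RUN_TO_TURN", ]
  expect_true(all(abs(rt$p - (1 - exp(-0.3 * 0.25))) < 1e-12))
  expect_true(all(pred$p >= 0 & pred$p <= 1))
})

test_that("empirical PSTH bookkeeping matches a hand-built example", {
  # one animal, one transition at absolute time 2.5 s
  tr <- track_from_string(paste(c(rep("R", 10), rep("T", 4)), collapse = ""))
  psth <- empirical_psth(list(tr), align_times = 2, window = c(-1, 1),
                         kind = "RUN_TO_TURN")
  expect_equal(psth$p[psth$time_s == 0.5], 1)
  expect_true(all(psth$p[psth$time_s < 0.5] == 0))
  # after the transition the animal is mid-turn: nobody at risk
  expect_true(all(psth$n[psth$time_s > 0.5] == 0))
  expect_true(all(psth$k <= psth$n))

  all_run <- track_from_string("RRRRRRRR")
  expect_error(empirical_psth(list(all_run), 1, c(-0.5, 0.5), "TURN_TO_RUN"),
               class = "optorc_empty_result")
})

test_that("stimulus-independent populations give a flat PSTH at 1-exp(-r dt)", {
  r <- 0.25
  m <- constant_hazard_model(r, r)
  s <- generate_bernoulli(500, seed = 23)
  pop <- simulate_population(m, s, n_animals = 120, seed = 230)
  psth <- empirical_psth(pop, align_times = c(100, 200, 300, 400),
                         window = c(-20, 20), kind = "RUN_TO_TURN")
  p_expect <- 1 - exp(-r * 0.25)
  expect_lt(abs(mean(psth$p) - p_expect) / p_expect, 0.1)
  expect_lt(max(abs(psth$p - p_expect)), 6 * sqrt(p_expect / min(psth$n)))
})

test_that("fitted LN models are faithful end to end at desk scale", {
  truth <- default_ground_truth("repulsive-monophasic")
  stim <- generate_bernoulli(1200, seed = 24)
  pop <- simulate_population(truth, stim, n_animals = 80, seed = 240)
  model <- fit_ln_model(pop, stim)
  expect_s3_class(model, "ln_model")
  expect_gt(cor(model$filters$RUN_TO_TURN$h, truth$filters$RUN_TO_TURN$h), 0.8)
  expect_gt(model$provenance$r_squared$RUN_TO_TURN, 0.5)
  expect_equal(model$provenance$n_tracks, 80)

  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$filters$RUN_TO_TURN$h, model$filters$RUN_TO_TURN$h)
  expect_equal(back$nonlins$TURN_TO_RUN$params, model$nonlins$TURN_TO_RUN$params)
  s2 <- make_step(60, switch_times = 30)
  expect_equal(predict_response(back, s2), predict_response(model, s2))
})
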
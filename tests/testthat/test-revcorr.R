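test_that("triggered averages of trivial inputs are exact", {
  const <- stimulus_train(rep(1, 100))
  ev <- data.frame(animal_id = "a", time_s = c(10, 15, 20),
                   kind = "RUN_TO_TURN")
  ta <- triggered_average(ev, const, "RUN_TO_TURN", window = 2)
  expect_true(all(ta$mean == 1))
  expect_true(all(ta$sem == 0))
  expect_equal(ta$lags, seq(-2, 0, by = 0.25))

  # single event: the average is the stimulus history verbatim
  set.seed(3)
  s <- stimulus_train(sample(c(-1, 1), 40, replace = TRUE))
  ev1 <- data.frame(animal_id = "a", time_s = 2, kind = "RUN_TO_TURN")
  ta1 <- triggered_average(ev1, s, "RUN_TO_TURN", window = 1)
  i <- round(2 / 0.25) + 1
  expect_equal(ta1$mean, s$values[(i - 4):i]) # 5 samples, lags -1 ... 0
  expect_equal(ta1$n_events, 1)
})

test_that("triggered_average equals the naive double-loop oracle", {
  set.seed(11)
  s <- stimulus_train(sample(c(-1, 1), 200, replace = TRUE))
  idx <- c(30, 41, 55, 78, 90, 120, 150, 166, 180, 195) # 1-based samples
  ev <- data.frame(animal_id = "a", time_s = (idx - 1) * 0.25,
                   kind = "TURN_TO_RUN")
  ta <- triggered_average(ev, s, "TURN_TO_RUN", window = 4)
  oracle <- naive_triggered_average(idx, s$values, n_lags = 17)
  expect_equal(ta$mean, oracle, tolerance = 1e-15)
})

test_that("events placed independently of the stimulus give a flat average", {
  s <- generate_bernoulli(3000, seed = 12)
  ev <- null_events(1e4, 10, 2990, seed = 13)
  ta <- triggered_average(ev, s, "RUN_TO_TURN", window = 4)
  expect_true(all(abs(ta$mean) < 3 / sqrt(1e4)))
})

test_that("events with truncated history are excluded and counted", {
  s <- generate_bernoulli(100, seed = 14)
  ev <- data.frame(animal_id = "a", time_s = c(1, 2, 50, 60),
                   kind = "RUN_TO_TURN")
  ta <- triggered_average(ev, s, "RUN_TO_TURN", window = 4)
  expect_equal(ta$n_events, 2)
  expect_equal(ta$n_excluded, 2)

  all_early <- ev[1:2, ]
  expect_error(triggered_average(all_early, s, "RUN_TO_TURN", window = 4),
               class = "optorc_empty_result")
  expect_error(triggered_average(ev, s, "TURN_TO_RUN", window = 4),
               class = "optorc_empty_result")
})

test_that("filter_from_ta applies the mean-event-rate scaling", {
  s <- stimulus_train(rep(1, 200))
  ev <- data.frame(animal_id = "a", time_s = c(10, 20, 30), kind = "RUN_TO_TURN")
  ta <- triggered_average(ev, s, "RUN_TO_TURN", window = 2)
  f <- filter_from_ta(ta, mean_events_per_trial = 10, trial_duration = 1200)
  expect_equal(f$h, rep(10 / 1200, 9))
  expect_equal(f$taus, seq(0, 2, by = 0.25))

  ta0 <- ta; ta0$mean <- rep(0, 9)
  expect_true(all(filter_from_ta(ta0, 10)$h == 0))
  expect_error(filter_from_ta(ta, 10, trial_duration = 0),
               class = "optorc_invalid_argument")
})

test_that("time reversal maps an impulse at lag -tau* to a tap at tau*", {
  s <- generate_bernoulli(200, seed = 15)
  ev <- null_events(50, 10, 190, seed = 16)
  ta <- triggered_average(ev, s, "RUN_TO_TURN", window = 2)
  ta$mean <- as.numeric(ta$lags == -0.5)
  f <- filter_from_ta(ta, 12)
  expect_equal(f$taus[which.max(f$h)], 0.5)
})

test_that("SEM shrinks as 1/sqrt(n_events)", {
  s <- generate_bernoulli(6000, seed = 17)
  sems <- sapply(c(100, 1000, 10000), function(n) {
    ev <- null_events(n, 10, 5990, seed = n)
    mean(triggered_average(ev, s, "RUN_TO_TURN")$sem)
  })
  ratios <- sems[-3] / sems[-1] # expect ~ sqrt(10) = 3.16
  expect_true(all(ratios > 2.2 & ratios < 4.5))
})

test_that("per-animal weighting equalizes unbalanced animals", {
  s <- stimulus_train(rep(c(1, -1), 100))
  # animal b contributes 9x the events of animal a
  ev <- data.frame(
    animal_id = c("a", rep("b", 9)),
    time_s = c(10, 20 + (1:9) * 2.5),
    kind = "RUN_TO_TURN"
  )
  pooled <- triggered_average(ev, s, "RUN_TO_TURN", window = 1)
  per_an <- triggered_average(ev, s, "RUN_TO_TURN", window = 1,
                              weighting = "per_animal")
  expect_equal(per_an$n, 2) # SEM across animals
  expect_equal(pooled$n, 10)
})

test_that("TA CSV and filter JSON round-trip", {
  s <- generate_bernoulli(300, seed = 18)
  ev <- null_events(40, 10, 290, seed = 19)
  ta <- triggered_average(ev, s, "RUN_TO_TURN")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_ta_csv(ta, p1)
  back <- read_ta_csv(p1)
  expect_equal(back$mean, ta$mean)
  expect_equal(back$sd, ta$sd)
  expect_equal(back$n, ta$n)

  f <- filter_from_ta(ta, 15)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_filter_json(f, p2)
  f2 <- read_filter_json(p2)
  expect_equal(f2$h, f$h)
  expect_equal(f2$kind, f$kind)
})
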
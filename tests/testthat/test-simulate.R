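test_that("simulation is deterministic and reproducible animal-by-animal", {
  truth <- default_ground_truth("repulsive-monophasic")
  stim <- generate_bernoulli(120, seed = 1)
  a <- simulate_population(truth, stim, n_animals = 4, seed = 10)
  b <- simulate_population(truth, stim, n_animals = 4, seed = 10)
  expect_identical(lapply(a, `[[`, "states"), lapply(b, `[[`, "states"))

  # counter scheme: animal i is the same track in a larger population
  big <- simulate_population(truth, stim, n_animals = 6, seed = 10)
  expect_identical(a[[3]]$states, big[[3]]$states)

  c_ <- simulate_population(truth, stim, n_animals = 4, seed = 11)
  expect_false(identical(lapply(a, `[[`, "states"), lapply(c_, `[[`, "states")))
})

test_that("zero run-to-turn hazard makes RUN absorbing", {
  m <- constant_hazard_model(0, 0.5)
  stim <- generate_bernoulli(60, seed = 2)
  pop <- simulate_population(m, stim, n_animals = 5, seed = 3)
  for (tr in pop) expect_true(all(tr$states == "RUN"))
})

test_that("constant-hazard run bouts match the discrete closed form", {
  r <- 0.2
  m <- constant_hazard_model(r, r)
  stim <- generate_bernoulli(1200, seed = 4)
  pop <- simulate_population(m, stim, n_animals = 300, seed = 40)
  bouts <- unlist(lapply(pop, function(tr) {
    rl <- rle(tr$states)
    k <- rl$lengths[rl$values == "RUN"]
    if (length(k) > 2) k[-c(1, length(k))] else integer() # drop censored ends
  }))
  expect_gt(length(bouts), 2e4)
  closed_form <- stim$dt / (1 - exp(-r * stim$dt)) # mean of the geometric bout
  expect_lt(abs(mean(bouts) * stim$dt / closed_form - 1), 0.02)
})

test_that("every animal conserves event counts between the two kinds", {
  truth <- default_ground_truth("attractive-biphasic")
  stim <- generate_bernoulli(1200, seed = 5)
  pop <- simulate_population(truth, stim, n_animals = 25, seed = 50)
  ev <- extract_transitions(pop)
  tab <- table(ev$animal_id, ev$kind)
  expect_true(all(abs(tab[, "RUN_TO_TURN"] - tab[, "TURN_TO_RUN"]) <= 1))
})

test_that("speed traces are state-dependent with a pre-turn ramp", {
  truth <- default_ground_truth("repulsive-monophasic")
  stim <- generate_bernoulli(600, seed = 6)
  sm <- speed_model()
  pop <- simulate_population(truth, stim, n_animals = 8, seed = 60,
                             speed_model = sm)
  for (tr in pop) {
    expect_equal(length(tr$speed), length(tr$states))
    run <- tr$states == "RUN"
    if (any(run) && any(!run)) {
      expect_gt(mean(tr$speed[run]), mean(tr$speed[!run]))
    }
  }
})

test_that("default ground truths have the documented shape classes", {
  rm_ <- default_ground_truth("repulsive-monophasic")
  h <- rm_$filters$RUN_TO_TURN$h
  expect_true(all(h >= 0))
  expect_true(all(h[rm_$filters$RUN_TO_TURN$taus > 2] == 0)) # lobe in last 2 s
  expect_equal(sum(diff(h > 0) == 1), 1) # a single lobe

  am <- default_ground_truth("attractive-monophasic")
  expect_true(all(am$filters$RUN_TO_TURN$h <= 0))
  expect_equal(am$filters$RUN_TO_TURN$h, -h)

  for (kind in c("repulsive-biphasic", "attractive-biphasic")) {
    hb <- default_ground_truth(kind)$filters$RUN_TO_TURN$h
    dt <- 0.25
    expect_lt(abs(sum(hb * dt)), sum(pmax(hb, 0) * dt)) # opposing lobes
    expect_lt(abs(sum(hb * dt)), 1e-9) # designed to integrate to zero
  }

  # turn-to-run filter sign is opposite to the run-to-turn valence
  expect_lt(sum(rm_$filters$TURN_TO_RUN$h), 0)
  expect_gt(sum(am$filters$TURN_TO_RUN$h), 0)

  expect_error(default_ground_truth("spiral"), class = "optorc_invalid_argument")
})

test_that("non-finite hazards abort with the offending time bin named", {
  bad <- constant_hazard_model(0.1, 0.1)
  bad$nonlins$RUN_TO_TURN$params$intercept <- Inf
  stim <- generate_bernoulli(10, seed = 7)
  expect_error(simulate_population(bad, stim, 2, seed = 1),
               "time bin", class = "optorc_simulation_failure")
})

test_that("tracks CSV round-trips states and speed", {
  truth <- default_ground_truth("repulsive-monophasic")
  stim <- generate_bernoulli(60, seed = 8)
  pop <- simulate_population(truth, stim, n_animals = 3, seed = 80,
                             speed_model = speed_model())
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(pop, path)
  back <- read_tracks_csv(path)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    orig <- pop[[i]]
    r <- back[[orig$animal_id]]
    expect_identical(r$states, orig$states)
    expect_equal(r$speed, orig$speed, tolerance = 1e-12)
    expect_equal(r$dt, orig$dt)
  }
})
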
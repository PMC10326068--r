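test_that("absorbing or rate-free models give a single-segment trajectory", {
  tr <- simulate_trajectory(rate_set(), "BFC", t_max = 50, seed = 1)
  expect_equal(nrow(tr$segments), 1L)
  expect_equal(tr$segments$state, "BFC")
  expect_equal(tr$segments$entry_time, 0)
  expect_equal(tr$t_end, 50)
  expect_error(simulate_trajectory(rate_set(), "XYZ", 10, seed = 1),
               "unknown state")
})

test_that("identical seeds give identical trajectories and cohorts", {
  r <- two_route_rates()
  expect_identical(simulate_trajectory(r, "BFC", 100, seed = 42),
                   simulate_trajectory(r, "BFC", 100, seed = 42))
  a <- simulate_cohort(r, 50, "BFC", window = 100, seed = 9)
  b <- simulate_cohort(r, 50, "BFC", window = 100, seed = 9)
  expect_identical(a$events, b$events)
  expect_identical(a$trajectories, b$trajectories)
  # and the CSV round-trip is faithful
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(a$events, path)
  expect_equal(read_event_table(path)$t_event, a$events$t_event)
})

test_that("sojourn times and route choice follow the exponential CTMC law", {
  r <- two_route_rates(0.05, 0.05)
  sim <- simulate_cohort(r, 10000, "BFC", window = 1000, seed = 123)
  ev <- sim$events
  expect_true(all(!ev$censored))  # window >> mean lifetime
  # route: binomial oracle, p = 0.5
  p_bf <- mean(ev$outcome == "to_BF")
  expect_lt(abs(p_bf - 0.5), 3 * sqrt(0.25 / 10000))
  # mean lifetime: exponential oracle 1/(k'_C + k'_F) = 10 s
  expect_lt(abs(mean(ev$t_event) - 10), 3 * 10 / sqrt(10000))
  # full distributional check
  ks <- suppressWarnings(stats::ks.test(ev$t_event, "pexp", 0.1))
  expect_gt(ks$p.value, 0.001)
})

test_that("asymmetric routes recover the k'_C/(k'_C+k'_F) fraction", {
  r <- two_route_rates(0.02, 0.01)
  sim <- simulate_cohort(r, 5000, "BFC", window = 2000, seed = 77)
  p_bf <- mean(sim$events$outcome == "to_BF")
  expect_lt(abs(p_bf - 2 / 3), 3 * sqrt(2 / 9 / 5000))
})

test_that("short windows censor at the closed-form rate", {
  r <- two_route_rates(0.05, 0.05)   # k = 0.1, mean lifetime 10 s
  window <- 1
  sim <- simulate_cohort(r, 4000, "BFC", window = window, seed = 5)
  p_obs <- 1 - exp(-0.1 * window)
  n_obs <- sum(!sim$events$censored)
  expect_lt(abs(n_obs - 4000 * p_obs), 3 * sqrt(4000 * p_obs * (1 - p_obs)))
  expect_true(all(sim$events$t_event[sim$events$censored] == window))
  expect_true(all(sim$events$outcome[sim$events$censored] == "censored"))
})

test_that("visit counts before uncapping are geometric with mean 1/p", {
  p <- 0.2
  r <- visit_rates(p = p, dwell_mean = 1, arrival = 1)
  visits <- vapply(1:3000, function(i) {
    tr <- simulate_trajectory(r, "BC", 500, seed = i)
    sum(tr$segments$state == "BCT")
  }, numeric(1))
  expect_lt(abs(mean(visits) - 1 / p), 3 * sd(visits) / sqrt(length(visits)))
  # chi-square goodness of fit against geometric(p), tail pooled
  kmax <- 15
  obs <- tabulate(pmin(visits, kmax), nbins = kmax)
  probs <- c(dgeom(0:(kmax - 2), p), 1 - pgeom(kmax - 2, p))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("empty cohorts and missing seeds are handled", {
  sim <- simulate_cohort(two_route_rates(), 0, "BFC", window = 10, seed = 1)
  expect_equal(nrow(sim$events), 0L)
  expect_error(simulate_cohort(two_route_rates(), 5, "BFC", window = 10),
               "seed")
})

test_that("ground-truth presence follows the majority-of-interval rule", {
  # constructed two-segment trajectory: BCT for 10 s, then BC
  traj <- structure(list(
    filament_id = 1L,
    segments = data.frame(state = c("BCT", "BC"), entry_time = c(0, 10)),
    t_end = 20), class = "state_trajectory")
  gt <- presence_ground_truth(traj, "twinfilin", 1)
  expect_equal(sum(gt), 10)
  expect_equal(gt[1:10], rep(1L, 10))
  # a sub-frame sojourn registers at most one frame, 0 if it straddles
  short1 <- structure(list(  # 0.4 s centred in frame 2
    filament_id = 1L,
    segments = data.frame(state = c("BC", "BCT", "BC"),
                          entry_time = c(0, 2.3, 2.7)),
    t_end = 5), class = "state_trajectory")
  expect_equal(sum(presence_ground_truth(short1, "twinfilin", 1)), 0)
  short2 <- structure(list(  # 0.8 s centred in frame 2
    filament_id = 1L,
    segments = data.frame(state = c("BC", "BCT", "BC"),
                          entry_time = c(0, 2.1, 2.9)),
    t_end = 5), class = "state_trajectory")
  expect_equal(sum(presence_ground_truth(short2, "twinfilin", 1)), 1)
  # a protein never present gives an all-zero vector
  expect_equal(sum(presence_ground_truth(traj, "formin", 1)), 0)
})

test_that("rendered traces report presence, length and bleaching", {
  bfc <- structure(list(
    filament_id = 1L,
    segments = data.frame(state = "BFC", entry_time = 0),
    t_end = 10), class = "state_trajectory")
  cp <- render_trace(bfc, "CP", frame_interval = 1)
  expect_true(all(cp$values == 1))
  # length channel integrates the per-state velocity
  bf <- structure(list(
    filament_id = 1L,
    segments = data.frame(state = "BF", entry_time = 0),
    t_end = 10), class = "state_trajectory")
  r <- rate_set(velocities = c(BF = 0.05))
  len <- render_trace(bf, "length", 1, rates = r)
  expect_equal(len$values, 0.05 * (0:10), tolerance = 1e-12)
  # very fast bleaching kills the signal despite constant occupancy
  bl <- render_trace(bfc, "CP", 1, bleach_rate = 100, seed = 3)
  expect_lt(mean(bl$values > 0.5), 0.2)
  expect_error(render_trace(bfc, "nope", 1), "unknown channel")
})

test_that("noiseless rendering is exactly the ground-truth presence", {
  r <- visit_rates(p = 0.1, dwell_mean = 2, arrival = 0.2)
  for (i in 1:20) {
    tr <- simulate_trajectory(r, "BC", t_max = 300, seed = 1000 + i)
    gt <- presence_ground_truth(tr, "twinfilin", 0.5)
    trc <- render_trace(tr, "twinfilin", 0.5)
    iv <- binarize_trace(trc, threshold = 0.5)
    expect_intervals_match_binary(iv$intervals, gt)
  }
})

test_that("trace CSV round-trips", {
  tr <- simulate_trajectory(visit_rates(), "BC", 50, seed = 8)
  trc <- render_trace(tr, "twinfilin", 0.5, noise_sd = 0.1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(trc, path)
  back <- read_traces(path)[[1]]
  expect_equal(back$values, trc$values, tolerance = 1e-6)
  expect_equal(back$frame_interval, 0.5)
})
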
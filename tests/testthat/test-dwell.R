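test_that("binarization finds, merges and filters presence runs", {
  expect_equal(nrow(binarize_trace(make_trace(rep(0, 30)), 0.5)$intervals), 0L)
  # clean pulse on frames 10..19 at 1 s/frame -> one 10 s interval
  v <- rep(0, 30); v[11:20] <- 1
  iv <- binarize_trace(make_trace(v), 0.5)$intervals
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start_frame, 10L)
  expect_equal(iv$end_frame, 20L)
  expect_false(iv$single_frame)
  # pulses 5..9 and 11..14 merge across a single off frame
  v <- rep(0, 20); v[6:10] <- 1; v[12:15] <- 1
  ivm <- binarize_trace(make_trace(v), 0.5, gap_tolerance = 1)$intervals
  expect_equal(nrow(ivm), 1L)
  expect_equal(c(ivm$start_frame, ivm$end_frame), c(5L, 15L))
  # without tolerance they stay separate; min_frames drops the short one
  iv2 <- binarize_trace(make_trace(v), 0.5)$intervals
  expect_equal(nrow(iv2), 2L)
  iv5 <- binarize_trace(make_trace(v), 0.5, min_frames = 5)$intervals
  expect_equal(nrow(iv5), 1L)
  # single-frame events are flagged as lower bounds
  v <- rep(0, 10); v[4] <- 1
  ivf <- binarize_trace(make_trace(v), 0.5)$intervals
  expect_true(ivf$single_frame)
  expect_error(binarize_trace(make_trace(numeric(0)), 0.5), "empty")
})

test_that("auto threshold separates baseline from the on level", {
  set.seed(5)
  v <- c(rnorm(200, 0, 0.05), rnorm(100, 1, 0.05))[sample(300)]
  thr <- barbedend:::auto_threshold(v)
  expect_gt(thr, 0.3); expect_lt(thr, 0.7)
})

test_that("dwell summary reports untrimmed mean and sem", {
  d1 <- dwell_summary(1.4)
  expect_equal(d1$mean, 1.4)
  expect_equal(d1$sem, 0)
  expect_true(d1$sem_undefined)
  d3 <- dwell_summary(c(1, 2, 3))
  expect_equal(d3$mean, 2)
  expect_equal(d3$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(d3$n_events, 3L)
  expect_error(dwell_summary(numeric(0)), "no dwell")
  # intervals input: durations in seconds honour the frame interval
  v <- rep(0, 20); v[3:6] <- 1
  iv <- binarize_trace(make_trace(v, frame_interval = 0.3), 0.5)
  expect_equal(dwell_summary(iv)$mean, 4 * 0.3, tolerance = 1e-12)
})

test_that("dwell mean matches the simulator's residence time", {
  set.seed(88)
  durations <- rexp(5000, 1 / 1.9)
  ds <- dwell_summary(durations)
  expect_lt(abs(ds$mean - 1.9), 3 * ds$sem)
})

test_that("visit counting includes the final uncapping visit", {
  # three pulses; uncapping during the third
  v <- rep(0, 30); v[c(3:4, 10:12, 20:22)] <- 1
  p <- binarize_trace(make_trace(v), 0.5)
  expect_equal(visits_until_uncapping(p, t_uncap = 20.5)$n_visits, 3L)
  expect_equal(visits_until_uncapping(p, t_uncap = 15)$n_visits, 2L)
  # spontaneous uncapping with no prior visits
  p0 <- binarize_trace(make_trace(rep(0, 30)), 0.5)
  r0 <- visits_until_uncapping(p0, t_uncap = 5)
  expect_equal(r0$n_visits, 0L)
  expect_true(r0$resolved)
  # unresolved filament
  ru <- visits_until_uncapping(p, t_uncap = NA)
  expect_false(ru$resolved)
  expect_equal(ru$n_visits, 3L)
  expect_error(visits_until_uncapping(
    binarize_trace(make_trace(v, t0 = 10), 0.5), t_uncap = 5), "precedes")
})

test_that("per-visit uncapping probability inverts the mean visit count", {
  recs <- lapply(1:5, function(i)
    structure(list(filament_id = i, n_visits = 1, t_uncap = 1,
                   resolved = TRUE), class = "uncap_visit_record"))
  est <- estimate_uncap_probability(recs, reps = 50, seed = 1)
  expect_equal(est$p_hat, 1)
  # reciprocal of the published 30.9-visit mean
  recs2 <- lapply(c(30, 31, 31.7), function(v)
    structure(list(filament_id = 1, n_visits = v, t_uncap = 1,
                   resolved = TRUE), class = "uncap_visit_record"))
  est2 <- estimate_uncap_probability(recs2, reps = 50, seed = 1)
  expect_equal(est2$mean_visits, 30.9, tolerance = 1e-12)
  expect_equal(est2$p_hat, 1 / 30.9, tolerance = 1e-12)
  # Monte-Carlo recovery of a known p from geometric counts
  set.seed(21)
  counts <- rgeom(5000, 0.2) + 1
  recs3 <- lapply(counts, function(v)
    structure(list(filament_id = 1, n_visits = v, t_uncap = 1,
                   resolved = TRUE), class = "uncap_visit_record"))
  est3 <- estimate_uncap_probability(recs3, reps = 100, seed = 2)
  expect_gt(est3$p_hat, 0.18); expect_lt(est3$p_hat, 0.22)
  expect_error(estimate_uncap_probability(list(
    structure(list(filament_id = 1, n_visits = 3, t_uncap = NA,
                   resolved = FALSE), class = "uncap_visit_record"))),
    "resolved")
})

test_that("frame-sampled dwell times bound the truth near the frame interval", {
  # dwells much longer than the frame interval are recovered closely;
  # sub-frame dwells are flagged lower bounds when they register at all
  r <- visit_rates(p = 0.1, dwell_mean = 5, arrival = 0.02)
  ivs <- lapply(1:50, function(i) {
    tr <- simulate_trajectory(r, "BC", 2000, seed = 400 + i)
    binarize_trace(render_trace(tr, "twinfilin", 0.5), 0.5)
  })
  ds <- dwell_summary(ivs)
  expect_lt(abs(ds$mean - 5), 0.5)  # within one frame interval of truth
})

test_that("bleach step counting classifies staircase traces", {
  expect_equal(count_bleach_steps(make_trace(rep(1, 50)), 0.5), 0L)
  stair <- make_trace(c(rep(2, 30), rep(1, 30), rep(0, 40)))
  expect_equal(count_bleach_steps(stair, 0.5), 2L)
  # an upward jump is not a bleaching step
  up <- make_trace(c(rep(0, 30), rep(1, 30)))
  expect_equal(count_bleach_steps(up, 0.5), 0L)
  # noisy single step detected in >= 95% of seeded replicates
  hits <- vapply(1:500, function(s) {
    set.seed(s)
    v <- c(rep(1, 50), rep(0, 50)) + rnorm(100, 0, 0.1)
    count_bleach_steps(make_trace(v), 0.5) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("depolymerization onset marks sustained length decrease", {
  v <- c(seq(0, 5, by = 0.5), rep(5, 5), seq(4.8, 3, by = -0.2))
  tr <- make_trace(v, frame_interval = 1, channel = "length")
  expect_equal(detect_depolymerization_onset(tr), 15)
  flat <- make_trace(rep(1, 20), channel = "length")
  expect_true(is.na(detect_depolymerization_onset(flat)))
})
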
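# Shared fixtures: small rate sets and trace constructors used across tests.

# symmetric two-route decision-complex model, no twinfilin
two_route_rates <- function(kc = 0.05, kf = 0.05) {
  rate_set(kprime_minus_C = kc, kprime_minus_F = kf)
}

# mechanistic CP-only uncapping model: BC <-> BCT visits, geometric uncapping
visit_rates <- function(p = 1 / 31, dwell_mean = 1.9, arrival = 0.05) {
  rate_set(k_minus_T = 1 / dwell_mean, p_uncap_BCT = p,
           k_on_T = 1, conc_T = arrival)
}

# channel_trace from a raw value vector
make_trace <- function(values, frame_interval = 1, t0 = 0, channel = "twinfilin",
                       filament_id = 1L) {
  structure(list(filament_id = filament_id, channel = channel,
                 frame_interval = frame_interval, t0 = t0, values = values),
            class = "channel_trace")
}

# event_table from outcome counts (exponential times; rate only sets scale)
make_events <- function(n_bf, n_bc, rate = 0.01, n_censored = 0,
                        window = 1000, seed = 1) {
  n <- n_bf + n_bc
  set.seed(seed)
  t_event <- sort(stats::rexp(n, rate))
  df <- data.frame(
    filament_id = seq_len(n + n_censored),
    t_event = c(t_event, rep(window, n_censored)),
    outcome = c(rep(c("to_BF", "to_BC"), c(n_bf, n_bc)), rep("censored", n_censored)),
    censored = rep(c(FALSE, TRUE), c(n, n_censored)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("event_table", "data.frame")
  df
}

# presence intervals reconstructed from a 0/1 ground-truth vector
intervals_from_binary <- function(gt) {
  r <- rle(as.logical(gt))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(start = as.integer(starts[r$values] - 1L),
       end = as.integer(ends[r$values]))
}

expect_intervals_match_binary <- function(intervals, gt) {
  ref <- intervals_from_binary(gt)
  testthat::expect_equal(as.integer(intervals$start_frame), ref$start)
  testthat::expect_equal(as.integer(intervals$end_frame), ref$end)
}
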
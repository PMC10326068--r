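# Fraction of each frame interval occupied by the given set of states.
# Frame k covers [t0 + k*dt, t0 + (k+1)*dt); there are
# floor((t_end - t0)/dt) + 1 frames, the last padded with the final state.
frame_occupancy <- function(traj, states, frame_interval, t0 = 0) {
  dt <- frame_interval
  stopifnot(dt > 0, t0 >= 0, t0 <= traj$t_end)
  n_frames <- floor((traj$t_end - t0) / dt) + 1L
  seg <- traj$segments
  starts <- seg$entry_time
  ends <- c(seg$entry_time[-1L], max(traj$t_end, t0 + n_frames * dt))
  occ <- numeric(n_frames)
  keep <- seg$state %in% states
  for (i in which(keep)) {
    s <- max(starts[i], t0); e <- min(ends[i], t0 + n_frames * dt)
    if (e <= s) next
    k0 <- floor((s - t0) / dt); k1 <- min(ceiling((e - t0) / dt) - 1, n_frames - 1L)
    ks <- k0:k1
    ov <- pmin(e, t0 + (ks + 1) * dt) - pmax(s, t0 + ks * dt)
    occ[ks + 1L] <- occ[ks + 1L] + ov
  }
  occ / dt
}

#' Ground-truth frame-sampled presence of a protein
#'
#' Deterministic binary indicator, per frame, of whether the given protein
#' occupies the barbed end for the majority of the frame interval (the same
#' majority-of-interval rule used by [render_trace()], under which
#' sub-frame events can vanish — measured single-frame dwells are lower
#' bounds).
#'
#' @param traj A `state_trajectory`.
#' @param protein One of `"actin"`, `"formin"`, `"CP"`, `"twinfilin"`.
#' @param frame_interval Frame interval (s).
#' @param t0 Time of the first frame (s).
#' @return Integer vector of 0/1, one per frame.
#' @export
presence_ground_truth <- function(traj, protein, frame_interval, t0 = 0) {
  if (!protein %in% names(.protein_states))
    stop("unknown protein: ", protein)
  as.integer(frame_occupancy(traj, .protein_states[[protein]],
                             frame_interval, t0) > 0.5)
}

#' Render a frame-sampled fluorescence or length trace
#'
#' Observation layer of the simulator: converts a state trajectory into the
#' kind of 1-D time series extracted from a TIRF movie. Fluorescence
#' channels report (presence of the channel's protein in the majority of
#' the frame) x (number of unbleached fluorophores) plus Gaussian noise;
#' photobleaching is one irreversible exponential off-time per fluorophore.
#' The `length` channel integrates the per-state elongation velocity of the
#' trajectory's [rate_set()].
#'
#' @param traj A `state_trajectory`.
#' @param channel One of `"actin"`, `"formin"`, `"CP"`, `"twinfilin"`,
#'   `"length"`.
#' @param frame_interval Frame interval (s).
#' @param noise_sd Gaussian noise sd (intensity units, or um for length).
#' @param bleach_rate Photobleaching rate per fluorophore (s^-1).
#' @param seed Integer seed for noise and bleaching; `NULL` uses the
#'   caller's RNG stream.
#' @param n_fluorophores Fluorophores per molecule (1 for CP/twinfilin;
#'   up to 2 for dimeric formin).
#' @param rates The [rate_set()] supplying velocities (length channel only).
#' @param t0 Time of the first frame (s).
#' @return A `channel_trace`: list with `filament_id`, `channel`,
#'   `frame_interval`, `t0` and per-frame `values`.
#' @export
render_trace <- function(traj, channel, frame_interval, noise_sd = 0,
                         bleach_rate = 0, seed = NULL, n_fluorophores = 1L,
                         rates = NULL, t0 = 0) {
  dt <- frame_interval
  stopifnot(dt > 0, noise_sd >= 0, bleach_rate >= 0)
  if (!channel %in% c(names(.protein_states), "length"))
    stop("unknown channel: ", channel)
  n_frames <- floor((traj$t_end - t0) / dt) + 1L
  with_seed(seed, {
    if (channel == "length") {
      vel <- if (is.null(rates)) stats::setNames(numeric(8), BARBED_STATES) else
        rates$velocities
      base <- .length_at(traj, vel, t0 + (seq_len(n_frames) - 1L) * dt)
    } else {
      present <- frame_occupancy(traj, .protein_states[[channel]], dt, t0) > 0.5
      if (bleach_rate > 0) {
        t_bleach <- stats::rexp(n_fluorophores, bleach_rate)
        mid <- t0 + (seq_len(n_frames) - 0.5) * dt
        alive <- vapply(mid, function(m) sum(t_bleach > m - t0), numeric(1))
      } else {
        alive <- rep(n_fluorophores, n_frames)
      }
      base <- as.numeric(present) * alive
    }
    values <- base + if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
    structure(list(filament_id = traj$filament_id, channel = channel,
                   frame_interval = dt, t0 = t0, values = values),
              class = "channel_trace")
  })
}

# Filament length (um) at the requested times: integral of the per-state
# velocity along the trajectory, starting from 0 at t = 0.
.length_at <- function(traj, velocities, times) {
  seg <- traj$segments
  starts <- seg$entry_time
  ends <- c(seg$entry_time[-1L], max(traj$t_end, max(times)))
  v <- velocities[seg$state]
  cumlen <- c(0, cumsum(v * (ends - starts)))
  vapply(times, function(t) {
    i <- findInterval(t, starts)
    if (i < 1L) return(0)
    cumlen[i] + v[i] * (min(t, ends[i]) - starts[i])
  }, numeric(1))
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("Channel trace: filament %s, channel %s, %d frames @ %g s\n",
              x$filament_id, x$channel, length(x$values), x$frame_interval))
  invisible(x)
}

#' Read / write channel traces as long-format CSV
#'
#' Columns: `filament_id,channel,frame,time_s,value` (frame is 0-based).
#'
#' @param traces A `channel_trace` or list of them.
#' @param path File path.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "channel_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    k <- seq_along(tr$values) - 1L
    data.frame(filament_id = tr$filament_id, channel = tr$channel,
               frame = k, time_s = tr$t0 + k * tr$frame_interval,
               value = tr$values, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @return `read_traces()` returns a named list of `channel_trace` objects
#'   (one per filament x channel).
#' @export
read_traces <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filament_id", "channel", "frame", "time_s", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("trace table is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (key in unique(paste(x$filament_id, x$channel, sep = "."))) {
    sub <- x[paste(x$filament_id, x$channel, sep = ".") == key, ]
    sub <- sub[order(sub$frame), ]
    dt <- if (nrow(sub) > 1) stats::median(diff(sub$time_s)) else 1
    out[[key]] <- structure(
      list(filament_id = sub$filament_id[1L], channel = sub$channel[1L],
           frame_interval = dt, t0 = sub$time_s[1L], values = sub$value),
      class = "channel_trace")
  }
  out
}
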
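# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Per-filament seed derived from a cohort seed
#'
#' Counter-based scheme used by [simulate_cohort()]: filament `i` of a
#' cohort seeded with `cohort_seed` uses
#' `(cohort_seed + 100003 * i) mod (2^31 - 1)`, so cohorts are
#' reproducible and independent of simulation order.
#'
#' @param cohort_seed Integer cohort seed.
#' @param i Filament counter (1-based).
#' @return An integer seed.
#' @export
filament_seed <- function(cohort_seed, i) {
  as.integer((as.numeric(cohort_seed) + 100003 * as.numeric(i)) %% 2147483647)
}

#' Simulate one barbed-end state trajectory (Gillespie)
#'
#' Exact stochastic simulation of the continuous-time Markov chain defined
#' by [build_transition_table()]: in each state the sojourn time is
#' exponential with the state's total exit propensity, and the next state
#' is chosen with probability proportional to the edge propensity.
#'
#' @param rates A [rate_set()].
#' @param initial_state One of [BARBED_STATES].
#' @param t_max Observation window (s).
#' @param seed Integer seed; identical seeds give identical trajectories.
#'   `NULL` uses (and advances) the caller's RNG stream.
#' @param filament_id Identifier stored on the trajectory.
#' @return A `state_trajectory`: list with `filament_id`, `segments` (data
#'   frame of `state`, `entry_time`) and `t_end = t_max`. The last segment
#'   extends to `t_end` or is an absorbing state.
#' @export
simulate_trajectory <- function(rates, initial_state = "BFC", t_max,
                                seed = NULL, filament_id = 1L) {
  stopifnot(inherits(rates, "rate_set"), t_max > 0)
  if (!initial_state %in% BARBED_STATES)
    stop("unknown state: ", initial_state)
  edges <- .edge_index(build_transition_table(rates))
  with_seed(seed, .gillespie(edges, initial_state, t_max, filament_id))
}

# index positive-propensity edges by from-state once per rate set
.edge_index <- function(tab) {
  keep <- tab$propensity > 0
  split(tab[keep, c("to", "propensity")],
        factor(tab$from[keep], levels = BARBED_STATES))
}

.gillespie <- function(edges, initial_state, t_max, filament_id) {
  states <- character(64L); times <- numeric(64L)
  n <- 1L; states[1L] <- initial_state; times[1L] <- 0
  t <- 0; cur <- initial_state
  repeat {
    out <- edges[[cur]]
    a0 <- if (is.null(out)) 0 else sum(out$propensity)
    if (a0 <= 0) break
    t <- t + stats::rexp(1L, a0)
    if (t >= t_max) break
    cur <- if (nrow(out) == 1L) out$to else
      sample(out$to, 1L, prob = out$propensity)
    n <- n + 1L
    if (n > length(states)) {
      states <- c(states, character(length(states)))
      times <- c(times, numeric(length(times)))
    }
    states[n] <- cur; times[n] <- t
  }
  structure(list(
    filament_id = filament_id,
    segments = data.frame(state = states[seq_len(n)],
                          entry_time = times[seq_len(n)],
                          stringsAsFactors = FALSE),
    t_end = t_max
  ), class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("Barbed-end trajectory (filament %s): %d segment(s), window %g s\n",
              x$filament_id, nrow(x$segments), x$t_end))
  print(utils::head(x$segments, 10))
  if (nrow(x$segments) > 10) cat("...\n")
  invisible(x)
}

# First resolution of the initially tracked complex, as observed in TIRF.
# BFC/BFCT cohorts: exit from {BFC, BFCT} to BF (CP left first) -> to_BF;
# to DETACHED or BCT (formin left first) -> to_BC.
# BF cohorts: filament loss (entry into DETACHED) -> to_BC.
# BC/BCT cohorts: uncapping (entry into B or UNCAPPED_DEPOL) -> uncapped.
resolve_event <- function(traj, initial_state, window) {
  seg <- traj$segments
  if (initial_state %in% c("BFC", "BFCT")) {
    complex <- c("BFC", "BFCT")
    idx <- which(!(seg$state %in% complex))
    idx <- idx[idx > 1L]
    if (length(idx)) {
      i <- idx[1L]
      out <- if (seg$state[i] == "BF") "to_BF" else "to_BC"
      return(list(t = seg$entry_time[i], outcome = out, censored = FALSE))
    }
  } else if (initial_state == "BF") {
    i <- match("DETACHED", seg$state)
    if (!is.na(i))
      return(list(t = seg$entry_time[i], outcome = "to_BC", censored = FALSE))
  } else if (initial_state %in% c("BC", "BCT")) {
    i <- which(seg$state %in% c("B", "UNCAPPED_DEPOL"))
    i <- i[i > 1L]
    if (length(i))
      return(list(t = seg$entry_time[i[1L]], outcome = "uncapped",
                  censored = FALSE))
  } else {
    stop("no resolution event defined for initial state ", initial_state)
  }
  list(t = window, outcome = "censored", censored = TRUE)
}

#' Simulate a cohort of filaments and extract the event table
#'
#' Runs one independent [simulate_trajectory()] per filament (per-filament
#' seeds derived deterministically from `seed`) and records, for each, the
#' first resolution of the initially tracked complex, or censoring at the
#' end of the observation window.
#'
#' For `BFC` cohorts the outcome is `to_BF` when CP leaves first (directly
#' or via a twinfilin visit) and `to_BC` when formin leaves first (the
#' filament is lost from view with formin). `BF` cohorts record filament
#' loss as `to_BC`; `BC` cohorts record uncapping as `uncapped`.
#'
#' @inheritParams simulate_trajectory
#' @param n_filaments Number of filaments.
#' @param window Observation window (s).
#' @param seed Cohort seed (required when `n_filaments > 0`).
#' @return A list with `trajectories` (list of `state_trajectory`) and
#'   `events` (an `event_table` data frame with columns `filament_id`,
#'   `t_event`, `outcome`, `censored`, `conc_C_uM`, `conc_T_uM`, `seed`).
#' @export
simulate_cohort <- function(rates, n_filaments, initial_state = "BFC",
                            window, seed = NULL) {
  stopifnot(inherits(rates, "rate_set"), n_filaments >= 0)
  if (n_filaments > 0 && is.null(seed))
    stop("'seed' is required for a stochastic cohort")
  if (!initial_state %in% BARBED_STATES)
    stop("unknown state: ", initial_state)
  edges <- .edge_index(build_transition_table(rates))
  trajs <- vector("list", n_filaments)
  ev <- vector("list", n_filaments)
  for (i in seq_len(n_filaments)) {
    trajs[[i]] <- with_seed(
      filament_seed(seed, i),
      .gillespie(edges, initial_state, window, filament_id = i))
    e <- resolve_event(trajs[[i]], initial_state, window)
    ev[[i]] <- data.frame(filament_id = i, t_event = e$t, outcome = e$outcome,
                          censored = e$censored, stringsAsFactors = FALSE)
  }
  events <- if (n_filaments > 0) do.call(rbind, ev) else
    data.frame(filament_id = integer(), t_event = numeric(),
               outcome = character(), censored = logical(),
               stringsAsFactors = FALSE)
  events$conc_C_uM <- rep(rates$conc_C, nrow(events))
  events$conc_T_uM <- rep(rates$conc_T, nrow(events))
  events$seed <- rep(if (is.null(seed)) NA_integer_ else seed, nrow(events))
  class(events) <- c("event_table", "data.frame")
  list(trajectories = trajs, events = events)
}

#' Read / write an event table as CSV
#'
#' Columns: `filament_id,t_event,outcome,censored,conc_C_uM,conc_T_uM,seed`;
#' times in seconds, concentrations in uM.
#'
#' @param events An `event_table` data frame.
#' @param path File path.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filament_id", "t_event", "outcome", "censored")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  x$censored <- as.logical(x$censored)
  class(x) <- c("event_table", "data.frame")
  x
}
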
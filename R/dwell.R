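#' Binarize a fluorescence trace into presence intervals
#'
#' Frames with intensity at or above the threshold are "on"; on-runs
#' separated by at most `gap_tolerance` off-frames are merged (no further
#' blinking correction); runs shorter than `min_frames` are discarded.
#' Intervals are half-open in frames, so duration is
#' `(end_frame - start_frame) * frame_interval`. Single-frame intervals
#' are flagged: their duration is a lower bound on the true dwell.
#'
#' @param trace A `channel_trace` (see [render_trace()]).
#' @param threshold Numeric intensity threshold, or `"auto"` to place it
#'   midway between the baseline and single-fluorophore intensity levels
#'   estimated from the trace's histogram (2-means).
#' @param min_frames Minimum run length kept (frames).
#' @param gap_tolerance Maximum off-gap merged into a run (frames).
#' @return A `presence_intervals`: list with `filament_id`, `intervals`
#'   (data frame `start_frame`, `end_frame`, 0-based half-open,
#'   `single_frame`), `frame_interval`, `t0`.
#' @export
binarize_trace <- function(trace, threshold = "auto", min_frames = 1L,
                           gap_tolerance = 0L) {
  stopifnot(inherits(trace, "channel_trace"),
            min_frames >= 1L, gap_tolerance >= 0L)
  v <- trace$values
  if (!length(v)) stop("empty trace")
  if (identical(threshold, "auto")) {
    threshold <- auto_threshold(v)
    # a flat trace has no separable on level: nothing is "on"
    if (!is.finite(threshold)) threshold <- max(v) + 1
  }
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  on <- v >= threshold
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start_frame = starts[r$values] - 1L,
                   end_frame = ends[r$values])
  # merge runs across short off-gaps
  if (nrow(iv) > 1L && gap_tolerance > 0L) {
    keep <- logical(nrow(iv)); keep[1L] <- TRUE; j <- 1L
    for (i in 2L:nrow(iv)) {
      if (iv$start_frame[i] - iv$end_frame[j] <= gap_tolerance) {
        iv$end_frame[j] <- iv$end_frame[i]
      } else {
        j <- i; keep[i] <- TRUE
      }
    }
    iv <- iv[keep, , drop = FALSE]
  }
  iv <- iv[iv$end_frame - iv$start_frame >= min_frames, , drop = FALSE]
  rownames(iv) <- NULL
  iv$single_frame <- (iv$end_frame - iv$start_frame) == 1L
  structure(list(filament_id = trace$filament_id, intervals = iv,
                 frame_interval = trace$frame_interval, t0 = trace$t0),
            class = "presence_intervals")
}

# Midpoint between the two intensity levels found by 2-means on the frame
# values; falls back to +Inf (nothing "on") for a flat trace.
auto_threshold <- function(values) {
  u <- unique(values)
  if (length(u) < 2L) return(Inf)
  km <- suppressWarnings(stats::kmeans(values, centers = range(u)))
  mean(km$centers)
}

#' @export
print.presence_intervals <- function(x, ...) {
  cat(sprintf("Presence intervals: filament %s, %d interval(s) @ %g s/frame\n",
              x$filament_id, nrow(x$intervals), x$frame_interval))
  invisible(x)
}

#' Durations (s) of presence intervals
#' @param intervals A `presence_intervals`.
#' @return Numeric vector of dwell durations in seconds.
#' @export
interval_durations <- function(intervals) {
  iv <- intervals$intervals
  (iv$end_frame - iv$start_frame) * intervals$frame_interval
}

#' Dwell-time summary statistics
#'
#' Mean and standard error of the mean over all dwell durations, with no
#' outlier trimming: every binding event enters the mean, including
#' single-frame events whose duration is a lower bound.
#'
#' @param x A `presence_intervals`, a list of them, or a numeric vector of
#'   durations in seconds.
#' @return A `dwell_summary`: list with `n_events`, `mean`, `sem`,
#'   `durations` and a `sem_undefined` flag when `n_events < 2` (sem is
#'   reported as 0 in that case).
#' @examples
#' dwell_summary(c(1, 2, 3))  # mean 2, sem 0.577
#' @export
dwell_summary <- function(x) {
  durations <-
    if (is.numeric(x)) x
    else if (inherits(x, "presence_intervals")) interval_durations(x)
    else unlist(lapply(x, interval_durations))
  if (!length(durations)) stop("no dwell events")
  n <- length(durations)
  sem_undefined <- n < 2L
  structure(list(
    n_events = n,
    mean = mean(durations),
    sem = if (sem_undefined) 0 else stats::sd(durations) / sqrt(n),
    sem_undefined = sem_undefined,
    durations = durations
  ), class = "dwell_summary")
}

#' @export
print.dwell_summary <- function(x, ...) {
  cat(sprintf("Mean dwell time = %.3g +/- %.2g s (+/- sem, n = %d events)%s\n",
              x$mean, x$sem, x$n_events,
              if (x$sem_undefined) " [sem undefined: single event]" else ""))
  invisible(x)
}

#' Count twinfilin visits preceding uncapping
#'
#' Counts the presence intervals that began at or before the uncapping
#' time, including the final (successful) visit, for one filament.
#'
#' @param presence A `presence_intervals` for the twinfilin channel.
#' @param t_uncap Uncapping time (s): onset of depolymerization or loss of
#'   the CP channel. Use `NA`/`Inf` for a filament whose uncapping was not
#'   observed (`resolved = FALSE`; all intervals are counted).
#' @return An `uncap_visit_record`: list with `filament_id`, `n_visits`,
#'   `t_uncap`, `resolved`.
#' @export
visits_until_uncapping <- function(presence, t_uncap) {
  stopifnot(inherits(presence, "presence_intervals"))
  resolved <- is.finite(t_uncap)
  starts <- presence$t0 +
    presence$intervals$start_frame * presence$frame_interval
  if (resolved && t_uncap < presence$t0)
    stop("'t_uncap' precedes the start of the trace")
  n <- if (resolved) sum(starts <= t_uncap) else length(starts)
  structure(list(filament_id = presence$filament_id, n_visits = n,
                 t_uncap = if (resolved) t_uncap else NA_real_,
                 resolved = resolved),
            class = "uncap_visit_record")
}

#' Per-visit uncapping probability from visit counts
#'
#' Under independent visits with a fixed per-visit success probability the
#' number of visits up to and including the uncapping one is geometric, so
#' the probability is estimated as the reciprocal of the mean visit count
#' over resolved filaments. Uncertainty by nonparametric bootstrap over
#' filaments.
#'
#' @param records List of `uncap_visit_record`s (see
#'   [visits_until_uncapping()]).
#' @param reps Bootstrap replicates.
#' @param level Central interval mass.
#' @param seed Integer seed for the bootstrap.
#' @return List with `p_hat`, `mean_visits`, `n_filaments`, `ci_low`,
#'   `ci_high`, `ci_level`.
#' @export
estimate_uncap_probability <- function(records, reps = 1000, level = 0.65,
                                       seed = NULL) {
  if (inherits(records, "uncap_visit_record")) records <- list(records)
  visits <- vapply(records, function(r) r$n_visits, numeric(1))
  resolved <- vapply(records, function(r) isTRUE(r$resolved), logical(1))
  visits <- visits[resolved & visits >= 1]
  if (!length(visits)) stop("no resolved uncapping records")
  p_hat <- 1 / mean(visits)
  boot <- with_seed(seed, {
    vapply(seq_len(reps), function(i)
      1 / mean(sample(visits, replace = TRUE)), numeric(1))
  })
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(p_hat = p_hat, mean_visits = mean(visits),
       n_filaments = length(visits),
       ci_low = qs[1L], ci_high = qs[2L], ci_level = level)
}

#' Detect the onset of depolymerization in a length trace
#'
#' Operational definition of the uncapping time: the first frame from
#' which the filament length decreases for at least `min_frames`
#' consecutive frame-to-frame steps (each drop exceeding `tolerance`).
#'
#' @param trace A `channel_trace` with `channel == "length"`.
#' @param min_frames Minimum number of consecutive decreasing steps.
#' @param tolerance Minimum per-step decrease (um) counted as shrinking.
#' @return Onset time (s), or `NA` if no such run exists.
#' @export
detect_depolymerization_onset <- function(trace, min_frames = 3L,
                                          tolerance = 0) {
  stopifnot(inherits(trace, "channel_trace"))
  d <- diff(trace$values) < -tolerance
  if (!any(d)) return(NA_real_)
  r <- rle(d)
  ends <- cumsum(r$lengths)
  i <- which(r$values & r$lengths >= min_frames)
  if (!length(i)) return(NA_real_)
  start_frame <- ends[i[1L]] - r$lengths[i[1L]]  # 0-based frame of onset
  trace$t0 + start_frame * trace$frame_interval
}
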
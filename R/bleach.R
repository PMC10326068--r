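#' Count photobleaching steps in an intensity trace
#'
#' Quality-control heuristic for classifying single- versus double-step
#' bleaching profiles (monomeric versus dimeric labels). The trace is
#' smoothed with a short running mean, split into piecewise-constant
#' segments by greedy binary segmentation (a split is accepted when the
#' two segment means differ by at least `min_step`), adjacent segments
#' closer than `min_step` are merged back, and the number of downward
#' level changes of at least `min_step` between consecutive segments is
#' returned. Intended for monotone-decreasing bleaching traces; returns 0
#' on flat traces.
#'
#' @param trace A `channel_trace`, or a numeric vector of intensities.
#' @param min_step Minimum intensity drop counted as one bleaching step.
#' @param smooth Running-mean window (frames, odd; 1 disables smoothing).
#' @param min_seg Minimum segment length (frames).
#' @return Integer number of downward steps.
#' @export
count_bleach_steps <- function(trace, min_step, smooth = 3L, min_seg = 2L) {
  v <- if (inherits(trace, "channel_trace")) trace$values else trace
  if (length(v) < 3L) stop("trace must have at least 3 frames")
  stopifnot(min_step > 0)
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    v <- as.numeric(stats::filter(v, k, sides = 2))
    v <- v[!is.na(v)]
  }
  bounds <- sort(unique(c(0L, .segment_splits(v, min_step, min_seg),
                          length(v))))
  means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(v[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  # merge criterion: absorb segments indistinguishable from their neighbor
  i <- 2L
  while (i <= length(means)) {
    if (abs(means[i] - means[i - 1L]) < min_step) {
      w1 <- bounds[i] - bounds[i - 1L]; w2 <- bounds[i + 1L] - bounds[i]
      means[i - 1L] <- (means[i - 1L] * w1 + means[i] * w2) / (w1 + w2)
      means <- means[-i]; bounds <- bounds[-i]
    } else i <- i + 1L
  }
  sum(diff(means) <= -min_step)
}

# Greedy binary segmentation: recursively place the change point with the
# largest between-segment mean difference, while it exceeds min_step.
.segment_splits <- function(v, min_step, min_seg, offset = 0L) {
  n <- length(v)
  if (n < 2L * min_seg) return(integer())
  cand <- min_seg:(n - min_seg)
  cs <- cumsum(v)
  left <- cs[cand] / cand
  right <- (cs[n] - cs[cand]) / (n - cand)
  gap <- abs(left - right)
  best <- which.max(gap)
  if (gap[best] < min_step) return(integer())
  s <- cand[best]
  c(.segment_splits(v[seq_len(s)], min_step, min_seg, offset),
    offset + s,
    .segment_splits(v[(s + 1L):n], min_step, min_seg, offset + s))
}
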
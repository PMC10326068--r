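#' Empirical survival curve of a filament cohort
#'
#' Step function `S(t) = 1 - (#events <= t) / n0` over a cohort of
#' filaments. Censored rows count in `n0` but never decrement the curve,
#' so `S` never falls below `n_censored / n0`.
#'
#' @param events An `event_table` (see [simulate_cohort()]) or data frame
#'   with columns `t_event` and `censored`.
#' @param grid Optional evaluation times; default is the sorted unique
#'   event times.
#' @return A `survival_curve`: list with `times` (starting at 0),
#'   `surviving_fraction`, `n0`, `n_censored`.
#' @export
survival_curve <- function(events, grid = NULL) {
  if (nrow(events) == 0L) stop("empty event table")
  if (any(events$t_event < 0, na.rm = TRUE)) stop("negative event times")
  n0 <- nrow(events)
  te <- sort(events$t_event[!events$censored])
  times <- if (is.null(grid)) unique(te) else sort(unique(c(0, grid)))
  if (any(times < 0)) stop("negative grid times")
  if (!length(times) || times[1L] > 0) times <- c(0, times)
  surv <- 1 - findInterval(times, te) / n0
  structure(list(times = times, surviving_fraction = surv, n0 = n0,
                 n_censored = sum(events$censored)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "Survival curve: n0 = %d (%d censored), %d time point(s), final S = %.3f\n",
    x$n0, x$n_censored, length(x$times), min(x$surviving_fraction)))
  invisible(x)
}

# Least-squares single-exponential rate on (times, surviving fraction)
# points; amplitude fixed at 1. Returns list(rate, rss, degenerate).
.fit_rate_ls <- function(times, surv) {
  keep <- times > 0
  t <- times[keep]; s <- surv[keep]
  if (!length(t) || all(s >= 1)) {
    return(list(rate = 0, rss = sum((surv - 1)^2), degenerate = TRUE))
  }
  obj <- function(k) sum((s - exp(-k * t))^2)
  # regression-through-origin of log S on t gives the starting rate; the
  # objective flattens for large k, so bracket the optimum by a log-spaced
  # grid scan before local refinement
  ls <- log(pmax(s, 1e-12))
  k0 <- -sum(t * ls) / sum(t * t)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / mean(t)
  grid <- k0 * 10^seq(-2, 2, length.out = 41)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- if (i == 1L) 0 else grid[i - 1L]
  hi <- if (i == length(grid)) grid[i] * 10 else grid[i + 1L]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
  list(rate = opt$minimum, rss = opt$objective, degenerate = FALSE)
}

# Maximum-likelihood exponential rate reconstructed from the step curve:
# events/total exposure, censored filaments exposed to the last time point.
.fit_rate_mle <- function(curve) {
  dS <- -diff(curve$surviving_fraction)
  m <- round(curve$n0 * dS)
  te <- curve$times[-1L]
  n_events <- sum(m)
  if (n_events == 0) return(list(rate = 0, rss = NA_real_, degenerate = TRUE))
  exposure <- sum(m * te) +
    (curve$n0 - n_events) * max(curve$times)
  list(rate = n_events / exposure, rss = NA_real_, degenerate = FALSE)
}

#' Fit a single-exponential decay to a survival curve
#'
#' The default (`method = "ls"`) minimizes the unweighted sum of squares
#' between the empirical surviving fraction and `exp(-k t)` over the
#' observation window, with amplitude fixed at 1 — fitting the dissociated
#' fraction to `1 - exp(-k t)` gives the identical rate, so only the
#' survival form is implemented. `method = "mle"` is the censored
#' exponential maximum-likelihood cross-check (events / total exposure),
#' reconstructed from the step curve.
#'
#' @param curve A [survival_curve()].
#' @param method `"ls"` (default) or `"mle"`.
#' @return A `rate_fit`: list with `rate` (s^-1), `rss`, `n`, `degenerate`
#'   flag, and `NA` confidence bounds until filled by
#'   [bootstrap_rate_ci()].
#' @export
fit_single_exponential <- function(curve, method = c("ls", "mle")) {
  stopifnot(inherits(curve, "survival_curve"))
  method <- match.arg(method)
  if (length(unique(curve$times)) < 3L)
    stop("need at least 3 distinct time points")
  fit <- if (method == "ls")
    .fit_rate_ls(curve$times, curve$surviving_fraction)
  else .fit_rate_mle(curve)
  rate_fit(rate = fit$rate, n = curve$n0, rss = fit$rss,
           degenerate = fit$degenerate, method = method)
}

rate_fit <- function(rate, n, rss = NA_real_, degenerate = FALSE,
                     method = "ls", ci_level = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     boot_sd = NA_real_) {
  structure(list(rate = rate, n = n, rss = rss, degenerate = degenerate,
                 method = method, ci_level = ci_level, ci_low = ci_low,
                 ci_high = ci_high, boot_sd = boot_sd),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Dissociation rate: %.4g s^-1 (n = %d, %s fit%s)\n",
              x$rate, x$n, x$method,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  if (!is.na(x$ci_low))
    cat(sprintf("  %d%% CI [%.4g, %.4g] s^-1, bootstrap sd %.4g\n",
                round(100 * x$ci_level), x$ci_low, x$ci_high, x$boot_sd))
  invisible(x)
}

#' Two-route decomposition of decision-complex dissociation
#'
#' Splits the fitted total dissociation rate `k_BFC` of the decision
#' complex into its CP-loss and formin-loss components using the observed
#' outcome counts: since `N_BF / N_BC = k'_C / k'_F`,
#' `k'_C = k_BFC * N_BF / (N_BF + N_BC)` and
#' `k'_F = k_BFC * N_BC / (N_BF + N_BC)`. Censored rows contribute to the
#' survival fit only, never to the route split.
#'
#' @param events An `event_table` with outcomes `to_BF` / `to_BC`.
#' @param method Fit method passed to [fit_single_exponential()].
#' @return A `route_decomposition`: list with `k_bfc`, `kprime_minus_C`,
#'   `kprime_minus_F` (s^-1), counts `n_bf`, `n_bc`, and the underlying
#'   `fit`.
#' @export
decompose_routes <- function(events, method = c("ls", "mle")) {
  obs <- events[!events$censored, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no non-censored events to decompose")
  fit <- fit_single_exponential(survival_curve(events), method = method)
  n_bf <- sum(obs$outcome == "to_BF")
  n_bc <- sum(obs$outcome == "to_BC")
  frac_bf <- n_bf / (n_bf + n_bc)
  structure(list(k_bfc = fit$rate,
                 kprime_minus_C = fit$rate * frac_bf,
                 kprime_minus_F = fit$rate * (1 - frac_bf),
                 n_bf = n_bf, n_bc = n_bc, fit = fit),
            class = "route_decomposition")
}

#' @export
print.route_decomposition <- function(x, ...) {
  cat(sprintf("BFC dissociation: k_BFC = %.4g s^-1\n", x$k_bfc))
  cat(sprintf("  to BF (CP left):     k'_C = %.4g s^-1  (N_BF = %d, %.1f%%)\n",
              x$kprime_minus_C, x$n_bf, 100 * x$n_bf / (x$n_bf + x$n_bc)))
  cat(sprintf("  to BC (formin left): k'_F = %.4g s^-1  (N_BC = %d, %.1f%%)\n",
              x$kprime_minus_F, x$n_bc, 100 * x$n_bc / (x$n_bf + x$n_bc)))
  invisible(x)
}

#' Fold change between two rates
#'
#' @param rate_a,rate_b Rates (s^-1); `rate_b` must be positive.
#' @return `rate_a / rate_b`.
#' @export
fold_change <- function(rate_a, rate_b) {
  if (any(rate_b <= 0)) stop("'rate_b' must be positive")
  rate_a / rate_b
}
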
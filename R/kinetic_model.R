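#' Surviving fraction of decision complexes
#'
#' Closed-form survival of the two-route first-order model: a barbed end
#' bound by both formin and CP (state `BFC`) exits with total rate
#' `kprime_minus_C + kprime_minus_F`, so the fraction of an initial cohort
#' still in `BFC` at time `t` is `exp(-(k'_C + k'_F) * t)`.
#'
#' @param t Time(s) since the start of observation (s); vectorized.
#' @param kprime_minus_C CP dissociation rate from `BFC` (s^-1).
#' @param kprime_minus_F Formin dissociation rate from `BFC` (s^-1).
#' @return Surviving fraction(s) in `[0, 1]`.
#' @examples
#' bfc_survival(149, kprime_minus_C = 1 / 298, kprime_minus_F = 1 / 298)
#' @export
bfc_survival <- function(t, kprime_minus_C, kprime_minus_F) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(kprime_minus_C < 0) || any(kprime_minus_F < 0))
    stop("rates must be non-negative")
  exp(-(kprime_minus_C + kprime_minus_F) * t)
}

#' Occupancy fractions of the two-route decision-complex model
#'
#' Fractions of an initial `BFC` cohort found in `BFC`, `BF` and `BC` at
#' time `t`. The complex decays with total rate `k = k'_C + k'_F`; the
#' mass leaving it splits between `BF` (weight `k'_C / k`) and `BC`
#' (weight `k'_F / k`):
#' `BFC(t) = e^(-kt)`, `BF(t) = (k'_C/k)(1 - e^(-kt))`,
#' `BC(t) = (k'_F/k)(1 - e^(-kt))`.
#' The three fractions sum to 1 for every `t`.
#'
#' @inheritParams bfc_survival
#' @return A data frame with columns `t`, `frac_BFC`, `frac_BF`, `frac_BC`
#'   (one row per element of `t`). If both rates are zero and `t > 0`, all
#'   mass stays in `BFC` and a warning is issued.
#' @examples
#' occupancy_fractions(log(2) / 0.03, 0.02, 0.01)  # (0.5, 1/3, 1/6)
#' @export
occupancy_fractions <- function(t, kprime_minus_C, kprime_minus_F) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(kprime_minus_C < 0) || any(kprime_minus_F < 0))
    stop("rates must be non-negative")
  k <- kprime_minus_C + kprime_minus_F
  s <- exp(-k * t)
  w_bf <- ifelse(k > 0, kprime_minus_C / k, 0)
  w_bc <- ifelse(k > 0, kprime_minus_F / k, 0)
  if (any(k == 0 & t > 0))
    warning("both dissociation rates are zero; all mass remains in BFC")
  data.frame(
    t = t,
    frac_BFC = s,
    frac_BF = w_bf * (1 - s),
    frac_BC = w_bc * (1 - s)
  )
}

#' Asymptotic fraction of complexes resolving to the formin-bound state
#'
#' The probability that a decision complex resolves by CP departure
#' (`BFC -> BF + C`) rather than formin departure, `k'_C / (k'_C + k'_F)`.
#' Equivalently the expected fraction `N_BF / (N_BF + N_BC)` of observed
#' outcomes.
#'
#' @inheritParams bfc_survival
#' @return Fraction in `(0, 1]`; the complement is the `BC` route fraction.
#' @export
route_fraction_bf <- function(kprime_minus_C, kprime_minus_F) {
  if (any(kprime_minus_C < 0) || any(kprime_minus_F < 0))
    stop("rates must be non-negative")
  k <- kprime_minus_C + kprime_minus_F
  if (any(k == 0))
    stop("route fraction undefined when both rates are zero")
  kprime_minus_C / k
}

#' Full propensity table of the barbed-end state model
#'
#' Expands a [rate_set()] into the per-edge first-order propensities of the
#' continuous-time Markov chain over [BARBED_STATES]. Bimolecular steps are
#' pre-multiplied by the ligand concentration (pseudo-first-order), since
#' concentrations are held constant within an experimental phase. Twinfilin
#' departure from `BCT`/`BFCT` branches by the per-visit uncapping
#' probability: from `BFCT`, an uncapping departure removes CP and
#' twinfilin together in a single event, leaving `BF`.
#'
#' @param rates A [rate_set()].
#' @return A data frame with columns `from`, `to`, `propensity` (s^-1) and
#'   `tag` (a label for the molecular event). States with no
#'   positive-propensity outgoing edge are absorbing.
#' @export
build_transition_table <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  r <- rates
  tab <- data.frame(
    from = c("B", "BF", "BF", "BFC", "BFC", "BFC",
             "BFCT", "BFCT", "BFCT",
             "BC", "BC", "BCT", "BCT"),
    to = c("BC", "BFC", "DETACHED", "BF", "DETACHED", "BFCT",
           "BFC", "BF", "BCT",
           "BCT", "B", "BC", "UNCAPPED_DEPOL"),
    propensity = c(
      r$k_on_C * r$conc_C,                     # B  -> BC   CP binds
      r$k_on_C * r$conc_C,                     # BF -> BFC  CP binds
      r$k_minus_F,                             # BF -> B+F, filament lost
      r$kprime_minus_C,                        # BFC -> BF + C
      r$kprime_minus_F,                        # BFC -> BC + F, filament lost
      r$k_on_T * r$conc_T,                     # BFC -> BFCT
      r$k_minus_T_BFCT * (1 - r$p_uncap_BFCT), # BFCT -> BFC
      r$k_minus_T_BFCT * r$p_uncap_BFCT,       # BFCT -> BF (T and C together)
      r$k_minus_F_BFCT,                        # BFCT -> BCT (never observed)
      r$k_on_T * r$conc_T,                     # BC -> BCT
      r$k_minus_C,                             # BC -> B (spontaneous uncap)
      r$k_minus_T * (1 - r$p_uncap_BCT),       # BCT -> BC
      r$k_minus_T * r$p_uncap_BCT              # BCT -> UNCAPPED_DEPOL
    ),
    tag = c("cp_binds", "cp_binds", "formin_leaves_filament_lost",
            "cp_leaves", "formin_leaves_filament_lost", "twinfilin_binds",
            "twinfilin_leaves", "twinfilin_uncaps_with_cp", "formin_leaves",
            "twinfilin_binds", "spontaneous_uncap",
            "twinfilin_leaves", "twinfilin_uncaps"),
    stringsAsFactors = FALSE
  )
  tab
}
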
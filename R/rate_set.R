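#' Barbed-end state labels
#'
#' The eight states of the barbed-end occupancy model. `B` is a free barbed
#' end, `F` a processively attached formin, `C` capping protein (CP) and `T`
#' twinfilin, so e.g. `BFC` is the formin-CP "decision complex" and `BFCT`
#' the transient trimeric complex with twinfilin. `DETACHED` (filament lost
#' from the field of view after formin release) and `UNCAPPED_DEPOL`
#' (barbed end uncapped by twinfilin and depolymerizing) are absorbing for
#' the observation model.
#'
#' @format Character vector of length 8.
#' @export
BARBED_STATES <- c("B", "BF", "BC", "BCT", "BFC", "BFCT",
                   "DETACHED", "UNCAPPED_DEPOL")

#' States that are absorbing for the observation model
#' @rdname BARBED_STATES
#' @export
ABSORBING_STATES <- c("DETACHED", "UNCAPPED_DEPOL")

# which protein is present in which state
.protein_states <- list(
  actin     = c("B", "BF", "BC", "BCT", "BFC", "BFCT", "UNCAPPED_DEPOL"),
  formin    = c("BF", "BFC", "BFCT"),
  CP        = c("BC", "BCT", "BFC", "BFCT"),
  twinfilin = c("BCT", "BFCT")
)

.rate_set_fields <- c(
  "k_minus_F", "k_minus_C", "kprime_minus_F", "kprime_minus_C",
  "k_on_C", "k_on_T", "k_minus_T", "k_minus_T_BFCT",
  "p_uncap_BCT", "p_uncap_BFCT", "conc_C", "conc_T",
  "k_minus_F_BFCT", "velocities"
)

#' Kinetic parameter set for the barbed-end state model
#'
#' Collects all first-order exit rates, bimolecular on-rates, per-visit
#' uncapping probabilities, ligand concentrations and per-state elongation
#' velocities used by the transition table and the simulator.
#'
#' @param k_minus_F Formin dissociation from a formin-only end,
#'   `BF -> B + F` (s^-1).
#' @param k_minus_C Spontaneous uncapping, `BC -> B + C` (s^-1).
#' @param kprime_minus_F Formin dissociation from the decision complex,
#'   `BFC -> BC + F` (s^-1). Observationally the filament is lost with
#'   formin, so the simulator records this route as `to_BC`.
#' @param kprime_minus_C CP dissociation from the decision complex,
#'   `BFC -> BF + C` (s^-1).
#' @param k_on_C CP association rate constant (uM^-1 s^-1), applied to
#'   `B -> BC` and `BF -> BFC`.
#' @param k_on_T Twinfilin association rate constant (uM^-1 s^-1), applied
#'   to `BC -> BCT` and `BFC -> BFCT`.
#' @param k_minus_T Twinfilin departure rate from `BCT` (s^-1).
#' @param k_minus_T_BFCT Twinfilin departure rate from `BFCT` (s^-1).
#' @param p_uncap_BCT Probability that a twinfilin departure from `BCT`
#'   carries CP away (uncapping; dimensionless, in `[0, 1]`).
#' @param p_uncap_BFCT Probability that a twinfilin departure from `BFCT`
#'   carries CP away, leaving `BF` (dimensionless, in `[0, 1]`).
#' @param conc_C CP concentration (uM).
#' @param conc_T Twinfilin concentration (uM).
#' @param k_minus_F_BFCT Optional formin loss from the trimeric complex,
#'   `BFCT -> BCT` (s^-1). No such event has been observed; default 0.
#' @param velocities Named numeric vector of per-state elongation
#'   velocities (um/s; may be zero or negative). Missing states default
#'   to 0.
#'
#' @return An object of class `rate_set` (a validated named list).
#' @seealso [build_transition_table()], [default_rates()]
#' @export
rate_set <- function(k_minus_F = 0, k_minus_C = 0,
                     kprime_minus_F = 0, kprime_minus_C = 0,
                     k_on_C = 0, k_on_T = 0,
                     k_minus_T = 0, k_minus_T_BFCT = 0,
                     p_uncap_BCT = 0, p_uncap_BFCT = 0,
                     conc_C = 0, conc_T = 0,
                     k_minus_F_BFCT = 0,
                     velocities = NULL) {
  vel <- stats::setNames(numeric(length(BARBED_STATES)), BARBED_STATES)
  if (!is.null(velocities)) {
    if (is.null(names(velocities)) || !all(names(velocities) %in% BARBED_STATES))
      stop("'velocities' must be a named vector with names among BARBED_STATES")
    vel[names(velocities)] <- velocities
  }
  x <- list(
    k_minus_F = k_minus_F, k_minus_C = k_minus_C,
    kprime_minus_F = kprime_minus_F, kprime_minus_C = kprime_minus_C,
    k_on_C = k_on_C, k_on_T = k_on_T,
    k_minus_T = k_minus_T, k_minus_T_BFCT = k_minus_T_BFCT,
    p_uncap_BCT = p_uncap_BCT, p_uncap_BFCT = p_uncap_BFCT,
    conc_C = conc_C, conc_T = conc_T,
    k_minus_F_BFCT = k_minus_F_BFCT,
    velocities = vel
  )
  validate_rate_set(x)
}

validate_rate_set <- function(x) {
  stopifnot(is.list(x))
  rate_fields <- setdiff(.rate_set_fields, c("velocities", "p_uncap_BCT", "p_uncap_BFCT"))
  for (f in rate_fields) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("rate_set field '%s' must be a single non-negative number", f))
  }
  for (f in c("p_uncap_BCT", "p_uncap_BFCT")) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("rate_set field '%s' must be a probability in [0, 1]", f))
  }
  if (!all(names(x$velocities) == BARBED_STATES) || any(!is.finite(x$velocities)))
    stop("rate_set field 'velocities' must be finite, one value per state")
  structure(x, class = "rate_set")
}

#' Default parameter set for the control decision-complex experiment
#'
#' Control (no twinfilin) two-route rates are anchored to the observed mean
#' BFC lifetime of 149 s and the 30:42 split of resolutions to `BF` vs `BC`:
#' the total exit rate is 1/149 s^-1, partitioned in the 30/72 : 42/72
#' ratio. Twinfilin dwell parameters use the observed mean residence times
#' (1.9 s on `BCT`, 1.4 s on `BFCT`) and per-visit uncapping probabilities
#' 1/30.9 (from `BCT`) and 1 (from `BFCT`; CP and twinfilin leave
#' together). Association rate constants and velocities are plausible
#' demonstration values, not measured quantities.
#'
#' @param conc_C CP concentration (uM), default 0.
#' @param conc_T Twinfilin concentration (uM), default 0.
#' @return A [rate_set()].
#' @export
default_rates <- function(conc_C = 0, conc_T = 0) {
  k_bfc <- 1 / 149
  rate_set(
    k_minus_F       = 4.5e-4,
    k_minus_C       = 4e-4,
    kprime_minus_C  = k_bfc * 30 / 72,
    kprime_minus_F  = k_bfc * 42 / 72,
    k_on_C          = 10,
    k_on_T          = 1,
    k_minus_T       = 1 / 1.9,
    k_minus_T_BFCT  = 1 / 1.4,
    p_uncap_BCT     = 1 / 30.9,
    p_uncap_BFCT    = 1,
    conc_C          = conc_C,
    conc_T          = conc_T,
    velocities      = c(B = 0.01, BF = 0.05, UNCAPPED_DEPOL = -0.05)
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Barbed-end kinetic parameter set\n")
  flat <- unlist(x[setdiff(.rate_set_fields, "velocities")])
  print(flat)
  cat("velocities (um/s):\n")
  print(x$velocities)
  invisible(x)
}

#' Read / write a rate set as JSON
#'
#' The serialized form is a flat JSON object with exactly the `rate_set`
#' field names (velocities as a nested named object). Unknown keys are
#' rejected.
#'
#' @param path File path.
#' @return `read_rate_set()` returns a [rate_set()]; `write_rate_set()`
#'   returns `path` invisibly.
#' @export
read_rate_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rate_set_from_list(x)
}

#' @rdname read_rate_set
#' @param rates A [rate_set()].
#' @export
write_rate_set <- function(rates, path) {
  stopifnot(inherits(rates, "rate_set"))
  out <- unclass(rates)
  out$velocities <- as.list(out$velocities)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

rate_set_from_list <- function(x) {
  unknown <- setdiff(names(x), .rate_set_fields)
  if (length(unknown))
    stop("unknown rate_set field(s): ", paste(unknown, collapse = ", "))
  vel <- x$velocities
  if (!is.null(vel)) vel <- unlist(vel)
  x$velocities <- NULL
  do.call(rate_set, c(x, list(velocities = vel)))
}
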
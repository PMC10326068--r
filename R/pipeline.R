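.config_defaults <- function() {
  list(
    rates = unclass(default_rates()),
    cohort = list(n_filaments = 100L, window = 1500, initial_state = "BFC"),
    observation = list(frame_interval = 0.2, noise_sd = 0, bleach_rate = 0),
    analysis = list(bootstrap_reps = 1000L, ci_level = 0.65,
                    threshold = "auto"),
    seed = NULL,
    output_dir = NULL
  )
}

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON run configuration, applies documented defaults for missing
#' sections, rejects unknown keys (naming the offending key) and validates
#' every field against the owning module's constraints. A `seed` is
#' required whenever any stochastic stage runs (`n_filaments > 0`).
#'
#' @param path Path to a JSON config file.
#' @return A validated `run_config` list with elements `rates`
#'   (a [rate_set()]), `cohort`, `observation`, `analysis`, `seed`,
#'   `output_dir`.
#' @seealso [run_pipeline()], [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(raw)
}

#' @rdname load_config
#' @param config A config-like list (e.g. parsed JSON).
#' @export
as_run_config <- function(config) {
  def <- .config_defaults()
  .check_keys(config, names(def), "config")
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  .check_keys(cfg$cohort, names(def$cohort), "config$cohort")
  .check_keys(cfg$observation, names(def$observation), "config$observation")
  .check_keys(cfg$analysis, names(def$analysis), "config$analysis")
  cfg$rates <- if (inherits(cfg$rates, "rate_set")) cfg$rates else
    rate_set_from_list(cfg$rates)
  with(cfg$cohort, stopifnot(n_filaments >= 0, window > 0,
                             initial_state %in% BARBED_STATES))
  with(cfg$observation, stopifnot(frame_interval > 0, noise_sd >= 0,
                                  bleach_rate >= 0))
  with(cfg$analysis, stopifnot(bootstrap_reps >= 2,
                               ci_level > 0, ci_level < 1))
  if (cfg$cohort$n_filaments > 0 && is.null(cfg$seed))
    stop("config field 'seed' is required when n_filaments > 0")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  out <- unclass(config)
  out$rates <- unclass(out$rates)
  out$rates$velocities <- as.list(out$rates$velocities)
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-fit-decompose-dwell pipeline
#'
#' Chains the package's stages into one reproducible run, mirroring the
#' phases of a decision-complex chase experiment: simulate a cohort of
#' filaments, write the event table and rendered multichannel traces, fit
#' the survival curve with a bootstrap confidence interval, decompose the
#' dissociation routes, and summarize twinfilin dwell times from the
#' rendered traces. The whole run is a pure function of (config, seed);
#' every JSON output embeds the config hash and package version.
#'
#' @param config A `run_config` (see [load_config()]).
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the fit, decomposition, dwell summary and
#'   the paths of the files written (`events.csv`, `traces.csv`,
#'   `fit.json`, `decomp.json`, `dwell.json`, `run.log`).
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir <- output_dir %||% config$output_dir
  if (is.null(dir)) stop("no output directory given")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(dir, "run.log")
  logf <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    if (!quiet) message(line)
  }
  cat("", file = log_path)
  prov <- list(config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("barbedend")),
               seed = config$seed)
  logf("pipeline start: %d filaments, initial state %s, window %g s",
       config$cohort$n_filaments, config$cohort$initial_state,
       config$cohort$window)

  sim <- simulate_cohort(config$rates, config$cohort$n_filaments,
                         config$cohort$initial_state,
                         config$cohort$window, seed = config$seed)
  write_event_table(sim$events, file.path(dir, "events.csv"))
  if (nrow(sim$events) == 0L)
    warning("pipeline ran with an empty cohort (n_filaments = 0)")
  n_obs <- sum(!sim$events$censored)
  logf("simulate: %d filaments, %d resolved, %d censored",
       nrow(sim$events), n_obs, sum(sim$events$censored))

  obs <- config$observation
  traces <- list()
  for (tr in sim$trajectories) {
    for (ch in c("formin", "CP", "twinfilin", "length")) {
      traces[[paste(tr$filament_id, ch, sep = ".")]] <- render_trace(
        tr, ch, obs$frame_interval, noise_sd = obs$noise_sd,
        bleach_rate = obs$bleach_rate,
        seed = filament_seed(config$seed %||% 0, tr$filament_id + 10000L),
        rates = config$rates)
    }
  }
  if (length(traces))
    write_traces(traces, file.path(dir, "traces.csv"))
  logf("render: %d traces @ %g s/frame", length(traces), obs$frame_interval)

  fit <- decomp <- NULL
  if (n_obs > 0) {
    curve <- survival_curve(sim$events)
    fit <- fit_single_exponential(curve)
    if (fit$rate > 0)
      fit <- bootstrap_rate_ci(fit$rate, n = curve$n0,
                               reps = config$analysis$bootstrap_reps,
                               level = config$analysis$ci_level,
                               window = config$cohort$window,
                               seed = filament_seed(config$seed, 999983L))
    logf("fit: k = %.4g s^-1 [%.4g, %.4g]", fit$rate,
         fit$ci_low, fit$ci_high)
    jsonlite::write_json(
      c(list(rate_per_s = fit$rate, ci_level = fit$ci_level,
             ci_low = fit$ci_low, ci_high = fit$ci_high,
             boot_sd = fit$boot_sd, n = fit$n,
             n_censored = curve$n_censored), prov),
      file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    if (any(sim$events$outcome %in% c("to_BF", "to_BC"))) {
      decomp <- decompose_routes(sim$events)
      logf("decompose: k_BFC = %.4g, k'_C = %.4g, k'_F = %.4g (N_BF %d, N_BC %d)",
           decomp$k_bfc, decomp$kprime_minus_C, decomp$kprime_minus_F,
           decomp$n_bf, decomp$n_bc)
      jsonlite::write_json(
        c(list(k_bfc = decomp$k_bfc,
               kprime_minus_C = decomp$kprime_minus_C,
               kprime_minus_F = decomp$kprime_minus_F,
               n_bf = decomp$n_bf, n_bc = decomp$n_bc), prov),
        file.path(dir, "decomp.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  dwell <- NULL
  twf <- traces[grepl("\\.twinfilin$", names(traces))]
  iv <- lapply(twf, binarize_trace, threshold = config$analysis$threshold)
  iv <- iv[vapply(iv, function(p) nrow(p$intervals) > 0, logical(1))]
  if (length(iv)) {
    dwell <- dwell_summary(iv)
    logf("dwell: %d twinfilin events, mean %.3g +/- %.2g s",
         dwell$n_events, dwell$mean, dwell$sem)
    jsonlite::write_json(
      c(list(n_events = dwell$n_events, mean_s = dwell$mean,
             sem_s = dwell$sem), prov),
      file.path(dir, "dwell.json"), auto_unbox = TRUE, digits = NA)
  } else {
    logf("dwell: no twinfilin events")
  }
  logf("pipeline done")
  invisible(list(fit = fit, decomposition = decomp, dwell = dwell,
                 events = sim$events, output_dir = dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
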
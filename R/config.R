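config_keys <- list(
  top = c("model", "scenarios", "wtp_grid", "psa", "output_dir", "seed",
          "log_level"),
  model = c("fixture", "knobs", "matrix", "costs", "utilities", "cost_unit",
            "discount_rate", "horizon", "half_cycle"),
  psa = c("n_iterations", "seed", "cost_cv", "ess"),
  scenario = c("name", "pd_share"),
  knobs = c("hd_mortality", "pd_mortality", "dialysis_to_tx",
            "tx_first_year_mortality", "tx_later_mortality", "rejection",
            "pd_to_tx")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    rlang::abort(sprintf("Unknown key '%s' in %s (allowed: %s).",
                         extra[1], where, paste(allowed, collapse = ", ")))
  }
}

config_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) {
    message(...)
  }
}

parse_model <- function(m, quiet = FALSE) {
  check_keys(m, config_keys$model, "model")
  if (!is.null(m$fixture)) {
    if (!identical(m$fixture, "esrd_iran")) {
      rlang::abort(sprintf("Unknown fixture '%s'; available: esrd_iran.",
                           m$fixture))
    }
    knobs <- if (is.null(m$knobs)) NULL else {
      check_keys(m$knobs, config_keys$knobs, "model$knobs")
      do.call(transition_knobs, m$knobs)
    }
    fix <- esrd_fixture(knobs = knobs,
                        half_cycle = isTRUE(m$half_cycle))
    return(fix$model)
  }
  for (req in c("costs", "utilities")) {
    if (is.null(m[[req]])) {
      rlang::abort(sprintf("model$%s is required for an inline model.", req))
    }
  }
  states <- rrt_states()
  live <- setdiff(states, "DEAD")
  check_keys(m$costs, states, "model$costs")
  check_keys(m$utilities, states, "model$utilities")
  costs <- stats::setNames(numeric(5), states)
  costs[live] <- vapply(live, function(s) {
    v <- m$costs[[s]]
    if (is.null(v)) rlang::abort(sprintf("model$costs$%s is missing.", s))
    v
  }, numeric(1))
  unit <- m$cost_unit
  if (is.null(unit) && any(costs > 1e5)) {
    unit <- "irr"
    if (!quiet) message("Costs exceed 100,000; interpreting as raw IRR.")
  }
  if (identical(unit, "irr")) {
    costs <- costs / 1e6
    if (!quiet) message("Converted costs from IRR to million IRR.")
  } else if (!is.null(unit) && !identical(unit, "million_irr")) {
    rlang::abort("model$cost_unit must be 'irr' or 'million_irr'.")
  }
  utilities <- stats::setNames(numeric(5), states)
  utilities[live] <- vapply(live, function(s) {
    v <- m$utilities[[s]]
    if (is.null(v)) rlang::abort(sprintf("model$utilities$%s is missing.", s))
    v
  }, numeric(1))
  transitions <- if (!is.null(m$knobs)) {
    check_keys(m$knobs, config_keys$knobs, "model$knobs")
    build_transition_matrix(do.call(transition_knobs, m$knobs))
  } else if (!is.null(m$matrix)) {
    P <- do.call(rbind, lapply(m$matrix, as.numeric))
    dimnames(P) <- list(states, states)
    P
  } else {
    rlang::abort("model needs either `knobs` or `matrix` transitions.")
  }
  markov_model(
    transitions, costs, utilities,
    discount_rate = m$discount_rate %||% 0.035,
    horizon = m$horizon %||% 10,
    half_cycle = isTRUE(m$half_cycle)
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration describing the model (inline, or the built-in
#' `esrd_iran` fixture), the scenarios, the willingness-to-pay grid and
#' optional PSA settings. Unknown keys are an error — there is no silent
#' tolerance for typos. Costs supplied in raw IRR (detected, or declared via
#' `cost_unit: irr`) are converted to million IRR with a logged note.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list: `model` ([markov_model()]), `scenarios`
#'   (tibble), `wtp_grid`, `psa` (settings list or `NULL`), `output_dir`,
#'   `seed`, `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file '%s' does not exist.", path))
  }
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' The programmatic counterpart of [load_config()]; validates the same
#' schema.
#'
#' @param raw Nested list in the config schema.
#' @return A `run_config`.
#' @export
as_run_config <- function(raw) {
  check_keys(raw, config_keys$top, "config")
  if (is.null(raw$model)) rlang::abort("Config must contain `model`.")
  log_level <- raw$log_level %||% "info"
  quiet <- identical(log_level, "quiet")
  model <- parse_model(raw$model, quiet = quiet)
  scenarios <- if (is.null(raw$scenarios)) {
    esrd_fixture()$scenarios
  } else {
    for (s in raw$scenarios) check_keys(s, config_keys$scenario, "scenarios[]")
    scenario_set(
      vapply(raw$scenarios, function(s) s$pd_share, numeric(1)),
      vapply(raw$scenarios, function(s) s$name %||% NA_character_,
             character(1))
    )
  }
  wtp_grid <- raw$wtp_grid %||% seq(0, 6000, by = 200)
  if (is.unsorted(wtp_grid) || any(wtp_grid < 0)) {
    rlang::abort("`wtp_grid` must be ascending and non-negative.")
  }
  psa <- raw$psa
  if (!is.null(psa)) check_keys(psa, config_keys$psa, "psa")
  structure(
    list(
      model = model,
      scenarios = scenarios,
      wtp_grid = as.numeric(wtp_grid),
      psa = psa,
      output_dir = raw$output_dir %||% ".",
      seed = as.integer(raw$seed %||% 1L),
      log_level = log_level,
      raw = raw
    ),
    class = "run_config"
  )
}

#' Serialize a run configuration to YAML
#'
#' Writes a YAML file that [load_config()] reads back to an equivalent
#' configuration (model payoffs, transitions, scenarios, grids and settings
#' all round-trip).
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  m <- config$model
  out <- list(
    model = list(
      matrix = lapply(seq_len(nrow(m$transitions)),
                      function(i) as.numeric(m$transitions[i, ])),
      costs = as.list(m$costs[setdiff(rrt_states(), "DEAD")]),
      utilities = as.list(m$utilities[setdiff(rrt_states(), "DEAD")]),
      cost_unit = "million_irr",
      discount_rate = m$discount_rate,
      horizon = m$horizon,
      half_cycle = m$half_cycle
    ),
    scenarios = lapply(seq_len(nrow(config$scenarios)), function(i) {
      list(name = config$scenarios$name[i],
           pd_share = config$scenarios$pd_share[i])
    }),
    wtp_grid = config$wtp_grid,
    psa = config$psa,
    output_dir = config$output_dir,
    seed = config$seed,
    log_level = config$log_level
  )
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

config_hash <- function(config) {
  rlang::hash(list(config$model[c("transitions", "costs", "utilities",
                                  "discount_rate", "horizon", "half_cycle")],
                   config$scenarios, config$wtp_grid, config$psa,
                   config$seed))
}

write_manifest <- function(config, files, dir) {
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("renalcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

ensure_output_dir <- function(config) {
  dir <- config$output_dir
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("Cannot create output_dir '%s'.", dir))
  }
  dir
}

#' Run the deterministic cost-utility analysis from a configuration
#'
#' Runs every scenario, writes one cohort-trace CSV per scenario, the CEA
#' table CSV, and a `manifest.json` recording the config hash, seed, package
#' version and timestamp. A console summary with conventional display
#' rounding (costs to 1 decimal, QALYs to 4, ICERs to 1) is printed unless
#' `log_level` is `"quiet"`; files always hold full precision.
#'
#' @param config A `run_config` (see [load_config()]).
#' @return Invisibly, the list of written file paths.
#' @export
run_deterministic <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- ensure_output_dir(config)
  files <- character(0)
  for (i in seq_len(nrow(config$scenarios))) {
    nm <- config$scenarios$name[i]
    trace <- run_cohort(config$model,
                        initial_distribution(config$scenarios$pd_share[i]))
    f <- file.path(dir, paste0("trace_", nm, ".csv"))
    write_trace_csv(trace, f)
    files <- c(files, f)
  }
  results <- run_scenarios(config$model, config$scenarios)
  tab <- cea_table(results)
  f <- file.path(dir, "cea_table.csv")
  write_cea_csv(tab, f)
  files <- c(files, f)
  files <- c(files, write_manifest(config, basename(files), dir))
  if (!identical(config$log_level, "quiet")) print(tab)
  invisible(files)
}

#' Run the probabilistic sensitivity analysis from a configuration
#'
#' Builds the default PSA specification from the config's `psa` settings
#' (`n_iterations`, `seed`, `cost_cv`, `ess`), runs the Monte Carlo
#' propagation, and writes the per-iteration summaries, the CEAC over the
#' config's WTP grid, the incremental cost-effectiveness plane points versus
#' the first scenario, and a manifest.
#'
#' @param config A `run_config` with a `psa` section (an empty section uses
#'   the defaults).
#' @return Invisibly, the list of written file paths.
#' @export
run_psa_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- ensure_output_dir(config)
  p <- config$psa %||% list()
  spec <- default_psa_spec(
    config$model,
    cost_cv = p$cost_cv %||% 0.2,
    ess = p$ess %||% 100,
    n_iterations = p$n_iterations %||% 1000,
    seed = p$seed %||% config$seed
  )
  config_log(config, "PSA: ", spec$n_iterations, " iterations, seed ",
             spec$seed)
  result <- run_psa(config$model, config$scenarios, spec)
  files <- c(
    write_psa_csv(result, file.path(dir, "psa_iterations.csv")),
    write_ceac_csv(ceac(result, config$wtp_grid),
                   file.path(dir, "ceac.csv"))
  )
  plane <- ce_plane(result)
  f <- file.path(dir, "ce_plane.csv")
  utils::write.csv(as.data.frame(plane), f, row.names = FALSE)
  files <- c(files, f)
  files <- c(files, write_manifest(config, basename(files), dir))
  invisible(files)
}

#' Calibrate transition knobs from a configuration
#'
#' Fits the transition knobs to per-scenario cost/QALY targets using the
#' config's model payoffs, then writes the knob report (YAML) and a
#' reproducibility log recording the start point, evaluation budget and
#' achieved error.
#'
#' @param config A `run_config`.
#' @param targets Target tibble (see [esrd_targets()], the default).
#' @param start Starting knobs; defaults to mid-range plausible values.
#' @param share_tx Passed to [calibrate_knobs()].
#' @return Invisibly, the `calibration_fit`.
#' @export
run_calibration <- function(config, targets = esrd_targets(),
                            start = NULL, share_tx = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir <- ensure_output_dir(config)
  if (is.null(start)) {
    start <- transition_knobs(0.12, 0.12, 0.04, 0.03, 0.02, 0.03)
  }
  fit <- calibrate_knobs(targets, config$model, start = start,
                         share_tx = share_tx)
  report <- list(
    source = "synthetic-calibrated",
    knobs = lapply(unclass(fit$knobs), as.numeric),
    achieved_sse = fit$value,
    max_rel_error = fit$max_rel_error,
    evaluations = fit$evaluations,
    converged = fit$converged,
    start = lapply(unclass(start), as.numeric),
    config_hash = config_hash(config)
  )
  yaml::write_yaml(report, file.path(dir, "calibration_report.yaml"))
  write_manifest(config, "calibration_report.yaml", dir)
  config_log(config, "Calibration max relative error: ",
             sprintf("%.3g%%", 100 * fit$max_rel_error))
  invisible(fit)
}
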
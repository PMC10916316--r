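#' Moment-matched gamma distribution for cost parameters
#'
#' Matches a gamma distribution to a mean and standard deviation:
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`. The round-trip mean and SD are
#' reproduced exactly.
#'
#' @param mean,sd Positive mean and standard deviation (million IRR).
#' @return A `dist_spec` with `family = "gamma"`, parameters `shape` and
#'   `scale`, and the source moments.
#' @export
#' @examples
#' gamma_from_moments(848.855549, 0.2 * 848.855549)
gamma_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) rlang::abort("`mean` and `sd` must be positive.")
  structure(
    list(family = "gamma",
         parameters = list(shape = (mean / sd)^2, scale = sd^2 / mean),
         source_moments = list(mean = mean, sd = sd)),
    class = "dist_spec"
  )
}

#' Moment-matched beta distribution for probabilities and utilities
#'
#' Matches a beta distribution to a mean and standard deviation:
#' `alpha = mean * k`, `beta = (1 - mean) * k` with
#' `k = mean * (1 - mean) / sd^2 - 1`. A beta cannot have
#' `sd^2 >= mean * (1 - mean)`; when a patient-level SD is infeasible at the
#' given mean and a sample size `n` is supplied, the standard error of the
#' mean `sd / sqrt(n)` is used instead and the fallback is recorded in the
#' returned source moments. The beta family lives on \[0, 1\], so states
#' valued worse than death are truncated at zero by construction.
#'
#' @param mean Mean in (0, 1).
#' @param sd Positive standard deviation.
#' @param n Optional sample size enabling the standard-error fallback.
#' @return A `dist_spec` with `family = "beta"` and parameters `alpha`,
#'   `beta`.
#' @export
#' @examples
#' beta_from_moments(0.5, 0.288675)           # ~uniform
#' beta_from_moments(0.423, 0.549, n = 312)   # SE fallback
beta_from_moments <- function(mean, sd, n = NULL) {
  if (mean <= 0 || mean >= 1) rlang::abort("`mean` must be in (0, 1).")
  if (sd <= 0) rlang::abort("`sd` must be positive.")
  v <- sd^2
  fallback <- NULL
  if (v >= mean * (1 - mean)) {
    if (is.null(n)) {
      rlang::abort(sprintf(
        "sd^2 = %.4g is infeasible for a beta with mean %.4g and no sample size was supplied.",
        v, mean
      ))
    }
    sd <- sd / sqrt(n)
    v <- sd^2
    if (v >= mean * (1 - mean)) {
      rlang::abort("Even the standard error of the mean is infeasible for a beta.")
    }
    fallback <- "se_of_mean"
  }
  k <- mean * (1 - mean) / v - 1
  structure(
    list(family = "beta",
         parameters = list(alpha = mean * k, beta = (1 - mean) * k),
         source_moments = list(mean = mean, sd = sd, n = n,
                               fallback = fallback)),
    class = "dist_spec"
  )
}

#' Degenerate (fixed-value) distribution
#'
#' @param value The fixed value.
#' @return A `dist_spec` with `family = "fixed"`.
#' @export
dist_fixed <- function(value) {
  structure(
    list(family = "fixed", parameters = list(value = value),
         source_moments = list(mean = value, sd = 0)),
    class = "dist_spec"
  )
}

#' Dirichlet distributions over transition-matrix rows
#'
#' Gives each non-absorbing row of a transition matrix a Dirichlet
#' distribution with concentrations `ess * p_ij` over its non-zero entries,
#' so sampled rows are row-stochastic by construction and structural zeros
#' (including the TX1 tunnel self-transition) stay exactly zero. The
#' absorbing `DEAD` row is fixed and never sampled. Sampled row means equal
#' the input probabilities.
#'
#' @param transitions A validated transition matrix.
#' @param ess Effective sample size (total concentration per row); larger
#'   values mean less uncertainty. Must be positive.
#' @return A named list of `dist_spec`s, one per row: `family = "dirichlet"`
#'   with concentrations `alpha` (zeros marking structural zeros), or
#'   `family = "fixed"` for rows with no uncertainty.
#' @export
dirichlet_rows <- function(transitions, ess = 100) {
  if (ess <= 0) rlang::abort("`ess` must be positive.")
  transitions <- validate_transitions(transitions)
  states <- rrt_states()
  out <- lapply(states, function(s) {
    p <- transitions[s, ]
    if (s == "DEAD" || sum(p > 0) <= 1) {
      structure(list(family = "fixed", parameters = list(value = p),
                     source_moments = list(mean = p, sd = 0 * p)),
                class = "dist_spec")
    } else {
      structure(list(family = "dirichlet",
                     parameters = list(alpha = ess * p),
                     source_moments = list(mean = p, ess = ess)),
                class = "dist_spec")
    }
  })
  stats::setNames(out, states)
}

rdirichlet_row <- function(alpha) {
  x <- numeric(length(alpha))
  nz <- alpha > 0
  g <- stats::rgamma(sum(nz), shape = alpha[nz], rate = 1)
  # a zero gamma draw (possible at tiny shapes) would break normalization
  while (sum(g) == 0) g <- stats::rgamma(sum(nz), shape = alpha[nz], rate = 1)
  x[nz] <- g / sum(g)
  names(x) <- names(alpha)
  x
}

draw_dist <- function(spec) {
  p <- spec$parameters
  switch(spec$family,
    fixed = p$value,
    gamma = stats::rgamma(1, shape = p$shape, scale = p$scale),
    beta = stats::rbeta(1, p$alpha, p$beta),
    dirichlet = rdirichlet_row(p$alpha),
    rlang::abort(sprintf("Unknown distribution family '%s'.", spec$family))
  )
}

#' Probabilistic sensitivity analysis specification
#'
#' Bundles one distribution per uncertain parameter: per-state cost and
#' utility distributions and per-row transition distributions, plus the
#' Monte Carlo settings.
#'
#' @param cost_dists,utility_dists Named lists of `dist_spec`s over the model
#'   states.
#' @param transition_dists Named list of per-row `dist_spec`s (see
#'   [dirichlet_rows()]).
#' @param n_iterations Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return A `psa_spec` object.
#' @export
psa_spec <- function(cost_dists, utility_dists, transition_dists,
                     n_iterations = 1000, seed = 1L) {
  states <- rrt_states()
  for (nm in c("cost_dists", "utility_dists", "transition_dists")) {
    x <- get(nm)
    if (!all(states %in% names(x))) {
      rlang::abort(sprintf("`%s` must name every state (%s).",
                           nm, paste(states, collapse = ", ")))
    }
    if (!all(vapply(x, inherits, logical(1), "dist_spec"))) {
      rlang::abort(sprintf("`%s` entries must be dist_spec objects.", nm))
    }
  }
  if (n_iterations < 1) rlang::abort("`n_iterations` must be >= 1.")
  structure(
    list(cost_dists = cost_dists[states],
         utility_dists = utility_dists[states],
         transition_dists = transition_dists[states],
         n_iterations = as.integer(n_iterations),
         seed = as.integer(seed)),
    class = "psa_spec"
  )
}

#' Default PSA specification for a model
#'
#' Costs get gamma distributions at a common coefficient of variation
#' (cost SDs are rarely published; the default CV of 0.2 is a conventional
#' choice, not an estimate). Utilities get beta distributions matched to the
#' standard error of the published mean (`sd / sqrt(n)`), because
#' patient-level SDs are infeasible for a beta at the published means.
#' Transition rows get Dirichlet distributions at effective sample size
#' `ess`, preserving row-stochasticity. `DEAD` payoffs stay fixed at zero.
#'
#' @param model A [markov_model()].
#' @param cost_cv Coefficient of variation for per-state costs (default 0.2).
#' @param utility_sd Named per-state patient-level SDs of the utilities.
#' @param utility_n Named per-state sample sizes behind the utility means.
#' @param ess Dirichlet effective sample size for transition rows
#'   (default 100).
#' @param n_iterations,seed Monte Carlo settings.
#' @return A `psa_spec`.
#' @export
#' @examples
#' fix <- esrd_fixture()
#' default_psa_spec(fix$model, seed = 7)
default_psa_spec <- function(model, cost_cv = 0.2,
                             utility_sd = c(PD = 0.468, HD = 0.549,
                                            TX1 = 0.341, TXP = 0.341),
                             utility_n = c(PD = 76, HD = 312,
                                           TX1 = 130, TXP = 130),
                             ess = 100, n_iterations = 1000, seed = 1L) {
  states <- rrt_states()
  cost_dists <- lapply(stats::setNames(states, states), function(s) {
    m <- model$costs[[s]]
    if (m <= 0 || cost_cv <= 0) dist_fixed(m) else
      gamma_from_moments(m, cost_cv * m)
  })
  utility_dists <- lapply(stats::setNames(states, states), function(s) {
    u <- model$utilities[[s]]
    if (s == "DEAD" || u <= 0 || u >= 1) return(dist_fixed(u))
    se <- utility_sd[[s]] / sqrt(utility_n[[s]])
    beta_from_moments(u, se)
  })
  psa_spec(cost_dists, utility_dists,
           dirichlet_rows(model$transitions, ess),
           n_iterations = n_iterations, seed = seed)
}

#' Run a probabilistic sensitivity analysis
#'
#' For each Monte Carlo iteration one joint parameter set is drawn (costs,
#' utilities, transition rows), the model is rebuilt, and every scenario is
#' evaluated on that same draw — common random parameters across scenarios,
#' as required for a meaningful acceptability curve. A draw yielding an
#' invalid transition matrix is rejected and redrawn, and the redraw count is
#' reported. Runs are bit-reproducible for a fixed seed.
#'
#' @param model A [markov_model()].
#' @param scenarios Tibble from [scenario_set()].
#' @param spec A [psa_spec()] (e.g. from [default_psa_spec()]).
#' @return A `psa_result`: list with `draws` (tibble of `iteration`, `name`,
#'   `pd_share`, `cost_million_irr`, `qaly`), `n_redraws`, `n_iterations`,
#'   `seed`, and the scenario table.
#' @export
run_psa <- function(model, scenarios, spec) {
  stopifnot(inherits(model, "markov_model"), inherits(spec, "psa_spec"))
  states <- rrt_states()
  set.seed(spec$seed)
  n_it <- spec$n_iterations
  n_sc <- nrow(scenarios)
  cost_out <- matrix(NA_real_, n_it, n_sc)
  qaly_out <- matrix(NA_real_, n_it, n_sc)
  n_redraws <- 0L
  for (it in seq_len(n_it)) {
    repeat {
      costs <- vapply(spec$cost_dists, draw_dist, numeric(1))
      utils_ <- vapply(spec$utility_dists, draw_dist, numeric(1))
      P <- t(vapply(spec$transition_dists, draw_dist,
                    numeric(length(states))))
      dimnames(P) <- list(states, states)
      m_it <- tryCatch(
        markov_model(P, costs, utils_,
                     discount_rate = model$discount_rate,
                     horizon = model$horizon,
                     half_cycle = model$half_cycle),
        error = function(e) NULL
      )
      if (!is.null(m_it)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100L * n_it) {
        rlang::abort("Too many invalid parameter draws; check the PSA spec.")
      }
    }
    for (j in seq_len(n_sc)) {
      s <- run_scenario(m_it, scenarios$pd_share[j], scenarios$name[j])
      cost_out[it, j] <- s$cost_million_irr
      qaly_out[it, j] <- s$qaly
    }
  }
  draws <- tibble::tibble(
    iteration = rep(seq_len(n_it), each = n_sc),
    name = rep(scenarios$name, n_it),
    pd_share = rep(scenarios$pd_share, n_it),
    cost_million_irr = as.vector(t(cost_out)),
    qaly = as.vector(t(qaly_out))
  )
  structure(
    list(draws = draws, scenarios = scenarios, n_redraws = n_redraws,
         n_iterations = n_it, seed = spec$seed),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_iterations, "iterations x", nrow(x$scenarios),
      "scenarios (seed", x$seed, ",", x$n_redraws, "redraws)\n")
  print(glance(x), ...)
  invisible(x)
}

psa_matrices <- function(result) {
  d <- result$draws
  sc <- result$scenarios$name
  list(
    cost = matrix(d$cost_million_irr, ncol = length(sc), byrow = TRUE,
                  dimnames = list(NULL, sc)),
    qaly = matrix(d$qaly, ncol = length(sc), byrow = TRUE,
                  dimnames = list(NULL, sc))
  )
}

# index of the NMB winner in one iteration; ties go to the cheaper scenario,
# then to input order
winner_idx <- function(nmb_row, cost_row) {
  order(-nmb_row, cost_row, seq_along(nmb_row))[1]
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that each scenario
#' is optimal: the proportion of PSA iterations in which it attains the
#' greatest net monetary benefit. Ties within an iteration are credited to
#' the cheaper scenario (never double counted), so the probabilities across
#' scenarios sum to 1 at every threshold.
#'
#' @param result A [run_psa()] result.
#' @param wtp_grid Ascending non-negative thresholds, million IRR per QALY.
#' @return A `ceac_curve` tibble: `wtp`, `name`, `prob`.
#' @export
ceac <- function(result, wtp_grid) {
  if (length(wtp_grid) == 0) rlang::abort("`wtp_grid` is empty.")
  if (any(wtp_grid < 0)) rlang::abort("`wtp_grid` must be non-negative.")
  m <- psa_matrices(result)
  sc <- result$scenarios$name
  n_it <- nrow(m$cost)
  rows <- lapply(wtp_grid, function(w) {
    nmb_m <- w * m$qaly - m$cost
    win <- vapply(seq_len(n_it),
                  function(i) winner_idx(nmb_m[i, ], m$cost[i, ]),
                  integer(1))
    tibble::tibble(wtp = w, name = sc,
                   prob = tabulate(win, length(sc)) / n_it)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Probability each scenario is optimal at one threshold
#'
#' The single-threshold slice of [ceac()], with binomial Monte Carlo
#' standard errors `sqrt(p (1 - p) / n)` attached.
#'
#' @param result A [run_psa()] result.
#' @param wtp Willingness-to-pay threshold, million IRR per QALY.
#' @return Tibble: `name`, `prob`, `se`.
#' @export
prob_optimal <- function(result, wtp) {
  out <- ceac(result, wtp)
  out <- tibble::as_tibble(out)[, c("name", "prob")]
  out$se <- sqrt(out$prob * (1 - out$prob) / result$n_iterations)
  out
}

#' Incremental cost-effectiveness plane points
#'
#' Per-iteration cost and QALY differences of each scenario versus the
#' baseline, for scatterplots of the PSA cloud.
#'
#' @param result A [run_psa()] result.
#' @param baseline Baseline scenario name; defaults to the first scenario.
#' @return Tibble: `iteration`, `name`, `delta_cost`, `delta_qaly`.
#' @export
ce_plane <- function(result, baseline = result$scenarios$name[1]) {
  d <- result$draws
  if (!baseline %in% d$name) {
    rlang::abort(sprintf("Baseline '%s' is not among the scenarios.", baseline))
  }
  base <- d[d$name == baseline, c("iteration", "cost_million_irr", "qaly")]
  names(base) <- c("iteration", "cost0", "qaly0")
  out <- dplyr::left_join(d[d$name != baseline, ], base, by = "iteration")
  tibble::tibble(
    iteration = out$iteration,
    name = out$name,
    delta_cost = out$cost_million_irr - out$cost0,
    delta_qaly = out$qaly - out$qaly0
  )
}

#' Export PSA iterations to CSV
#' @param result A `psa_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result$draws), path, row.names = FALSE)
  invisible(path)
}

#' Export a CEAC to CSV (one probability column per scenario)
#' @param curve A `ceac_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ceac_csv <- function(curve, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(curve),
                             names_from = "name", values_from = "prob")
  utils::write.csv(as.data.frame(wide), path, row.names = FALSE)
  invisible(path)
}
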
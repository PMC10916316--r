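#' Health states of the renal replacement therapy model
#'
#' The model tracks a cohort of end-stage renal disease patients over five
#' states: peritoneal dialysis (`PD`), hemodialysis (`HD`), first year after
#' kidney transplant (`TX1`), subsequent transplant years (`TXP`), and death
#' (`DEAD`, absorbing). `TX1` is a tunnel state: its occupants stay for exactly
#' one cycle, so first-year and later-year transplant costs can differ within
#' a memoryless chain.
#'
#' @return Character vector of the five state labels, in model order.
#' @export
#' @examples
#' rrt_states()
rrt_states <- function() {
  c("PD", "HD", "TX1", "TXP", "DEAD")
}

#' Validate a per-cycle transition probability matrix
#'
#' Checks that `transitions` is a square numeric matrix over the model states
#' with all entries in \[0, 1\], every row summing to 1, an absorbing `DEAD`
#' row, and zero probability of remaining in the `TX1` tunnel state. Rows that
#' sum to 1 within `renormalize_tol` are renormalized with a warning; larger
#' deviations are an error naming the offending row.
#'
#' @param transitions Square numeric matrix of per-cycle transition
#'   probabilities, rows = origin states, columns = destination states.
#'   Dimnames, if absent, are set to [rrt_states()].
#' @param tol Tolerance on row sums after validation (default `1e-9`).
#' @param renormalize_tol Row-sum deviations up to this value are silently
#'   repaired by renormalization, with a warning (default `1e-6`).
#' @return The validated (possibly renormalized) matrix, invisibly classed
#'   for downstream use.
#' @export
#' @examples
#' P <- diag(5)
#' dimnames(P) <- list(rrt_states(), rrt_states())
#' P["TX1", "TX1"] <- 0; P["TX1", "TXP"] <- 1
#' validate_transitions(P)
validate_transitions <- function(transitions, tol = 1e-9,
                                 renormalize_tol = 1e-6) {
  states <- rrt_states()
  n <- length(states)
  if (!is.matrix(transitions) || !is.numeric(transitions)) {
    rlang::abort("`transitions` must be a numeric matrix.")
  }
  if (nrow(transitions) != n || ncol(transitions) != n) {
    rlang::abort(sprintf(
      "`transitions` must be %dx%d over states (%s); got %dx%d.",
      n, n, paste(states, collapse = ", "),
      nrow(transitions), ncol(transitions)
    ))
  }
  if (any(!is.finite(transitions))) {
    rlang::abort("`transitions` contains non-finite entries.")
  }
  if (is.null(dimnames(transitions))) {
    dimnames(transitions) <- list(states, states)
  } else if (!identical(rownames(transitions), states) ||
             !identical(colnames(transitions), states)) {
    rlang::abort(sprintf(
      "`transitions` dimnames must be the states in order: %s.",
      paste(states, collapse = ", ")
    ))
  }

  bad <- which(transitions < -renormalize_tol |
                 transitions > 1 + renormalize_tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    rlang::abort(sprintf(
      "Transition probability [%s -> %s] = %g is outside [0, 1].",
      states[i], states[j], transitions[i, j]
    ))
  }

  sums <- rowSums(transitions)
  dev <- abs(sums - 1)
  if (any(dev > renormalize_tol)) {
    i <- which.max(dev)
    rlang::abort(sprintf(
      "Row %s sums to %.10g, not 1 (deviation %.3g exceeds %.1g).",
      states[i], sums[i], dev[i], renormalize_tol
    ))
  }
  if (any(dev > tol)) {
    rlang::warn(sprintf(
      "Renormalizing %d row(s) whose sums deviate from 1 by up to %.3g.",
      sum(dev > tol), max(dev)
    ))
    transitions <- pmin(pmax(transitions / sums, 0), 1)
  }

  dead_row <- transitions["DEAD", ]
  if (!isTRUE(all.equal(unname(dead_row),
                        as.numeric(states == "DEAD"), tolerance = tol))) {
    rlang::abort("DEAD must be absorbing: its row must be the unit vector onto DEAD.")
  }
  if (transitions["TX1", "TX1"] > tol) {
    rlang::abort(sprintf(
      "TX1 is a one-cycle tunnel state: P[TX1 -> TX1] must be 0, got %g.",
      transitions["TX1", "TX1"]
    ))
  }
  transitions
}

#' Per-cycle discount factor
#'
#' Payoffs accrued during cycle `t` (based on state occupancy at the start of
#' cycle `t`) are discounted by `(1 + rate)^(-t)`, so the first year is
#' undiscounted. Vectorized over `cycle`.
#'
#' @param cycle Non-negative integer cycle index (0-based).
#' @param rate Annual discount rate as a proportion in \[0, 1).
#' @return Numeric discount factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(0:3, 0.035)
discount_factor <- function(cycle, rate) {
  if (any(cycle < 0)) rlang::abort("`cycle` must be non-negative.")
  if (rate < 0 || rate >= 1) rlang::abort("`rate` must be in [0, 1).")
  (1 + rate)^(-cycle)
}

#' Construct a Markov cohort model
#'
#' Bundles the transition matrix, per-state annual payoffs, discount rate and
#' horizon into a validated model object. Costs are in million Iranian Rial
#' (IRR) per state-year; utilities are QALY weights in \[-1, 1\]. `DEAD` must
#' carry zero cost and zero utility.
#'
#' @param transitions Per-cycle transition matrix (see
#'   [validate_transitions()]).
#' @param costs Named numeric vector of annual per-state costs, million IRR;
#'   names must be [rrt_states()].
#' @param utilities Named numeric vector of per-state QALY weights.
#' @param discount_rate Annual discount rate, default 0.035.
#' @param horizon Number of one-year cycles, default 10.
#' @param half_cycle Logical; apply the half-cycle correction (average of
#'   start- and end-of-cycle occupancy) when accruing payoffs. Default `FALSE`.
#' @return An object of class `markov_model`.
#' @export
markov_model <- function(transitions, costs, utilities,
                         discount_rate = 0.035, horizon = 10,
                         half_cycle = FALSE) {
  states <- rrt_states()
  transitions <- validate_transitions(transitions)
  costs <- costs[states]
  utilities <- utilities[states]
  if (any(is.na(costs)) || any(is.na(utilities))) {
    rlang::abort("`costs` and `utilities` must be named over all five states.")
  }
  if (any(costs < 0)) rlang::abort("Per-state costs must be non-negative.")
  if (any(utilities < -1 | utilities > 1)) {
    rlang::abort("Utilities must lie in [-1, 1].")
  }
  if (costs[["DEAD"]] != 0 || utilities[["DEAD"]] != 0) {
    rlang::abort("DEAD must have zero cost and zero utility.")
  }
  if (!is.numeric(horizon) || horizon < 1 || horizon != round(horizon)) {
    rlang::abort("`horizon` must be a positive integer number of cycles.")
  }
  if (discount_rate < 0 || discount_rate >= 1) {
    rlang::abort("`discount_rate` must be in [0, 1).")
  }
  structure(
    list(
      states = states,
      transitions = transitions,
      costs = costs,
      utilities = utilities,
      discount_rate = discount_rate,
      horizon = as.integer(horizon),
      half_cycle = isTRUE(half_cycle)
    ),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> ", length(x$states), " states, horizon ",
      x$horizon, " years, discount ", x$discount_rate * 100, "%",
      if (x$half_cycle) ", half-cycle corrected" else "", "\n", sep = "")
  cat("costs (million IRR/yr): ",
      paste(sprintf("%s=%.6g", x$states, x$costs), collapse = " "), "\n",
      sep = "")
  cat("utilities: ",
      paste(sprintf("%s=%.3f", x$states, x$utilities), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Initial cohort distribution on dialysis
#'
#' Scenarios start the whole incident cohort on dialysis: a share `pd_share`
#' in peritoneal dialysis and the remainder in hemodialysis.
#'
#' @param pd_share Proportion of the cohort starting in PD, in \[0, 1\].
#' @return Named numeric vector over the model states summing to 1.
#' @export
#' @examples
#' initial_distribution(0.03)
initial_distribution <- function(pd_share) {
  if (pd_share < 0 || pd_share > 1) {
    rlang::abort("`pd_share` must be in [0, 1].")
  }
  stats::setNames(c(pd_share, 1 - pd_share, 0, 0, 0), rrt_states())
}

check_init <- function(init) {
  states <- rrt_states()
  if (is.null(names(init)) || !all(names(init) %in% states)) {
    rlang::abort("`init` must be a numeric vector named with model states.")
  }
  full <- stats::setNames(numeric(length(states)), states)
  full[names(init)] <- init
  init <- full
  if (any(init < 0)) rlang::abort("`init` entries must be non-negative.")
  if (abs(sum(init) - 1) > 1e-12) {
    rlang::abort(sprintf("`init` must sum to 1, got %.15g.", sum(init)))
  }
  if (init[["TX1"]] > 0 || init[["TXP"]] > 0 || init[["DEAD"]] > 0) {
    rlang::abort("The cohort must start on dialysis: mass only on PD and HD.")
  }
  init
}

#' Run the cohort simulation
#'
#' Propagates the initial state-occupancy vector through `horizon` cycles of
#' the transition matrix: row `t + 1` of the trace equals row `t` times the
#' matrix.
#'
#' @param model A [markov_model()].
#' @param init Initial occupancy, a named vector over the states (see
#'   [initial_distribution()]).
#' @return A `cohort_trace` tibble with a `cycle` column (0 to `horizon`) and
#'   one occupancy column per state; every row sums to 1.
#' @export
#' @examples
#' m <- esrd_fixture()$model
#' run_cohort(m, initial_distribution(0.03))
run_cohort <- function(model, init) {
  stopifnot(inherits(model, "markov_model"))
  init <- check_init(init)
  states <- model$states
  T_ <- model$horizon
  occ <- matrix(0, nrow = T_ + 1, ncol = length(states),
                dimnames = list(NULL, states))
  occ[1, ] <- init
  for (t in seq_len(T_)) {
    occ[t + 1, ] <- occ[t, , drop = FALSE] %*% model$transitions
  }
  out <- tibble::as_tibble(occ)
  out <- dplyr::bind_cols(tibble::tibble(cycle = 0:T_), out)
  class(out) <- c("cohort_trace", class(out))
  out
}

trace_matrix <- function(trace) {
  as.matrix(trace[, rrt_states(), drop = FALSE])
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Totals are sums over cycles `t = 0 .. horizon - 1` of
#' `discount_factor(t, rate)` times the inner product of the cycle-`t`
#' occupancy row with the per-state payoff. With the half-cycle correction the
#' mean of rows `t` and `t + 1` replaces row `t`, approximating mid-cycle
#' transitions.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param model The [markov_model()] supplying payoffs, discount rate and the
#'   half-cycle flag; individual pieces can be overridden via the remaining
#'   arguments.
#' @param costs,utilities Optional named per-state payoff overrides.
#' @param discount_rate,half_cycle Optional overrides of the model settings.
#' @return A one-row tibble with `cost_million_irr` (discounted total cost, C
#'   in the ICER) and `qaly` (discounted total QALYs, E in the ICER).
#' @export
accumulate_payoffs <- function(trace, model,
                               costs = model$costs,
                               utilities = model$utilities,
                               discount_rate = model$discount_rate,
                               half_cycle = model$half_cycle) {
  occ <- trace_matrix(trace)
  T_ <- nrow(occ) - 1L
  if (T_ < 1) rlang::abort("Trace must contain at least one cycle.")
  costs <- costs[rrt_states()]
  utilities <- utilities[rrt_states()]
  rows <- occ[seq_len(T_), , drop = FALSE]
  if (isTRUE(half_cycle)) {
    rows <- (rows + occ[seq_len(T_) + 1L, , drop = FALSE]) / 2
  }
  df <- discount_factor(0:(T_ - 1L), discount_rate)
  tibble::tibble(
    cost_million_irr = sum(df * (rows %*% costs)),
    qaly = sum(df * (rows %*% utilities))
  )
}

#' Export a cohort trace to CSV
#'
#' Writes the trace with its `cycle` column followed by one occupancy column
#' per state label.
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("cycle", rrt_states())],
                   path, row.names = FALSE)
  invisible(path)
}
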
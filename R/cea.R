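#' Define PD/HD mixture scenarios
#'
#' A scenario is an incident cohort that starts with proportion `pd_share` on
#' peritoneal dialysis and the remainder on hemodialysis.
#'
#' @param pd_share Numeric vector of PD starting shares in \[0, 1\].
#' @param name Optional character vector of scenario labels; defaults to
#'   `S1`, `S2`, ...
#' @return A tibble with columns `name` and `pd_share`.
#' @export
#' @examples
#' scenario_set(c(0.03, 0.30, 0.50, 0.70))
scenario_set <- function(pd_share, name = paste0("S", seq_along(pd_share))) {
  if (any(pd_share < 0 | pd_share > 1)) {
    rlang::abort("`pd_share` values must be in [0, 1].")
  }
  if (anyDuplicated(name)) rlang::abort("Scenario names must be unique.")
  tibble::tibble(name = as.character(name), pd_share = as.numeric(pd_share))
}

#' Run one scenario through the cohort model
#'
#' Builds the initial distribution for `pd_share`, runs the cohort and
#' accumulates discounted payoffs.
#'
#' @param model A [markov_model()].
#' @param pd_share PD starting share in \[0, 1\].
#' @param name Scenario label carried into the result.
#' @return A one-row tibble: `name`, `pd_share`, `cost_million_irr`, `qaly`.
#' @export
run_scenario <- function(model, pd_share, name = "scenario") {
  trace <- run_cohort(model, initial_distribution(pd_share))
  dplyr::bind_cols(
    tibble::tibble(name = name, pd_share = pd_share),
    accumulate_payoffs(trace, model)
  )
}

#' Run a set of scenarios
#'
#' @param model A [markov_model()].
#' @param scenarios A tibble from [scenario_set()] (columns `name`,
#'   `pd_share`).
#' @return A tibble with one row per scenario: `name`, `pd_share`,
#'   `cost_million_irr`, `qaly`.
#' @export
#' @examples
#' fix <- esrd_fixture()
#' run_scenarios(fix$model, fix$scenarios)
run_scenarios <- function(model, scenarios) {
  if (anyDuplicated(scenarios$name)) {
    rlang::abort("Scenario names must be unique.")
  }
  purrr::map2_dfr(scenarios$name, scenarios$pd_share,
                  function(nm, sh) run_scenario(model, sh, nm))
}

#' Incremental cost-effectiveness ratio with dominance verdict
#'
#' Compares a comparator strategy against a reference. The ICER
#' `(C2 - C1) / (E2 - E1)` is reported only when it is meaningful: when the
#' comparator gains QALYs at extra cost (northeast quadrant) or loses QALYs
#' and saves cost (southwest trade-off). Otherwise a dominance verdict is
#' returned instead of a ratio, and an effect difference of exactly zero
#' yields an undefined-ICER verdict rather than a division.
#'
#' @param reference,comparator One-row data frames (or named lists) with
#'   `cost_million_irr` and `qaly`.
#' @return A list of class `icer_result` with `delta_cost`, `delta_qaly`,
#'   `icer` (NA unless a ratio applies) and `verdict`, one of
#'   `"icer"`, `"southwest"`, `"comparator_dominates"`,
#'   `"reference_dominates"`, `"undefined"`.
#' @export
#' @examples
#' icer(list(cost_million_irr = 4750.5, qaly = 2.6756),
#'      list(cost_million_irr = 4846.8, qaly = 2.7181))
icer <- function(reference, comparator) {
  dc <- comparator[["cost_million_irr"]] - reference[["cost_million_irr"]]
  de <- comparator[["qaly"]] - reference[["qaly"]]
  res <- if (de == 0) {
    if (dc == 0) {
      list(icer = NA_real_, verdict = "undefined")
    } else if (dc > 0) {
      list(icer = NA_real_, verdict = "reference_dominates")
    } else {
      list(icer = NA_real_, verdict = "comparator_dominates")
    }
  } else if (de > 0) {
    if (dc <= 0) {
      list(icer = NA_real_, verdict = "comparator_dominates")
    } else {
      list(icer = dc / de, verdict = "icer")
    }
  } else {
    if (dc >= 0) {
      list(icer = NA_real_, verdict = "reference_dominates")
    } else {
      list(icer = dc / de, verdict = "southwest")
    }
  }
  structure(c(list(delta_cost = dc, delta_qaly = de), res),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result> dCost =", format(x$delta_cost), "million IRR, dQALY =",
      format(x$delta_qaly), "\n")
  if (x$verdict %in% c("icer", "southwest")) {
    cat("ICER:", round(x$icer, 1), "million IRR per QALY",
        if (x$verdict == "southwest") "(southwest trade-off)", "\n")
  } else {
    cat("verdict:", x$verdict, "\n")
  }
  invisible(x)
}

strictly_dominated <- function(cost, qaly) {
  n <- length(cost)
  vapply(seq_len(n), function(i) {
    any(cost <= cost[i] & qaly >= qaly[i] &
          (cost < cost[i] | qaly > qaly[i]))
  }, logical(1))
}

#' Build the cost-effectiveness table
#'
#' Sorts scenario results by ascending cost, flags strict dominance (another
#' strategy is at least as cheap and at least as effective, better on one
#' margin) and extended dominance (a sequential ICER exceeding that of the
#' next frontier step, so a mixture of neighbours beats the strategy), then
#' computes sequential ICERs along the retained efficiency frontier and ICERs
#' of every strategy versus the baseline. Sequential ICERs along the frontier
#' are non-decreasing by construction.
#'
#' @param results Tibble from [run_scenarios()]; at least two rows with
#'   unique names.
#' @param baseline Name of the baseline scenario for the vs-baseline ICERs;
#'   defaults to the cheapest.
#' @return A `cea_table` tibble sorted by cost with columns `name`,
#'   `pd_share` (if present), `cost_million_irr`, `qaly`, `delta_cost`,
#'   `delta_qaly`, `icer_sequential` (each retained row vs the previous
#'   frontier row), `icer_vs_baseline`, `dominated`, `ext_dominated`. The
#'   first (cheapest) row has empty increments.
#' @export
#' @examples
#' fix <- esrd_fixture()
#' cea_table(run_scenarios(fix$model, fix$scenarios))
cea_table <- function(results, baseline = NULL) {
  if (nrow(results) < 2) rlang::abort("Need at least two scenario results.")
  if (anyDuplicated(results$name)) {
    rlang::abort("Duplicate scenario names in `results`.")
  }
  if (is.null(baseline)) {
    baseline <- results$name[which.min(results$cost_million_irr)]
  }
  if (!baseline %in% results$name) {
    rlang::abort(sprintf("Baseline '%s' is not among the scenarios.", baseline))
  }
  tab <- dplyr::arrange(results, .data$cost_million_irr, .data$qaly,
                        .data$name)
  tab$dominated <- strictly_dominated(tab$cost_million_irr, tab$qaly)
  tab$ext_dominated <- FALSE

  # Extended dominance: walk the candidate frontier, dropping any strategy
  # whose sequential ICER exceeds that of the next step up. The relative
  # tolerance keeps exactly collinear points (mixtures of two cohorts) on the
  # frontier in the face of floating-point noise.
  repeat {
    keep <- which(!tab$dominated & !tab$ext_dominated)
    if (length(keep) < 3) break
    c_ <- tab$cost_million_irr[keep]
    e_ <- tab$qaly[keep]
    ic <- (c_[-1] - c_[-length(c_)]) / (e_[-1] - e_[-length(e_)])
    tol <- 1e-8 * pmax(abs(ic[-length(ic)]), 1)
    drop <- which(diff(ic) < -tol)
    if (length(drop) == 0) break
    tab$ext_dominated[keep[drop[1] + 1]] <- TRUE
  }

  tab$delta_cost <- NA_real_
  tab$delta_qaly <- NA_real_
  tab$icer_sequential <- NA_real_
  frontier <- which(!tab$dominated & !tab$ext_dominated)
  if (length(frontier) > 1) {
    for (k in seq_along(frontier)[-1]) {
      i <- frontier[k]; prev <- frontier[k - 1]
      tab$delta_cost[i] <- tab$cost_million_irr[i] - tab$cost_million_irr[prev]
      tab$delta_qaly[i] <- tab$qaly[i] - tab$qaly[prev]
      tab$icer_sequential[i] <- tab$delta_cost[i] / tab$delta_qaly[i]
    }
  }

  b <- which(tab$name == baseline)
  tab$icer_vs_baseline <- vapply(seq_len(nrow(tab)), function(i) {
    if (i == b) return(NA_real_)
    r <- icer(tab[b, ], tab[i, ])
    if (r$verdict %in% c("icer", "southwest")) r$icer else NA_real_
  }, numeric(1))

  attr(tab, "baseline") <- baseline
  class(tab) <- c("cea_table", class(tab))
  tab
}

#' Net monetary benefit
#'
#' `NMB = wtp * QALYs - cost`, in million IRR. The strategy maximizing NMB at
#' a willingness-to-pay threshold is the threshold-optimal choice.
#'
#' @param cost Total discounted cost, million IRR (vectorized).
#' @param qaly Total discounted QALYs.
#' @param wtp Willingness-to-pay threshold, million IRR per QALY; must be
#'   non-negative.
#' @return Numeric NMB, million IRR.
#' @export
#' @examples
#' nmb(4989.6, 2.7811, wtp = 3000)
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) rlang::abort("`wtp` must be non-negative.")
  wtp * qaly - cost
}

#' Pick the NMB-optimal scenario at a willingness-to-pay threshold
#'
#' @param results Tibble from [run_scenarios()].
#' @param wtp Willingness-to-pay threshold, million IRR per QALY.
#' @return A one-row tibble: the chosen scenario with its `nmb` and `wtp`;
#'   ties are broken toward the lowest cost.
#' @export
decide <- function(results, wtp) {
  if (nrow(results) < 1) rlang::abort("`results` is empty.")
  v <- nmb(results$cost_million_irr, results$qaly, wtp)
  best <- which(v == max(v))
  if (length(best) > 1) {
    best <- best[which.min(results$cost_million_irr[best])]
  }
  out <- results[best, ]
  out$nmb <- v[best]
  out$wtp <- wtp
  out
}

#' Export a CEA table to CSV
#'
#' Columns mirror the standard cost-utility table layout (scenario, costs in
#' million IRR, QALYs, increments, sequential ICER) plus dominance flags and
#' the vs-baseline ICER; values are written at full precision.
#'
#' @param tab A `cea_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(tab, path) {
  cols <- intersect(
    c("name", "pd_share", "cost_million_irr", "qaly", "delta_cost",
      "delta_qaly", "icer_sequential", "icer_vs_baseline", "dominated",
      "ext_dominated"),
    names(tab)
  )
  utils::write.csv(as.data.frame(tab)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cea_table <- function(x, ...) {
  cat("<cea_table> baseline:", attr(x, "baseline"), "\n")
  disp <- dplyr::mutate(
    tibble::as_tibble(x),
    cost_million_irr = round(.data$cost_million_irr, 1),
    qaly = round(.data$qaly, 4),
    delta_cost = round(.data$delta_cost, 1),
    delta_qaly = round(.data$delta_qaly, 4),
    icer_sequential = round(.data$icer_sequential, 1),
    icer_vs_baseline = round(.data$icer_vs_baseline, 1)
  )
  print(disp, ...)
  invisible(x)
}
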
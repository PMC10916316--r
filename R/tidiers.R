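#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CEA table
#'
#' @param x A `cea_table`.
#' @param ... Unused.
#' @return A plain tibble of the table rows.
#' @method tidy cea_table
#' @export
tidy.cea_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a CEA table
#'
#' @param x A `cea_table`.
#' @param ... Unused.
#' @return Tibble: number of strategies, frontier size, baseline, cost and
#'   QALY ranges.
#' @method glance cea_table
#' @export
glance.cea_table <- function(x, ...) {
  tibble::tibble(
    n_strategies = nrow(x),
    n_frontier = sum(!x$dominated & !x$ext_dominated),
    baseline = attr(x, "baseline"),
    cost_range = diff(range(x$cost_million_irr)),
    qaly_range = diff(range(x$qaly))
  )
}

#' Tidy a PSA result into its per-iteration draws
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Tibble: `iteration`, `name`, `pd_share`, `cost_million_irr`,
#'   `qaly`.
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) {
  x$draws
}

#' Per-scenario Monte Carlo summary of a PSA result
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Tibble with per-scenario means and SDs of cost and QALYs.
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$draws, .data$name),
    cost_mean = mean(.data$cost_million_irr),
    cost_sd = stats::sd(.data$cost_million_irr),
    qaly_mean = mean(.data$qaly),
    qaly_sd = stats::sd(.data$qaly),
    .groups = "drop"
  )
}

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return Per-target tibble with fitted values and relative errors.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  x$fitted
}

#' One-row summary of a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return Tibble: objective value, max relative error, evaluations,
#'   convergence flag.
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$value,
    max_rel_error = x$max_rel_error,
    evaluations = x$evaluations,
    converged = x$converged
  )
}

#' Cost-effectiveness plane of a CEA table
#'
#' Plots each strategy's discounted totals with the efficiency frontier
#' drawn through the non-dominated strategies.
#'
#' @param object A `cea_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cea_table
#' @export
autoplot.cea_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  frontier <- df[!df$dominated & !df$ext_dominated, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qaly,
                                   y = .data$cost_million_irr)) +
    ggplot2::geom_line(data = frontier, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$dominated |
                                       .data$ext_dominated), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "QALYs (discounted)",
                  y = "Cost (million IRR, discounted)",
                  title = "Cost-effectiveness plane")
}

#' Incremental cost-effectiveness plane of a PSA cloud
#'
#' Scatter of per-iteration cost and QALY differences versus the baseline
#' scenario.
#'
#' @param object A `psa_result`.
#' @param baseline Baseline scenario name (default: first scenario).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object,
                                baseline = object$scenarios$name[1], ...) {
  df <- ce_plane(object, baseline)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_qaly,
                                   y = .data$delta_cost,
                                   colour = .data$name)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (million IRR)",
                  colour = "Scenario",
                  title = paste("Incremental CE plane vs", baseline))
}

#' Cost-effectiveness acceptability curves
#'
#' Probability each scenario is NMB-optimal across the willingness-to-pay
#' grid.
#'
#' @param object A `ceac_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$wtp, y = .data$prob,
                               colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (million IRR per QALY)",
                  y = "Probability cost-effective", colour = "Scenario",
                  title = "Cost-effectiveness acceptability curves")
}

#' @export
plot.cea_table <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.psa_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.ceac_curve <- function(x, ...) print(autoplot(x, ...))
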
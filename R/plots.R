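# ggplot2 displays for traces, tornado diagrams, CEAC, CE plane and budget
# impact.

#' @importFrom ggplot2 ggplot aes geom_area geom_line geom_point geom_col
#'   geom_segment geom_vline geom_hline labs scale_y_continuous
#'   scale_x_continuous theme_minimal facet_wrap
NULL

#' Plot a cohort trace
#'
#' Stacked state-occupancy area chart over age.
#'
#' @param object A `"cohort_trace"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(all_of(health_states()), names_to = "state",
                        values_to = "occupancy") %>%
    mutate(state = factor(.data$state, levels = rev(health_states())))
  ggplot(long, aes(x = .data$age, y = .data$occupancy,
                   fill = .data$state)) +
    geom_area() +
    labs(x = "Age (years)", y = "Cohort occupancy", fill = "State",
         title = paste0("Cohort trace: ", attr(object, "strategy"))) +
    theme_minimal()
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars from the ICER at each parameter's low bound to the ICER
#' at its high bound, widest swing on top, with the base-case ICER marked.
#'
#' @param object A `"cua_owsa"` from [run_owsa()].
#' @param top Number of parameters to display (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cua_owsa
#' @export
autoplot.cua_owsa <- function(object, top = 10, ...) {
  d <- as_tibble(object) %>%
    head(top) %>%
    mutate(id = factor(.data$id, levels = rev(.data$id)))
  ggplot(d) +
    geom_segment(aes(x = .data$icer_at_low, xend = .data$icer_at_high,
                     y = .data$id, yend = .data$id), linewidth = 4,
                 colour = "steelblue") +
    geom_vline(xintercept = attr(object, "base_icer"), linetype = 2) +
    labs(x = "ICER (THB per QALY gained)", y = NULL,
         title = sprintf("Tornado: %s vs %s", attr(object, "comparator"),
                         attr(object, "reference"))) +
    theme_minimal()
}

#' Plot a probabilistic sensitivity analysis
#'
#' Either the cost-effectiveness acceptability curves (probability each
#' strategy yields the highest net monetary benefit, against willingness to
#' pay) or the cost-effectiveness plane (incremental cost vs incremental
#' QALYs per iteration, against the reference).
#'
#' @param object A `"cua_psa"` from [run_psa()].
#' @param what `"ceac"` (default) or `"plane"`.
#' @param wtp_line Vertical/threshold marker (THB/QALY); default 160,000.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cua_psa
#' @export
autoplot.cua_psa <- function(object, what = c("ceac", "plane"),
                             wtp_line = 160000, ...) {
  what <- match.arg(what)
  if (what == "ceac") {
    ggplot(object$ceac, aes(x = .data$wtp, y = .data$probability,
                            colour = .data$strategy)) +
      geom_line() +
      geom_vline(xintercept = wtp_line, linetype = 2) +
      scale_y_continuous(limits = c(0, 1)) +
      labs(x = "Willingness to pay (THB per QALY)",
           y = "Probability cost-effective", colour = "Strategy",
           title = "Cost-effectiveness acceptability curves") +
      theme_minimal()
  } else {
    ggplot(object$plane, aes(x = .data$incremental_qaly,
                             y = .data$incremental_cost,
                             colour = .data$strategy)) +
      geom_point(alpha = 0.4, size = 0.8) +
      geom_hline(yintercept = 0) + geom_vline(xintercept = 0) +
      labs(x = "Incremental QALYs", y = "Incremental cost (THB)",
           colour = "Strategy",
           title = paste0("Cost-effectiveness plane vs ",
                          object$reference)) +
      theme_minimal()
  }
}

#' Plot a budget impact projection
#'
#' @param object A `"cua_bia"` from [budget_impact()].
#' @param ... Unused.
#' @return A ggplot of yearly and cumulative incremental expenditure.
#' @method autoplot cua_bia
#' @export
autoplot.cua_bia <- function(object, ...) {
  d <- as_tibble(object) %>%
    tidyr::pivot_longer(c("incremental_cost", "cumulative_cost"),
                        names_to = "series", values_to = "thb")
  ggplot(d, aes(x = .data$year, y = .data$thb / 1e6)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~ .data$series, scales = "free_y") +
    labs(x = "Year", y = "Million THB",
         title = "Budget impact (undiscounted)") +
    theme_minimal()
}

#' Cumulative mortality validation curves
#'
#' Cumulative death-state occupancy by age for one or more strategies, the
#' curve used to compare modelled survival against external cohort data.
#'
#' @param params A `"cua_params"` object.
#' @param ages Ages to evaluate (default 55-65).
#' @param strategies Strategies to plot.
#' @return A ggplot.
#' @export
plot_mortality_curves <- function(params, ages = 55:65,
                                  strategies = strategy_names()) {
  d <- map_dfr(strategies, function(s) {
    cumulative_mortality(run_cohort(params, s), ages) %>%
      mutate(strategy = s)
  })
  ggplot(d, aes(x = .data$age, y = .data$cumulative_mortality,
                colour = .data$strategy)) +
    geom_line() + geom_point() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Age (years)", y = "Cumulative mortality",
         colour = "Strategy", title = "Modelled cumulative mortality") +
    theme_minimal()
}
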
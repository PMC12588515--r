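# Economic settings: discounting, threshold, currency and costing constants.

#' Economic settings for the cost-utility analysis
#'
#' Bundles the economic constants of the evaluation: the annual discount rate
#' applied to costs and outcomes, the willingness-to-pay threshold used for
#' net-monetary-benefit ranking, the THB-to-USD exchange rate used in the
#' reporting layer, the hospital cost-to-charge ratio, the cohort's starting
#' age and terminal age, the gross national income per capita used by the
#' human-capital valuation of informal care, and a consumer price index table
#' for inflating costs to a common fiscal year.
#'
#' Defaults reflect Thai health-technology-assessment practice: 3%/yr
#' discounting, a societal willingness to pay of 160,000 THB per QALY,
#' 1 THB = 0.02877 USD (2023), a cost-to-charge ratio of 1.63, treatment
#' initiation at age 55, and a one-year cycle.
#'
#' @param discount_rate Annual discount rate (fraction/yr, >= 0).
#' @param wtp_threshold Willingness to pay, THB per QALY gained.
#' @param exchange_rate USD per THB (> 0).
#' @param cost_to_charge_ratio Factor relating billed charges to economic
#'   costs (> 0); see [charge_to_cost()].
#' @param charge_direction `"charge_over_cost"` (default) means charges are
#'   `ratio` times costs, so conversion divides; `"cost_over_charge"`
#'   multiplies instead.
#' @param start_age Age (years) at treatment initiation.
#' @param max_age Terminal age (years) capping the lifetime horizon.
#' @param cycle_length Cycle length in years; the model is annual.
#' @param gni_per_capita Gross national income per capita, THB/yr.
#' @param cpi_index Named numeric vector mapping fiscal year to consumer
#'   price index value.
#' @param psa_row_n Dirichlet concentration (effective sample size) used when
#'   probabilistic sensitivity analysis re-draws a transition row; defaults
#'   to 60, the per-arm size of the source trial.
#' @return A list with class `"econ_settings"`.
#' @export
#' @examples
#' econ_settings()$wtp_threshold
econ_settings <- function(discount_rate = 0.03,
                          wtp_threshold = 160000,
                          exchange_rate = 0.02877,
                          cost_to_charge_ratio = 1.63,
                          charge_direction = c("charge_over_cost",
                                               "cost_over_charge"),
                          start_age = 55,
                          max_age = 100,
                          cycle_length = 1,
                          gni_per_capita = 249600,
                          cpi_index = c("2019" = 100.4, "2020" = 99.5,
                                        "2021" = 100.7, "2022" = 106.8,
                                        "2023" = 108.1),
                          psa_row_n = 60) {
  charge_direction <- match.arg(charge_direction)
  s <- list(
    discount_rate = discount_rate,
    wtp_threshold = wtp_threshold,
    exchange_rate = exchange_rate,
    cost_to_charge_ratio = cost_to_charge_ratio,
    charge_direction = charge_direction,
    start_age = start_age,
    max_age = max_age,
    cycle_length = cycle_length,
    gni_per_capita = gni_per_capita,
    cpi_index = cpi_index,
    psa_row_n = psa_row_n
  )
  class(s) <- "econ_settings"
  bad <- settings_violations(s)
  if (nrow(bad) > 0) {
    abort(paste0("invalid economic settings: ",
                 paste(bad$message, collapse = "; ")))
  }
  s
}

settings_violations <- function(s) {
  v <- list()
  chk <- function(ok, parameter, rule, value) {
    if (!isTRUE(ok)) {
      v[[length(v) + 1]] <<- tibble(
        parameter = parameter, rule = rule, value = as.numeric(value)[1],
        message = paste0(parameter, ": ", rule, " (got ", value, ")")
      )
    }
  }
  chk(is.numeric(s$discount_rate) && s$discount_rate >= 0,
      "discount_rate", "must be >= 0", s$discount_rate)
  chk(is.numeric(s$exchange_rate) && s$exchange_rate > 0,
      "exchange_rate", "must be > 0", s$exchange_rate)
  chk(is.numeric(s$cost_to_charge_ratio) && s$cost_to_charge_ratio > 0,
      "cost_to_charge_ratio", "must be > 0", s$cost_to_charge_ratio)
  chk(is.numeric(s$max_age) && s$max_age > s$start_age,
      "max_age", "must exceed start_age", s$max_age)
  chk(is.numeric(s$gni_per_capita) && s$gni_per_capita > 0,
      "gni_per_capita", "must be > 0", s$gni_per_capita)
  chk(is.numeric(s$wtp_threshold) && s$wtp_threshold >= 0,
      "wtp_threshold", "must be >= 0", s$wtp_threshold)
  if (length(v) == 0) violations_tibble() else bind_rows(v)
}

violations_tibble <- function() {
  tibble(parameter = character(), rule = character(),
         value = numeric(), message = character())
}

#' @export
print.econ_settings <- function(x, ...) {
  cat("<econ_settings>\n")
  cat(sprintf("  discount rate        %.3f /yr\n", x$discount_rate))
  cat(sprintf("  WTP threshold        %s THB/QALY\n",
              format(x$wtp_threshold, big.mark = ",")))
  cat(sprintf("  exchange rate        %.5f USD/THB\n", x$exchange_rate))
  cat(sprintf("  cost-to-charge       %.2f (%s)\n", x$cost_to_charge_ratio,
              x$charge_direction))
  cat(sprintf("  ages                 %d -> %d, cycle %g yr\n",
              x$start_age, x$max_age, x$cycle_length))
  cat(sprintf("  GNI per capita       %s THB/yr\n",
              format(x$gni_per_capita, big.mark = ",")))
  invisible(x)
}
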
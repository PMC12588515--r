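# Discounted lifetime totals, incremental cost-effectiveness with dominance
# classification, costing transformations, and budget impact projection.

# Per-state annual amounts for one strategy as a 6 x 3 matrix (state x model
# year); years beyond 3 resolve to the year-3 column.  Death rows are 0.
state_year_matrix <- function(tab, strategy, value_col = "value") {
  m <- matrix(0, nrow = 6, ncol = 3,
              dimnames = list(health_states(), NULL))
  t <- tab[tab$strategy == strategy, ]
  if (nrow(t) > 0) {
    idx <- (t$year - 1L) * 6L + match(t$state, health_states())
    agg <- rowsum(t[[value_col]], idx)
    m[as.integer(rownames(agg))] <- agg[, 1]
  }
  m
}

#' Discounted lifetime totals for one strategy
#'
#' Accumulates discounted lifetime cost, life years and QALYs over a cohort
#' trace: flows of cycle `t` are earned by the occupancy at the start of the
#' cycle and discounted by \eqn{(1+r)^{-t}} with `t = 0` for the first
#' cycle (first-cycle flows undiscounted).  Cost and utility values beyond
#' model year 3 resolve to their year-3 (steady-state) values.
#'
#' @param trace A `"cohort_trace"` from [run_cohort()].
#' @param params The `"cua_params"` the trace was generated from.
#' @return One-row tibble: `strategy`, `cost` (THB), `ly`, `qaly`,
#'   `discount_rate`.
#' @export
#' @examples
#' p <- fixture_parameters()
#' discounted_totals(run_cohort(p, "CAPD"), p)
discounted_totals <- function(trace, params) {
  strategy <- attr(trace, "strategy")
  if (is.null(strategy) || !strategy %in% unique(params$costs$strategy)) {
    abort("trace strategy not present in the parameter tables")
  }
  r <- params$settings$discount_rate
  occ <- as.matrix(trace[, health_states()])
  t_idx <- trace$cycle
  disc <- (1 + r)^(-t_idx)
  year_col <- pmin(t_idx + 1, 3)

  cost_m <- state_year_matrix(params$costs, strategy)
  util_m <- state_year_matrix(params$utilities, strategy)
  util_m["DEATH", ] <- 0

  per_cycle_cost <- rowSums(occ * t(cost_m[, year_col, drop = FALSE]))
  per_cycle_qaly <- rowSums(occ * t(util_m[, year_col, drop = FALSE]))
  per_cycle_ly <- rowSums(occ[, alive_states(), drop = FALSE])

  tibble(
    strategy = strategy,
    cost = sum(disc * per_cycle_cost),
    ly = sum(disc * per_cycle_ly),
    qaly = sum(disc * per_cycle_qaly),
    discount_rate = r
  )
}

#' Discounted totals for several strategies
#'
#' Convenience wrapper running [run_cohort()] and [discounted_totals()] for
#' each strategy.
#'
#' @param params A `"cua_params"` object.
#' @param strategies Character vector of strategies (default all three).
#' @param death_override Passed through to [run_cohort()].
#' @return Tibble with one row per strategy.
#' @export
strategy_totals <- function(params, strategies = strategy_names(),
                            death_override = NULL) {
  map_dfr(strategies, function(s) {
    discounted_totals(run_cohort(params, s, death_override = death_override),
                      params)
  })
}

#' Incremental cost-utility table
#'
#' Computes pairwise incrementals of every comparator against the reference
#' strategy: incremental cost, life years and QALYs, the incremental
#' cost-effectiveness ratio per QALY and per life year
#' (\eqn{\Delta C / \Delta E}), and a dominance classification.  A
#' comparator is *dominated* when it costs more and yields fewer QALYs
#' (\eqn{\Delta C > 0}, \eqn{\Delta QALY < 0}) and *dominant* in the
#' mirror case; dominated comparators still report the signed ratio, as
#' customary in published tables.  \eqn{\Delta E = 0} yields an infinite
#' (undefined) ratio rather than an error.
#'
#' @param totals Tibble with columns `strategy`, `cost`, `ly`, `qaly`
#'   (e.g. from [strategy_totals()], or totals taken from a published
#'   table).
#' @param reference Name of the reference strategy (present in `totals`).
#' @param settings Economic settings (supplies the willingness-to-pay
#'   threshold attached to the result).
#' @return A `"cua_result"` object: list of `totals`, `comparisons`,
#'   `reference`, `wtp_threshold`.
#' @export
#' @examples
#' tot <- tibble::tibble(
#'   strategy = c("CAPD", "CAPD_ICO", "APD"),
#'   cost = c(2487161, 3429977, 2623402),
#'   ly = c(3.56, 4.92, 3.42),
#'   qaly = c(2.76, 3.80, 2.54)
#' )
#' cua_table(tot, reference = "CAPD")
cua_table <- function(totals, reference, settings = econ_settings()) {
  totals <- as_tibble(totals)
  if (!reference %in% totals$strategy) {
    abort(paste0("reference strategy '", reference, "' not in totals"))
  }
  if (nrow(totals) < 2) abort("need at least two strategies")
  ref <- totals[totals$strategy == reference, ]

  comparisons <- totals %>%
    filter(.data$strategy != reference) %>%
    mutate(
      incremental_cost = .data$cost - ref$cost,
      incremental_ly = .data$ly - ref$ly,
      incremental_qaly = .data$qaly - ref$qaly,
      icer_per_qaly = .data$incremental_cost / .data$incremental_qaly,
      icer_per_ly = .data$incremental_cost / .data$incremental_ly,
      dominance = dplyr::case_when(
        .data$incremental_cost > 0 & .data$incremental_qaly < 0 ~ "dominated",
        .data$incremental_cost < 0 & .data$incremental_qaly > 0 ~ "dominant",
        .default = "none"
      )
    ) %>%
    select("strategy", "incremental_cost", "incremental_ly",
           "incremental_qaly", "icer_per_qaly", "icer_per_ly", "dominance")

  structure(
    list(totals = totals, comparisons = comparisons, reference = reference,
         wtp_threshold = settings$wtp_threshold),
    class = "cua_result"
  )
}

#' Run the full base-case cost-utility analysis
#'
#' Runs the cohort model for every strategy and assembles the incremental
#' cost-utility table against the reference (glucose-based CAPD by
#' default).
#'
#' @param params A `"cua_params"` object.
#' @param reference Reference strategy (default `"CAPD"`).
#' @param strategies Strategies to evaluate.
#' @param death_override Passed through to [run_cohort()].
#' @return A `"cua_result"` object.
#' @export
#' @examples
#' run_cua(fixture_parameters())
run_cua <- function(params, reference = "CAPD",
                    strategies = strategy_names(), death_override = NULL) {
  totals <- strategy_totals(params, strategies,
                            death_override = death_override)
  cua_table(totals, reference, settings = params$settings)
}

#' @export
print.cua_result <- function(x, ...) {
  cat("Cost-utility analysis (reference:", x$reference, ")\n\n")
  tot <- x$totals %>%
    mutate(cost = format(round(.data$cost), big.mark = ","),
           ly = sprintf("%.2f", .data$ly), qaly = sprintf("%.2f", .data$qaly))
  print(as.data.frame(tot), row.names = FALSE)
  cat("\nIncremental vs", x$reference, ":\n")
  cmp <- x$comparisons %>%
    mutate(
      incremental_cost = format(round(.data$incremental_cost),
                                big.mark = ","),
      icer_per_qaly = ifelse(
        .data$dominance == "dominated",
        sprintf("Dominated (%s)", format(round(.data$icer_per_qaly),
                                         big.mark = ",")),
        format(round(.data$icer_per_qaly), big.mark = ",")),
      dplyr::across(c("incremental_ly", "incremental_qaly"),
                    ~ sprintf("%.2f", .x))
    ) %>%
    select("strategy", "incremental_cost", "incremental_ly",
           "incremental_qaly", "icer_per_qaly", "dominance")
  print(as.data.frame(cmp), row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Costing transformations

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert THB amounts to USD for reporting
#'
#' Multiplies by the exchange rate and additionally reports the value
#' rounded half-away-from-zero to whole dollars, the convention used for
#' published figures.  All model accumulation stays in THB; conversion is a
#' reporting layer only.
#'
#' @param amount_thb Numeric vector of amounts in THB.
#' @param settings Economic settings (supplies `exchange_rate`, USD per
#'   THB).
#' @return Tibble with columns `thb`, `usd` (unrounded), `usd_rounded`.
#' @export
#' @examples
#' convert_currency(160000)  # 4,603 USD
convert_currency <- function(amount_thb, settings = econ_settings()) {
  usd <- amount_thb * settings$exchange_rate
  tibble(thb = amount_thb, usd = usd, usd_rounded = round_half_away(usd))
}

#' Inflate costs between fiscal years with the consumer price index
#'
#' @param cost Numeric vector of costs (THB).
#' @param from_year,to_year Fiscal years present in `settings$cpi_index`.
#' @param settings Economic settings.
#' @return `cost * cpi(to_year) / cpi(from_year)`.
#' @export
#' @examples
#' adjust_cpi(100000, 2019, 2023)
adjust_cpi <- function(cost, from_year, to_year,
                       settings = econ_settings()) {
  cpi <- settings$cpi_index
  for (y in c(from_year, to_year)) {
    if (!as.character(y) %in% names(cpi)) {
      abort(paste0("no CPI index value for year ", y))
    }
  }
  cost * cpi[[as.character(to_year)]] / cpi[[as.character(from_year)]]
}

#' Convert billed hospital charges to economic costs
#'
#' Applies the cost-to-charge ratio.  With the default direction
#' (`"charge_over_cost"`, ratio 1.63) charges exceed costs and the charge
#' is divided by the ratio; the direction is configurable in
#' [econ_settings()] because conventions differ between hospital systems.
#'
#' @param charge Numeric vector of billed charges (THB, >= 0).
#' @param settings Economic settings.
#' @return Numeric vector of economic costs (THB).
#' @export
#' @examples
#' charge_to_cost(163)  # 100 THB at ratio 1.63
charge_to_cost <- function(charge, settings = econ_settings()) {
  if (any(charge < 0)) abort("`charge` must be >= 0")
  ratio <- settings$cost_to_charge_ratio
  if (!is.numeric(ratio) || ratio <= 0) {
    abort("cost-to-charge ratio must be > 0")
  }
  if (settings$charge_direction == "charge_over_cost") {
    charge / ratio
  } else {
    charge * ratio
  }
}

#' Value informal caregiving time by the human-capital method
#'
#' Values unpaid caregiving hours at an hourly wage derived from gross
#' national income per capita: GNI divided by 52 weeks and a 48-hour
#' working week.
#'
#' @param hours Annual caregiving hours (>= 0).
#' @param settings Economic settings (supplies `gni_per_capita`, THB/yr).
#' @return Annual informal-care cost, THB/yr.
#' @export
#' @examples
#' informal_care_cost(52 * 48)  # exactly one GNI per capita
informal_care_cost <- function(hours, settings = econ_settings()) {
  if (any(hours < 0)) abort("`hours` must be >= 0")
  hours * settings$gni_per_capita / (52 * 48)
}

#' Undiscounted budget impact projection
#'
#' Projects the payer's incremental expenditure from switching the eligible
#' population to a new treatment: each year's impact is the number of
#' eligible patients times the difference in annual per-patient treatment
#' cost, held constant over the horizon (constant-population assumption)
#' and never discounted.
#'
#' @param patients_per_year Eligible patients treated per year (>= 0).
#' @param annual_cost_new,annual_cost_old Annual per-patient treatment cost
#'   (THB) under the new and current treatment.
#' @param horizon_years Projection horizon (default 10 years).
#' @return A `"cua_bia"` tibble: `year`, `patients`, `incremental_cost`,
#'   `cumulative_cost` (THB).
#' @export
#' @examples
#' budget_impact(600, 747167, 650000)
budget_impact <- function(patients_per_year, annual_cost_new,
                          annual_cost_old, horizon_years = 10) {
  if (any(c(patients_per_year, annual_cost_new, annual_cost_old,
            horizon_years) < 0)) {
    abort("budget impact inputs must be >= 0")
  }
  yearly <- patients_per_year * (annual_cost_new - annual_cost_old)
  out <- tibble(
    year = seq_len(horizon_years),
    patients = patients_per_year,
    incremental_cost = yearly,
    cumulative_cost = cumsum(rep(yearly, horizon_years))
  )
  structure(out, class = c("cua_bia", class(out)))
}
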
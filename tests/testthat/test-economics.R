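# Economics layer: discounting, incremental CUA, costing transforms, BIA.

test_that("undiscounted QALYs equal life years at full health", {
  p <- toy_matrix_params(constant_death_matrix(0.3), cost = 1000,
                         utility = 1,
                         settings = econ_settings(discount_rate = 0))
  tot <- discounted_totals(run_cohort(p, "CAPD"), p)
  expect_equal(tot$qaly, tot$ly, tolerance = 1e-12)
})

test_that("three discounted annual payments sum to the geometric series", {
  # alive with certainty for cycles 0-2, certain death entering cycle 3
  s <- health_states()
  rows <- list()
  for (arm in strategy_names()) {
    for (y in 1:3) {
      for (a in setdiff(s, "DEATH")) {
        if (y < 3) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            strategy = arm, year = y, from = a, to = a, value = 1,
            provenance = "toy")
        } else {
          rows[[length(rows) + 1]] <- tibble::tibble(
            strategy = arm, year = y, from = a, to = "DEATH", value = 1,
            provenance = "toy")
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        strategy = arm, year = y, from = "DEATH", to = "DEATH", value = 1,
        provenance = "toy")
    }
  }
  grid <- tidyr::expand_grid(strategy = strategy_names(),
                             state = setdiff(s, "DEATH"), year = 1:3)
  costs <- dplyr::mutate(grid, component = "medical", value = 100000,
                         informal_care = FALSE, provenance = "toy")
  utilities <- dplyr::mutate(grid, value = 0.5, provenance = "toy")
  p <- cua_parameters(dplyr::bind_rows(rows), costs, utilities,
                      settings = econ_settings(discount_rate = 0.03))
  tot <- discounted_totals(run_cohort(p, "CAPD"), p)
  expect_equal(tot$cost, 100000 * (1 + 1.03^-1 + 1.03^-2),
               tolerance = 1e-12)
  expect_equal(tot$ly, 1 + 1.03^-1 + 1.03^-2, tolerance = 1e-12)
})

test_that("a cohort that is entirely dead accrues nothing", {
  p <- fixture_parameters()
  tr <- tibble::tibble(cycle = 0:2, age = 55:57, CAPD = 0, CAPD_ICO = 0,
                       APD = 0, HD = 0, KT = 0, DEATH = 1)
  tr <- structure(tr, class = c("cohort_trace", class(tr)),
                  strategy = "CAPD", start_age = 55)
  tot <- discounted_totals(tr, p)
  expect_equal(tot$cost, 0)
  expect_equal(tot$ly, 0)
  expect_equal(tot$qaly, 0)
})

test_that("totals are non-increasing in the discount rate", {
  totals_at <- function(r) {
    strategy_totals(fixture_parameters(econ_settings(discount_rate = r)))
  }
  t0 <- totals_at(0); t3 <- totals_at(0.03); t6 <- totals_at(0.06)
  expect_true(all(t0$cost >= t3$cost & t3$cost >= t6$cost))
  expect_true(all(t0$qaly >= t3$qaly & t3$qaly >= t6$qaly))
  expect_true(all(t0$ly >= t3$ly & t3$ly >= t6$ly))
})

test_that("zero discounting reproduces the plain cycle sums", {
  p <- fixture_parameters(econ_settings(discount_rate = 0))
  tr <- run_cohort(p, "CAPD")
  tot <- discounted_totals(tr, p)
  occ <- as.matrix(tr[, health_states()])
  alive <- setdiff(health_states(), "DEATH")
  expect_equal(tot$ly, sum(occ[, alive]), tolerance = 1e-12)
})

test_that("published totals give the published incrementals and dominance", {
  res <- cua_table(published_totals(), reference = "CAPD")
  cmp <- tidy(res)
  ico <- cmp[cmp$strategy == "CAPD_ICO", ]
  apd <- cmp[cmp$strategy == "APD", ]
  expect_equal(ico$incremental_cost, 942816)
  expect_equal(ico$incremental_ly, 1.36)
  expect_equal(ico$incremental_qaly, 1.04)
  expect_equal(apd$incremental_cost, 136241)
  expect_equal(apd$incremental_ly, -0.14)
  expect_equal(apd$incremental_qaly, -0.22)
  expect_equal(apd$dominance, "dominated")
  expect_equal(ico$dominance, "none")
  # dominated comparator still carries its signed ratio
  expect_lt(apd$icer_per_qaly, 0)
  expect_lt(apd$icer_per_ly, 0)
})

test_that("swapping reference and comparator negates the incrementals", {
  tot <- published_totals()
  a <- tidy(cua_table(tot, "CAPD"))
  b <- tidy(cua_table(tot, "CAPD_ICO"))
  expect_equal(b$incremental_cost[b$strategy == "CAPD"],
               -a$incremental_cost[a$strategy == "CAPD_ICO"])
  expect_equal(b$incremental_qaly[b$strategy == "CAPD"],
               -a$incremental_qaly[a$strategy == "CAPD_ICO"])
})

test_that("scaling all costs scales all ICERs by the same factor", {
  tot <- published_totals()
  k <- 2.5
  scaled <- dplyr::mutate(tot, cost = cost * k)
  a <- tidy(cua_table(tot, "CAPD"))
  b <- tidy(cua_table(scaled, "CAPD"))
  expect_equal(b$icer_per_qaly, k * a$icer_per_qaly, tolerance = 1e-12)
  expect_equal(b$icer_per_ly, k * a$icer_per_ly, tolerance = 1e-12)
})

test_that("an identical comparator yields an undefined, not erroring, ICER", {
  tot <- dplyr::bind_rows(
    published_totals()[1, ],
    dplyr::mutate(published_totals()[1, ], strategy = "CAPD_ICO")
  )
  res <- tidy(cua_table(tot, "CAPD"))
  expect_equal(res$incremental_cost, 0)
  expect_equal(res$incremental_qaly, 0)
  expect_false(is.finite(res$icer_per_qaly))
})

test_that("currency conversion reproduces the published USD figures", {
  conv <- convert_currency(c(160000, 908440, 2487161, 942816, 0))
  expect_equal(conv$usd_rounded, c(4603, 26136, 71556, 27125, 0))
  expect_equal(conv$usd, c(160000, 908440, 2487161, 942816, 0) * 0.02877)
})

test_that("CPI adjustment is a ratio of index values and telescopes", {
  s <- econ_settings(cpi_index = c("2019" = 100, "2021" = 110,
                                   "2023" = 121))
  expect_equal(adjust_cpi(500, 2021, 2021, s), 500)
  expect_equal(adjust_cpi(100, 2019, 2021, s), 110)
  chained <- adjust_cpi(adjust_cpi(100, 2019, 2021, s), 2021, 2023, s)
  expect_equal(chained, adjust_cpi(100, 2019, 2023, s), tolerance = 1e-12)
  expect_error(adjust_cpi(100, 1999, 2023, s), "1999")
})

test_that("charge-to-cost conversion respects ratio and direction", {
  expect_equal(charge_to_cost(163), 100)
  expect_equal(charge_to_cost(0), 0)
  s1 <- econ_settings(cost_to_charge_ratio = 1)
  expect_equal(charge_to_cost(123.45, s1), 123.45)
  s2 <- econ_settings(charge_direction = "cost_over_charge")
  expect_equal(charge_to_cost(100, s2), 163)
  expect_error(charge_to_cost(-1), ">= 0")
})

test_that("informal care is valued at the GNI-derived hourly wage", {
  s <- econ_settings(gni_per_capita = 249600)
  expect_equal(informal_care_cost(52 * 48, s), 249600)
  expect_equal(informal_care_cost(0, s), 0)
  expect_equal(informal_care_cost(10, s), 1000)
  expect_error(informal_care_cost(-5, s), ">= 0")
})

test_that("budget impact is linear, undiscounted and cumulative", {
  zero <- budget_impact(0, 800000, 650000)
  expect_true(all(zero$incremental_cost == 0))
  expect_true(all(zero$cumulative_cost == 0))

  one <- budget_impact(1, 750000, 650000)
  expect_equal(one$incremental_cost, rep(100000, 10))
  expect_equal(one$cumulative_cost[10], 10 * 100000)

  # linearity in patients and in the cost difference
  b1 <- budget_impact(300, 740000, 650000)
  b2 <- budget_impact(600, 740000, 650000)
  expect_equal(b2$incremental_cost, 2 * b1$incremental_cost)
  b3 <- budget_impact(300, 830000, 650000)
  expect_equal(b3$incremental_cost, 2 * b1$incremental_cost)
})
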
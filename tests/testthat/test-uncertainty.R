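# Sensitivity and scenario analyses: tornado, PSA, mortality inflation,
# external inputs.

test_that("tornado entries are sorted by swing and include icodextrin cost", {
  p <- fixture_parameters()
  ow <- run_owsa(p, "CAPD", "CAPD_ICO")
  expect_true(all(diff(ow$swing) <= 1e-9))
  expect_true(any(grepl("icodextrin", ow$id)))
  expect_true(is.finite(attr(ow, "base_icer")))
})

test_that("a degenerate bound (low = high = mean) has zero swing, ranked last", {
  p <- fixture_parameters()
  i <- which(p$uncertainty$id == "utility.CAPD_ICO.CAPD_ICO.y1")
  p$uncertainty$low[i] <- p$uncertainty$mean[i]
  p$uncertainty$high[i] <- p$uncertainty$mean[i]
  ids <- c("utility.CAPD_ICO.CAPD_ICO.y1",
           "cost.CAPD_ICO.CAPD_ICO.y1.icodextrin",
           "prob.CAPD_ICO.y1.CAPD_ICO.DEATH")
  ow <- run_owsa(p, "CAPD", "CAPD_ICO", parameters = ids)
  expect_equal(ow$swing[ow$id == "utility.CAPD_ICO.CAPD_ICO.y1"], 0)
  expect_equal(ow$id[nrow(ow)], "utility.CAPD_ICO.CAPD_ICO.y1")
})

test_that("raising a comparator-only cost raises the ICER", {
  p <- fixture_parameters()
  i <- which(p$uncertainty$id == "cost.CAPD_ICO.CAPD_ICO.y1.icodextrin")
  p$uncertainty$low[i] <- p$uncertainty$mean[i]
  p$uncertainty$high[i] <- 2 * p$uncertainty$mean[i]
  ow <- run_owsa(p, "CAPD", "CAPD_ICO",
                 parameters = "cost.CAPD_ICO.CAPD_ICO.y1.icodextrin")
  expect_equal(ow$icer_at_low, attr(ow, "base_icer"), tolerance = 1e-12)
  expect_gt(ow$icer_at_high, ow$icer_at_low)
})

test_that("an infeasible bound is clipped to the boundary with a note", {
  p <- fixture_parameters()
  id <- "prob.CAPD.y1.CAPD.DEATH"
  i <- which(p$uncertainty$id == id)
  p$uncertainty$high[i] <- 1.4
  expect_message(
    ow <- run_owsa(p, "CAPD", "CAPD_ICO", parameters = id),
    "clipped"
  )
  expect_true(is.finite(ow$icer_at_high))
})

test_that("a parameter not touching either strategy has zero swing", {
  p <- fixture_parameters()
  ow <- run_owsa(p, "CAPD", "CAPD_ICO",
                 parameters = c("cost.APD.APD.y1.medical",
                                "utility.APD.APD.y2",
                                "prob.APD.y1.APD.DEATH"))
  expect_equal(ow$swing, rep(0, 3))
})

test_that("probabilistic draws are seed-reproducible and valid", {
  p <- fixture_parameters()
  d1 <- draw_psa_parameters(p, seed = 7)
  d2 <- draw_psa_parameters(p, seed = 7)
  expect_identical(d1$transitions, d2$transitions)
  expect_identical(d1$costs, d2$costs)
  expect_identical(d1$utilities, d2$utilities)
  expect_false(identical(draw_psa_parameters(p, seed = 8)$costs, d1$costs))
  for (s in 1:10) {
    expect_equal(nrow(validate_parameters(draw_psa_parameters(p, s))), 0)
  }
})

test_that("zero-variance metadata reproduces the base case exactly", {
  p <- fixture_parameters()
  p$uncertainty$se <- 0
  d <- draw_psa_parameters(p, seed = 1)
  expect_identical(d$transitions, p$transitions)
  expect_identical(d$costs, p$costs)
  expect_identical(d$utilities, p$utilities)
})

test_that("beta draws match the requested mean", {
  p <- fixture_parameters()
  p$uncertainty$se <- 0
  i <- which(p$uncertainty$id == "utility.CAPD.CAPD.y1")
  p$uncertainty$mean[i] <- 0.2
  p$uncertainty$se[i] <- 0.05
  set.seed(42)
  draws <- replicate(1000, {
    d <- draw_psa_parameters(p)
    d$utilities$value[d$utilities$strategy == "CAPD" &
                        d$utilities$state == "CAPD" &
                        d$utilities$year == 1]
  })
  expect_lt(abs(mean(draws) - 0.2), 3 * 0.05 / sqrt(1000))
  expect_gt(stats::sd(draws), 0.03)
})

test_that("PSA output is bit-identical under the same seed", {
  p <- fixture_parameters()
  a <- run_psa(p, iterations = 10, seed = 3, wtp_grid = c(0, 160000, 1e6))
  b <- run_psa(p, iterations = 10, seed = 3, wtp_grid = c(0, 160000, 1e6))
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  expect_identical(a$plane, b$plane)
})

test_that("CEAC probabilities sum to one at every willingness-to-pay", {
  p <- fixture_parameters()
  psa <- run_psa(p, iterations = 40, seed = 5)
  sums <- psa$ceac |>
    dplyr::group_by(wtp) |>
    dplyr::summarise(s = sum(probability))
  expect_equal(sums$s, rep(1, length(psa$wtp_grid)))
  expect_true(all(psa$ceac$probability >= 0 & psa$ceac$probability <= 1))
})

test_that("degenerate PSA equals the deterministic base case", {
  p <- fixture_parameters()
  p$uncertainty$se <- 0
  base <- strategy_totals(p)
  psa <- run_psa(p, iterations = 3, seed = 1,
                 wtp_grid = c(0, 160000, 1600000))
  for (i in 1:3) {
    it <- psa$draws[psa$draws$iteration == i, c("strategy", "cost", "ly",
                                                "qaly")]
    expect_equal(as.data.frame(it), as.data.frame(base[, names(it)]))
  }
  # the base-case NMB maximiser is certain at every threshold
  for (w in unique(psa$ceac$wtp)) {
    nmb <- w * base$qaly - base$cost
    best <- base$strategy[which.max(nmb)]
    at <- psa$ceac[psa$ceac$wtp == w, ]
    expect_equal(at$probability[at$strategy == best], 1)
  }
})

test_that("CEAC limits select the cheapest and the most effective strategy", {
  p <- fixture_parameters()
  psa <- run_psa(p, iterations = 30, seed = 11,
                 wtp_grid = c(0, 1e9))
  cheapest_freq <- psa$draws |>
    dplyr::group_by(iteration) |>
    dplyr::summarise(win = strategy[which.min(cost)]) |>
    dplyr::count(win)
  at0 <- psa$ceac[psa$ceac$wtp == 0, ]
  for (i in seq_len(nrow(cheapest_freq))) {
    expect_equal(
      at0$probability[at0$strategy == cheapest_freq$win[i]],
      cheapest_freq$n[i] / 30
    )
  }
  best_freq <- psa$draws |>
    dplyr::group_by(iteration) |>
    dplyr::summarise(win = strategy[which.max(qaly)]) |>
    dplyr::count(win)
  athi <- psa$ceac[psa$ceac$wtp == 1e9, ]
  for (i in seq_len(nrow(best_freq))) {
    expect_equal(
      athi$probability[athi$strategy == best_freq$win[i]],
      best_freq$n[i] / 30
    )
  }
})

test_that("the base-case NMB maximiser tops the mean acceptability curve", {
  p <- fixture_parameters()
  base <- strategy_totals(p)
  nmb <- 160000 * base$qaly - base$cost
  best <- base$strategy[which.max(nmb)]
  probs <- vapply(1:5, function(s) {
    psa <- run_psa(p, iterations = 60, seed = s, wtp_grid = 160000)
    at <- psa$ceac
    setNames(at$probability, at$strategy)[c("CAPD", "CAPD_ICO", "APD")]
  }, numeric(3))
  mean_prob <- rowMeans(probs)
  expect_equal(names(which.max(mean_prob)), best)
})

test_that("zero mortality inflation is bit-identical to the base case", {
  p <- fixture_parameters()
  base <- run_cua(p)
  s0 <- scenario_mortality_inflation(p, 0)
  expect_identical(s0$totals, base$totals)
  expect_identical(s0$comparisons, base$comparisons)
  expect_error(scenario_mortality_inflation(p, 1.5), "\\[0, 1\\]")
  expect_error(scenario_mortality_inflation(p, -0.1), "\\[0, 1\\]")
})

test_that("inflated mortality caps at certain death", {
  # constant hazard 0.6 in years 1-3 and hence steady; f = 1 doubles it to
  # 1.2, capped at 1: survivors of cycle 3 all die in cycle 4
  p <- toy_matrix_params(constant_death_matrix(0.6), cost = 0, utility = 1,
                         settings = econ_settings(discount_rate = 0))
  res <- scenario_mortality_inflation(p, 1, reference = "CAPD")
  ly <- res$totals$ly[res$totals$strategy == "CAPD"]
  expect_equal(ly, 1 + 0.4 + 0.4^2 + 0.4^3, tolerance = 1e-12)
})

test_that("the comparator stays beyond the threshold across the sweep", {
  p <- fixture_parameters()
  icers <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    res <- scenario_mortality_inflation(p, f)
    res$comparisons$icer_per_qaly[res$comparisons$strategy == "CAPD_ICO"]
  }, numeric(1))
  expect_true(all(is.finite(icers)))
  expect_true(all(icers > 160000))
  # smooth, modest variation across the sweep
  expect_lt(max(abs(diff(icers))) / icers[1], 0.25)
})

test_that("external inputs equal to the base case reproduce it", {
  p <- fixture_parameters()
  base <- run_cua(p)
  res <- scenario_external_inputs(p, replacement_utility = p$utilities)
  expect_identical(res$totals, base$totals)
})

test_that("lowering comparator utilities lowers its incremental QALYs", {
  p <- fixture_parameters()
  base <- run_cua(p)
  repl <- p$utilities |>
    dplyr::filter(strategy == "CAPD_ICO", state != "DEATH") |>
    dplyr::mutate(value = value - 0.1)
  res <- scenario_external_inputs(p, replacement_utility = repl)
  expect_lt(
    res$comparisons$incremental_qaly[res$comparisons$strategy == "CAPD_ICO"],
    base$comparisons$incremental_qaly[base$comparisons$strategy ==
                                        "CAPD_ICO"]
  )
})

test_that("age-indexed mortality maps onto cycles via the starting age", {
  p <- fixture_parameters()
  # suppress all deaths in the cycle starting at age 56 for the CAPD arm
  ov <- tibble::tibble(strategy = "CAPD", age = 56, value = 0)
  res <- scenario_external_inputs(p, replacement_mortality = ov)
  tr <- run_cohort(p, "CAPD", death_override = ov)
  cm <- cumulative_mortality(tr, 55:57)
  expect_equal(cm$cumulative_mortality[2], 0.1667)
  expect_equal(cm$cumulative_mortality[3], 0.1667)  # no deaths that cycle
  # certain immediate death via the override
  ov1 <- tibble::tibble(strategy = "CAPD", age = 55, value = 1)
  tr1 <- run_cohort(p, "CAPD", death_override = ov1)
  expect_equal(tr1$DEATH[2], 1)
  expect_error(
    scenario_external_inputs(
      p, replacement_mortality = tibble::tibble(age = 60, value = 1.2)),
    "\\[0, 1\\]")
  expect_true(inherits(res, "cua_result"))
})
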
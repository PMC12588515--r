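# One-way (tornado) sensitivity analysis, probabilistic sensitivity
# analysis with CE plane and acceptability curves, and scenario analyses.

icer_between <- function(params, reference, comparator,
                         death_override = NULL) {
  tot <- strategy_totals(params, c(reference, comparator),
                         death_override = death_override)
  ref <- tot[tot$strategy == reference, ]
  cmp <- tot[tot$strategy == comparator, ]
  (cmp$cost - ref$cost) / (cmp$qaly - ref$qaly)
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full lifetime model twice per parameter - once at its low and
#' once at its high bound, all other parameters at base case - and records
#' the ICER of the comparator against the reference each time.  Entries are
#' returned sorted by the ICER swing (|high - low|), the ordering of a
#' tornado diagram.  Bounds that would breach a structural invariant (e.g.
#' a probability above 1) are clipped to the feasible boundary with a note.
#'
#' @param params A `"cua_params"` object with uncertainty metadata.
#' @param reference,comparator Strategy names; the ICER is
#'   comparator-vs-reference.
#' @param parameters Optional character vector of parameter ids to restrict
#'   to (default: every row of the uncertainty table).
#' @return A `"cua_owsa"` tibble: `id`, `target`, `strategy`, `low`,
#'   `high`, `icer_at_low`, `icer_at_high`, `swing`, sorted by `swing`
#'   descending, with the base-case ICER attached as attribute
#'   `base_icer`.
#' @export
#' @examples
#' \donttest{
#' ow <- run_owsa(fixture_parameters(), "CAPD", "CAPD_ICO")
#' head(ow, 3)
#' }
run_owsa <- function(params, reference = "CAPD", comparator = "CAPD_ICO",
                     parameters = NULL) {
  assert_strategy(reference); assert_strategy(comparator)
  meta <- params$uncertainty
  if (is.null(meta) || nrow(meta) == 0) {
    abort("parameter set carries no uncertainty metadata")
  }
  if (!is.null(parameters)) meta <- meta[meta$id %in% parameters, ]

  base_icer <- icer_between(params, reference, comparator)
  res <- map_dfr(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    lo <- icer_between(set_parameter(params, row, row$low),
                       reference, comparator)
    hi <- icer_between(set_parameter(params, row, row$high),
                       reference, comparator)
    tibble(id = row$id, target = row$target, strategy = row$strategy,
           low = row$low, high = row$high,
           icer_at_low = lo, icer_at_high = hi,
           swing = abs(hi - lo))
  })
  res <- res %>% arrange(desc(.data$swing))
  structure(res, class = c("cua_owsa", class(res)),
            base_icer = base_icer, reference = reference,
            comparator = comparator)
}

# ---------------------------------------------------------------------------
# Probabilistic sensitivity analysis

draw_beta <- function(m, se) {
  if (se == 0) return(m)
  v <- se^2
  if (v >= m * (1 - m)) {
    inform(sprintf(
      "beta moment match infeasible (mean %.4g, se %.4g); uniform fallback",
      m, se))
    lo <- max(0, m - sqrt(3) * se)
    hi <- min(1, m + sqrt(3) * se)
    return(runif(1, lo, hi))
  }
  k <- m * (1 - m) / v - 1
  rbeta(1, m * k, (1 - m) * k)
}

draw_gamma <- function(m, se) {
  if (se == 0 || m == 0) return(m)
  v <- se^2
  rgamma(1, shape = m^2 / v, rate = m / v)
}

# Draw one Dirichlet row: alpha_j = p_j * n keeps the row mean at p.
draw_dirichlet_row <- function(p, n) {
  g <- rgamma(length(p), shape = p * n, rate = 1)
  g / sum(g)
}

# Single draw using the current RNG stream.
draw_psa_once <- function(params) {
  meta <- params$uncertainty
  if (is.null(meta)) abort("parameter set carries no uncertainty metadata")

  costs <- params$costs
  cmeta <- meta[meta$target == "cost", ]
  for (i in seq_len(nrow(cmeta))) {
    row <- cmeta[i, ]
    if (row$se == 0) next
    j <- which(costs$strategy == row$strategy & costs$state == row$state &
                 costs$year == row$year & costs$component == row$component)
    costs$value[j] <- draw_gamma(row$mean, row$se)
  }

  utilities <- params$utilities
  umeta <- meta[meta$target == "utility", ]
  for (i in seq_len(nrow(umeta))) {
    row <- umeta[i, ]
    if (row$se == 0) next
    j <- which(utilities$strategy == row$strategy &
                 utilities$state == row$state & utilities$year == row$year)
    utilities$value[j] <- draw_beta(row$mean, row$se)
  }

  tr <- params$transitions
  tmeta <- meta[meta$target == "transition", ]
  any_trans <- FALSE
  if (nrow(tmeta) > 0) {
    rows_to_draw <- tmeta %>%
      group_by(.data$strategy, .data$year, .data$from) %>%
      summarise(draw = any(.data$se > 0), .groups = "drop") %>%
      filter(.data$draw)
    n0 <- params$settings$psa_row_n
    for (i in seq_len(nrow(rows_to_draw))) {
      g <- rows_to_draw[i, ]
      j <- which(tr$strategy == g$strategy & tr$year == g$year &
                   tr$from == g$from)
      tr$value[j] <- draw_dirichlet_row(tr$value[j], n0)
      any_trans <- TRUE
    }
  }

  out <- params
  out$costs <- costs
  out$utilities <- utilities
  out$transitions <- tr
  if (any_trans && isTRUE(out$steady_derived)) out <- rebuild_steady(out)
  out
}

#' Draw one probabilistic parameter set
#'
#' Samples every parameter with positive standard error from its assigned
#' family - gamma for costs and beta for utilities, both matched to the
#' stated mean and standard error by the method of moments, and Dirichlet
#' for transition rows with concentration `psa_row_n` preserving the row
#' mean.  Steady-state rows are re-derived from the drawn years 1-3.  An
#' infeasible beta moment match (standard error too large for the mean)
#' falls back to a uniform draw on the clipped feasible interval with a
#' note.  Identical seeds give identical draws; parameters with zero
#' standard error are returned unchanged.
#'
#' @param params A `"cua_params"` object with uncertainty metadata.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A validated `"cua_params"` draw.
#' @export
#' @examples
#' d <- draw_psa_parameters(fixture_parameters(), seed = 7)
draw_psa_parameters <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_psa_once(params)
}

#' Default willingness-to-pay grid
#'
#' 0 to 1,600,000 THB/QALY in 10,000-THB steps (ten times the Thai
#' threshold), always containing 160,000 exactly.
#'
#' @return Numeric vector of WTP values (THB/QALY).
#' @export
default_wtp_grid <- function() seq(0, 1600000, by = 10000)

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo uncertainty analysis: each iteration draws a parameter set
#' via [draw_psa_parameters()], runs the lifetime model for every strategy
#' and records discounted cost and QALYs.  From the draws it derives the
#' cost-effectiveness plane (incrementals against the reference) and the
#' cost-effectiveness acceptability curve: at each willingness-to-pay value
#' the probability that each strategy has the highest net monetary benefit
#' \eqn{\lambda \cdot QALY - cost}, ties broken toward the cheaper
#' strategy.
#'
#' @param params A `"cua_params"` object with uncertainty metadata.
#' @param iterations Number of Monte-Carlo iterations (default 1000).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param wtp_grid Willingness-to-pay grid (THB/QALY) for the CEAC.
#' @param reference Reference strategy for the CE plane.
#' @return A `"cua_psa"` object: list with `draws` (iteration, strategy,
#'   cost, ly, qaly), `ceac` (wtp, strategy, probability), `plane`
#'   (iteration, strategy, incremental_cost, incremental_qaly), plus the
#'   grid, seed, iteration count and reference.
#' @export
#' @examples
#' \donttest{
#' psa <- run_psa(fixture_parameters(), iterations = 50, seed = 1)
#' dplyr::filter(psa$ceac, wtp == 160000)
#' }
run_psa <- function(params, iterations = 1000, seed = 1,
                    wtp_grid = default_wtp_grid(), reference = "CAPD") {
  if (iterations < 1) abort("`iterations` must be >= 1")
  assert_strategy(reference)
  set.seed(seed)

  draws <- map_dfr(seq_len(iterations), function(i) {
    dp <- draw_psa_once(params)
    strategy_totals(dp) %>%
      mutate(iteration = i) %>%
      select("iteration", "strategy", "cost", "ly", "qaly")
  })

  strat <- strategy_names()
  cost_m <- matrix(draws$cost[order(draws$iteration,
                                    match(draws$strategy, strat))],
                   ncol = length(strat), byrow = TRUE,
                   dimnames = list(NULL, strat))
  qaly_m <- matrix(draws$qaly[order(draws$iteration,
                                    match(draws$strategy, strat))],
                   ncol = length(strat), byrow = TRUE,
                   dimnames = list(NULL, strat))

  ceac <- map_dfr(wtp_grid, function(lambda) {
    nmb <- lambda * qaly_m - cost_m
    winner <- vapply(seq_len(nrow(nmb)), function(i) {
      cand <- which(nmb[i, ] == max(nmb[i, ]))
      cand[which.min(cost_m[i, cand])]
    }, integer(1))
    tibble(wtp = lambda, strategy = strat,
           probability = tabulate(winner, nbins = length(strat)) /
             iterations)
  })

  ref_cost <- cost_m[, reference]
  ref_qaly <- qaly_m[, reference]
  plane <- draws %>%
    filter(.data$strategy != reference) %>%
    mutate(incremental_cost = .data$cost - ref_cost[.data$iteration],
           incremental_qaly = .data$qaly - ref_qaly[.data$iteration]) %>%
    select("iteration", "strategy", "incremental_cost", "incremental_qaly")

  structure(
    list(draws = draws, ceac = ceac, plane = plane, wtp_grid = wtp_grid,
         iterations = iterations, seed = seed, reference = reference),
    class = "cua_psa"
  )
}

#' @export
print.cua_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %s), reference %s\n",
              x$iterations, format(x$seed), x$reference))
  at <- x$ceac[x$ceac$wtp == 160000, ]
  if (nrow(at) > 0) {
    cat("CEAC at WTP 160,000 THB/QALY:\n")
    print(as.data.frame(at), row.names = FALSE)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Scenario analyses

#' Scenario: inflate long-term mortality
#'
#' Multiplies the steady-state (year 4+) death probability of every alive
#' state by `1 + f`, capped at 1, rescaling the remaining destinations
#' proportionally, then recomputes the full cost-utility analysis.  `f = 0`
#' reproduces the base case exactly.
#'
#' @param params A `"cua_params"` object.
#' @param f Mortality inflation fraction in \[0, 1\] (0% to 100%).
#' @param reference Reference strategy for the CUA table.
#' @return A `"cua_result"` with attribute `mortality_inflation = f`.
#' @export
#' @examples
#' scenario_mortality_inflation(fixture_parameters(), 0.5)
scenario_mortality_inflation <- function(params, f, reference = "CAPD") {
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1) {
    abort("`f` must be a single fraction in [0, 1]")
  }
  tr <- params$transitions
  steady <- tr$year == STEADY_YEAR & tr$from != "DEATH"
  groups <- unique(tr[steady, c("strategy", "from")])
  for (i in seq_len(nrow(groups))) {
    j <- which(steady & tr$strategy == groups$strategy[i] &
                 tr$from == groups$from[i])
    jd <- j[tr$to[j] == "DEATH"]
    jo <- setdiff(j, jd)
    d_old <- if (length(jd) == 1) tr$value[jd] else 0
    d_new <- min(1, d_old * (1 + f))
    if (length(jd) == 1) tr$value[jd] <- d_new
    if (d_old < 1) {
      # ratio first: at f = 0 it is exactly 1 and the base case is untouched
      tr$value[jo] <- tr$value[jo] * ((1 - d_new) / (1 - d_old))
    } else {
      tr$value[jo] <- 0
    }
  }
  out <- params
  out$transitions <- tr
  out$steady_derived <- FALSE
  res <- run_cua(out, reference = reference)
  attr(res, "mortality_inflation") <- f
  res
}

#' Scenario: external mortality and utility inputs
#'
#' Re-runs the cost-utility analysis with replacement inputs from an
#' external source (e.g. a comparable regional setting): age-specific
#' annual death probabilities override the model's transition mortality at
#' the cycles the ages map to (via the starting age), and replacement
#' utilities override matching rows of the utility table.  Everything else
#' stays at base case.
#'
#' @param params A `"cua_params"` object.
#' @param replacement_mortality Optional tibble (`strategy` optional,
#'   `age`, `value`) of annual death probabilities by age.
#' @param replacement_utility Optional tibble (`strategy`, `state`, `year`,
#'   `value`) overriding matching utility rows.
#' @param reference Reference strategy for the CUA table.
#' @return A `"cua_result"`.
#' @export
#' @examples
#' p <- fixture_parameters()
#' scenario_external_inputs(p, replacement_utility = p$utilities)
scenario_external_inputs <- function(params, replacement_mortality = NULL,
                                     replacement_utility = NULL,
                                     reference = "CAPD") {
  out <- params
  if (!is.null(replacement_utility)) {
    ru <- as_tibble(replacement_utility)
    if (any(ru$value < -1 | ru$value > 1)) {
      abort("replacement utilities must lie in [-1, 1]")
    }
    u <- out$utilities
    key <- paste(u$strategy, u$state, u$year)
    rkey <- paste(ru$strategy, ru$state, ru$year)
    hit <- match(rkey, key)
    if (anyNA(hit)) {
      abort(paste0("replacement utility rows match no base row: ",
                   paste(head(rkey[is.na(hit)], 3), collapse = "; ")))
    }
    u$value[hit] <- ru$value
    out$utilities <- u
  }
  if (!is.null(replacement_mortality)) {
    rm_ <- as_tibble(replacement_mortality)
    if (any(rm_$value < 0 | rm_$value > 1)) {
      abort("replacement mortality probabilities must lie in [0, 1]")
    }
  }
  run_cua(out, reference = reference,
          death_override = replacement_mortality)
}
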
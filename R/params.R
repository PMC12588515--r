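# Parameter registry: transition schedules, cost and utility tables,
# uncertainty metadata and economic settings, with validation.
#
# Tables are plain tibbles in long format so they round-trip through CSV:
#   transitions: strategy, year (1,2,3; 4 = steady state), from, to, value,
#                provenance
#   costs:       strategy, state, year (1..3), component, value,
#                informal_care, provenance
#   utilities:   strategy, state, year (1..3), value, provenance
#   uncertainty: id, target, strategy, state, from, to, year, component,
#                family, mean, se, low, high
# Years beyond 3 resolve to the steady transition row and to the year-3
# cost/utility values.

STEADY_YEAR <- 4L

#' Assemble a model parameter set
#'
#' Bundles the per-strategy transition schedules, cost and utility tables,
#' per-parameter uncertainty metadata, economic settings and the structural
#' transition mask into a single validated object consumed by
#' [run_cohort()], [run_cua()] and the sensitivity-analysis functions.
#'
#' If `transitions` carries no steady-state rows (`year == 4`), they are
#' derived from years 1-3: the steady annual death probability is the mean of
#' the three observed annual death probabilities, all other destinations are
#' held at their year-3 values and rescaled over the non-death mass so the
#' row still sums to 1.
#'
#' @param transitions Tibble with columns `strategy`, `year` (1, 2, 3, and
#'   optionally 4 for the steady state), `from`, `to`, `value`, and
#'   optionally `provenance`.  Zero entries may be omitted.
#' @param costs Tibble with columns `strategy`, `state`, `year` (1-3),
#'   `component`, `value` (THB/yr, 2023 prices), and optionally
#'   `informal_care` (logical flag marking components valued by the
#'   human-capital method) and `provenance`.
#' @param utilities Tibble with columns `strategy`, `state`, `year` (1-3),
#'   `value` (EQ-5D-5L utility), and optionally `provenance`.
#' @param settings An [econ_settings()] object.
#' @param uncertainty Optional tibble of per-parameter uncertainty metadata;
#'   defaults to [uncertainty_defaults()] applied to the tables.
#' @param mask Structural transition mask, see [transition_mask()].
#' @param validate If `TRUE` (default) abort when [validate_parameters()]
#'   reports violations.
#' @return An object of class `"cua_params"`.
#' @seealso [fixture_parameters()], [random_parameters()],
#'   [load_parameters()], [write_parameters()]
#' @export
cua_parameters <- function(transitions, costs, utilities,
                           settings = econ_settings(),
                           uncertainty = NULL,
                           mask = transition_mask(),
                           validate = TRUE) {
  transitions <- as_tibble(transitions)
  costs <- as_tibble(costs)
  utilities <- as_tibble(utilities)
  if (!"provenance" %in% names(transitions)) {
    transitions$provenance <- "unstated"
  }
  if (!"provenance" %in% names(costs)) costs$provenance <- "unstated"
  if (!"informal_care" %in% names(costs)) costs$informal_care <- FALSE
  if (!"provenance" %in% names(utilities)) utilities$provenance <- "unstated"
  transitions$year <- as.integer(transitions$year)
  costs$year <- as.integer(costs$year)
  utilities$year <- as.integer(utilities$year)

  steady_derived <- !any(transitions$year == STEADY_YEAR)
  p <- structure(
    list(transitions = transitions, costs = costs, utilities = utilities,
         uncertainty = uncertainty, settings = settings, mask = mask,
         steady_derived = steady_derived),
    class = "cua_params"
  )
  if (steady_derived) p <- rebuild_steady(p)
  if (is.null(uncertainty)) p$uncertainty <- uncertainty_defaults(p)
  if (validate) {
    v <- validate_parameters(p)
    if (nrow(v) > 0) {
      abort(paste0("invalid parameter set:\n  ",
                   paste(head(v$message, 10), collapse = "\n  ")))
    }
  }
  p
}

#' @export
print.cua_params <- function(x, ...) {
  strat <- unique(x$transitions$strategy)
  cat("<cua_params>\n")
  cat("  strategies:", paste(strat, collapse = ", "), "\n")
  cat("  states:    ", paste(health_states(), collapse = ", "), "\n")
  cat(sprintf("  transitions: %d entries (steady state %s)\n",
              nrow(x$transitions),
              if (isTRUE(x$steady_derived)) "derived from years 1-3"
              else "supplied"))
  cat(sprintf("  costs: %d rows; utilities: %d rows; uncertainty: %d rows\n",
              nrow(x$costs), nrow(x$utilities),
              if (is.null(x$uncertainty)) 0L else nrow(x$uncertainty)))
  print(x$settings)
  invisible(x)
}

# Dense 6 x 6 x 4 transition array for one strategy (years 1-3 + steady).
transition_array <- function(params, strategy) {
  s <- health_states()
  tr <- params$transitions[params$transitions$strategy == strategy, ]
  arr <- array(0, dim = c(6, 6, 4),
               dimnames = list(from = s, to = s,
                               year = c("1", "2", "3", "steady")))
  arr[cbind(match(tr$from, s), match(tr$to, s),
            pmin(tr$year, STEADY_YEAR))] <- tr$value
  arr
}

# Steady-state rule: death probability is the mean of the years 1-3 annual
# death probabilities; every other destination keeps its year-3 value,
# rescaled over the non-death mass so the row sums to 1 again.
# Base-R on dense arrays: this sits on the hot path of the one-way and
# probabilistic sensitivity analyses.
derive_steady_rows <- function(transitions) {
  s <- health_states()
  out <- vector("list", 0)
  for (strat in unique(transitions$strategy)) {
    tr <- transitions[transitions$strategy == strat &
                        transitions$year %in% 1:3, ]
    arr <- array(0, dim = c(6, 6, 3))
    arr[cbind(match(tr$from, s), match(tr$to, s), tr$year)] <- tr$value
    P3 <- arr[, , 3]
    d_star <- (arr[, 6, 1] + arr[, 6, 2] + arr[, 6, 3]) / 3
    d3 <- P3[, 6]
    steady <- P3
    scale <- ifelse(d3 < 1, (1 - d_star) / (1 - d3), 0)
    steady[, -6] <- P3[, -6] * scale
    steady[, 6] <- d_star
    # a year-3 row with no survivors leaves nothing to rescale: the
    # steady-state survival mass (1 - d_star) stays in place
    for (i in which(d3 >= 1 & d_star < 1)) steady[i, i] <- 1 - d_star[i]
    steady[6, ] <- c(0, 0, 0, 0, 0, 1)
    nz <- which(steady != 0, arr.ind = TRUE)
    out[[length(out) + 1]] <- tibble(
      strategy = strat, year = STEADY_YEAR,
      from = s[nz[, 1]], to = s[nz[, 2]],
      value = steady[nz], provenance = "derived"
    )
  }
  bind_rows(out)
}

rebuild_steady <- function(params) {
  keep <- params$transitions[params$transitions$year != STEADY_YEAR, ]
  params$transitions <- bind_rows(keep, derive_steady_rows(keep))
  params$steady_derived <- TRUE
  params
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and returns the
#' violations as data rather than raising: each transition row must sum to 1
#' (within 1e-9) with entries in \[0, 1\]; death must be absorbing; entries
#' forbidden by the structural mask must be exactly zero; costs must be
#' non-negative; utilities must lie in \[-1, 1\] with the death state at 0;
#' uncertainty metadata must have feasible means and ordered bounds; and the
#' economic settings must be internally consistent.
#'
#' @param params A `"cua_params"` object (no validity assumed).
#' @return A tibble with columns `parameter`, `rule`, `value`, `message`;
#'   zero rows if and only if every invariant holds.
#' @export
#' @examples
#' validate_parameters(fixture_parameters())
validate_parameters <- function(params) {
  v <- list()
  add <- function(parameter, rule, value) {
    v[[length(v) + 1]] <<- tibble(
      parameter = parameter, rule = rule, value = value,
      message = sprintf("%s: %s (observed %.6g)", parameter, rule, value)
    )
  }
  s <- health_states()
  tr <- params$transitions

  dup <- tr %>%
    dplyr::count(.data$strategy, .data$year, .data$from, .data$to) %>%
    filter(.data$n > 1)
  for (i in seq_len(nrow(dup))) {
    add(sprintf("transition %s y%d %s->%s", dup$strategy[i], dup$year[i],
                dup$from[i], dup$to[i]),
        "duplicate entry", dup$n[i])
  }

  bad_state <- tr %>% filter(!(.data$from %in% s) | !(.data$to %in% s))
  for (i in seq_len(nrow(bad_state))) {
    add(sprintf("transition %s y%d %s->%s", bad_state$strategy[i],
                bad_state$year[i], bad_state$from[i], bad_state$to[i]),
        "unknown health state", NA_real_)
  }

  rng <- tr %>% filter(.data$value < 0 | .data$value > 1)
  for (i in seq_len(nrow(rng))) {
    add(sprintf("transition %s y%d %s->%s", rng$strategy[i], rng$year[i],
                rng$from[i], rng$to[i]),
        "probability outside [0, 1]", rng$value[i])
  }

  for (strat in unique(tr$strategy)) {
    arr <- transition_array(params, strat)
    for (y in 1:4) {
      P <- arr[, , y]
      rs <- rowSums(P)
      for (f in s) {
        if (abs(rs[f] - 1) > 1e-9) {
          add(sprintf("transition %s y%d row %s", strat, y, f),
              "row sum must equal 1", rs[f])
        }
      }
      if (any(P["DEATH", ] != c(0, 0, 0, 0, 0, 1))) {
        add(sprintf("transition %s y%d row DEATH", strat, y),
            "absorbing state: DEATH row must be the unit vector on DEATH",
            P["DEATH", "DEATH"])
      }
      forb <- which(!params$mask & P != 0, arr.ind = TRUE)
      for (k in seq_len(nrow(forb))) {
        add(sprintf("transition %s y%d %s->%s", strat, y,
                    s[forb[k, 1]], s[forb[k, 2]]),
            "forbidden by transition mask (must be exactly 0)",
            P[forb[k, 1], forb[k, 2]])
      }
    }
  }

  bad_cost <- params$costs %>% filter(.data$value < 0)
  for (i in seq_len(nrow(bad_cost))) {
    add(sprintf("cost %s %s y%d %s", bad_cost$strategy[i], bad_cost$state[i],
                bad_cost$year[i], bad_cost$component[i]),
        "cost must be >= 0", bad_cost$value[i])
  }

  bad_u <- params$utilities %>% filter(.data$value < -1 | .data$value > 1)
  for (i in seq_len(nrow(bad_u))) {
    add(sprintf("utility %s %s y%d", bad_u$strategy[i], bad_u$state[i],
                bad_u$year[i]),
        "utility bound: value must lie in [-1, 1]", bad_u$value[i])
  }
  dead_u <- params$utilities %>%
    filter(.data$state == "DEATH", .data$value != 0)
  for (i in seq_len(nrow(dead_u))) {
    add(sprintf("utility %s DEATH y%d", dead_u$strategy[i], dead_u$year[i]),
        "DEATH utility must be 0", dead_u$value[i])
  }

  un <- params$uncertainty
  if (!is.null(un) && nrow(un) > 0) {
    bad_beta <- un %>%
      filter(.data$family == "beta",
             .data$mean < 0 | .data$mean > 1 |
               (.data$se > 0 & (.data$mean <= 0 | .data$mean >= 1)))
    for (i in seq_len(nrow(bad_beta))) {
      add(un_id(bad_beta[i, ]), "beta mean must lie in (0, 1)",
          bad_beta$mean[i])
    }
    bad_gamma <- un %>% filter(.data$family == "gamma", .data$mean < 0)
    for (i in seq_len(nrow(bad_gamma))) {
      add(un_id(bad_gamma[i, ]), "gamma mean must be >= 0", bad_gamma$mean[i])
    }
    bad_ord <- un %>% filter(.data$low > .data$mean | .data$mean > .data$high)
    for (i in seq_len(nrow(bad_ord))) {
      add(un_id(bad_ord[i, ]), "bounds must satisfy low <= mean <= high",
          bad_ord$mean[i])
    }
  }

  bind_rows(c(v, list(settings_violations(params$settings))))
}

un_id <- function(row) row$id[1]

# ---------------------------------------------------------------------------
# Point modification used by one-way sensitivity analysis: set one scalar
# parameter identified by a row of the uncertainty table.

# For a transition entry the remaining destinations in the row are rescaled
# proportionally so the row still sums to 1; values outside [0, 1] are
# clipped to the feasible boundary with a note.  Modifying a year 1-3 entry
# re-derives the steady-state rows.
set_parameter <- function(params, meta, value) {
  stopifnot(nrow(meta) == 1)
  if (meta$target == "cost") {
    value <- clip_note(value, 0, Inf, meta$id)
    i <- which(params$costs$strategy == meta$strategy &
                 params$costs$state == meta$state &
                 params$costs$year == meta$year &
                 params$costs$component == meta$component)
    params$costs$value[i] <- value
  } else if (meta$target == "utility") {
    value <- clip_note(value, -1, 1, meta$id)
    i <- which(params$utilities$strategy == meta$strategy &
                 params$utilities$state == meta$state &
                 params$utilities$year == meta$year)
    params$utilities$value[i] <- value
  } else if (meta$target == "transition") {
    value <- clip_note(value, 0, 1, meta$id)
    params <- set_transition(params, meta$strategy, meta$year,
                             meta$from, meta$to, value)
  } else {
    abort(paste0("unknown parameter target: ", meta$target))
  }
  params
}

clip_note <- function(value, lo, hi, id) {
  out <- min(max(value, lo), hi)
  if (out != value) {
    inform(sprintf("parameter %s: %.6g clipped to feasible value %.6g",
                   id, value, out))
  }
  out
}

set_transition <- function(params, strategy, year, from, to, value) {
  tr <- params$transitions
  in_row <- tr$strategy == strategy & tr$year == year & tr$from == from
  i_target <- which(in_row & tr$to == to)
  i_other <- which(in_row & tr$to != to)
  old <- if (length(i_target) == 1) tr$value[i_target] else 0
  rest <- sum(tr$value[i_other])

  if (length(i_target) == 0) {
    tr <- bind_rows(tr, tibble(strategy = strategy, year = as.integer(year),
                               from = from, to = to, value = value,
                               provenance = "modified"))
  } else {
    tr$value[i_target] <- value
  }
  if (rest > 0) {
    tr$value[i_other] <- tr$value[i_other] * (1 - value) / rest
  } else if (value < 1) {
    # row had full mass on the target: park the residual on staying put
    i_stay <- which(in_row & tr$to == from)
    if (length(i_stay) == 0) {
      tr <- bind_rows(tr, tibble(strategy = strategy,
                                 year = as.integer(year), from = from,
                                 to = from, value = 1 - value,
                                 provenance = "modified"))
    } else {
      tr$value[i_stay] <- 1 - value
    }
  }
  params$transitions <- tr
  if (isTRUE(params$steady_derived) && year %in% 1:3) {
    params <- rebuild_steady(params)
  }
  params
}
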
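# Small hand-built parameter sets used across the tests.

# Parameter set whose years 1-3 all use the same 6 x 6 matrix P (the steady
# state derived from them is then P itself for constant hazards).  Costs and
# utilities are flat across alive states and years.
toy_matrix_params <- function(P, cost = 0, utility = 1,
                              settings = econ_settings()) {
  s <- health_states()
  rows <- list()
  for (arm in strategy_names()) {
    for (y in 1:3) {
      nz <- which(P != 0, arr.ind = TRUE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        strategy = arm, year = y, from = s[nz[, 1]], to = s[nz[, 2]],
        value = P[nz], provenance = "toy"
      )
    }
  }
  grid <- tidyr::expand_grid(strategy = strategy_names(),
                             state = setdiff(s, "DEATH"), year = 1:3)
  costs <- dplyr::mutate(grid, component = "medical", value = cost,
                         informal_care = FALSE, provenance = "toy")
  utilities <- dplyr::mutate(grid, value = utility, provenance = "toy")
  cua_parameters(rows |> dplyr::bind_rows(), costs, utilities,
                 settings = settings)
}

# Constant-hazard matrix: every alive state dies with probability p and
# otherwise stays put.
constant_death_matrix <- function(p) {
  s <- health_states()
  P <- matrix(0, 6, 6, dimnames = list(s, s))
  for (a in setdiff(s, "DEATH")) {
    P[a, "DEATH"] <- p
    P[a, a] <- 1 - p
  }
  P["DEATH", "DEATH"] <- 1
  P
}

# Independent cohort bookkeeping: explicit loops over source and destination
# states, no matrix algebra.  Oracle for the engine.
naive_trace <- function(params, strategy) {
  s <- health_states()
  occ <- setNames(rep(0, 6), s)
  occ[strategy] <- 1
  out <- list(occ)
  n <- params$settings$max_age - params$settings$start_age
  for (t in seq_len(n)) {
    P <- transition_matrix(params, strategy, t - 1)
    nxt <- setNames(rep(0, 6), s)
    for (from in s) {
      for (to in s) {
        nxt[to] <- nxt[to] + occ[from] * P[from, to]
      }
    }
    occ <- nxt
    out[[t + 1]] <- occ
    if (sum(occ[setdiff(s, "DEATH")]) < 1e-9) break
  }
  do.call(rbind, out)
}

# The trial-reported annual probabilities the fixture must embed verbatim.
printed_probs <- function() {
  list(
    death = list(CAPD = c(0.1667, 0.2449, 0.2424),
                 CAPD_ICO = c(0.1167, 0.1633, 0.1212)),
    hd_transfer = list(CAPD = c(0.0167, 0.0408, 0.1515),
                       CAPD_ICO = c(0.0500, 0.1020, 0.2424))
  )
}

# Published per-strategy discounted lifetime totals (cost THB, LY, QALY).
published_totals <- function() {
  tibble::tibble(
    strategy = c("CAPD", "CAPD_ICO", "APD"),
    cost = c(2487161, 3429977, 2623402),
    ly = c(3.56, 4.92, 3.42),
    qaly = c(2.76, 3.80, 2.54)
  )
}
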
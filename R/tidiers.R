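# broom-style tidiers for the fitted result objects.

#' Tidy a cost-utility result
#'
#' Returns the pairwise comparison table (one row per comparator vs the
#' reference) as a tibble.
#'
#' @param x A `"cua_result"`.
#' @param ... Unused.
#' @return Tibble of incrementals, ICERs and dominance per comparator.
#' @method tidy cua_result
#' @export
tidy.cua_result <- function(x, ...) {
  x$comparisons %>% mutate(reference = x$reference, .before = 1)
}

#' One-row summary of a cost-utility result
#'
#' @param x A `"cua_result"`.
#' @param ... Unused.
#' @return One-row tibble: reference strategy, number of strategies, the
#'   willingness-to-pay threshold, and the strategy with the highest net
#'   monetary benefit at that threshold.
#' @method glance cua_result
#' @export
glance.cua_result <- function(x, ...) {
  nmb <- x$wtp_threshold * x$totals$qaly - x$totals$cost
  tibble(
    reference = x$reference,
    n_strategies = nrow(x$totals),
    wtp_threshold = x$wtp_threshold,
    nmb_best = x$totals$strategy[which.max(nmb)],
    n_dominated = sum(x$comparisons$dominance == "dominated")
  )
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `"cua_psa"`.
#' @param type One of `"ceac"` (default), `"draws"`, `"plane"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @method tidy cua_psa
#' @export
tidy.cua_psa <- function(x, type = c("ceac", "draws", "plane"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x A `"cua_psa"`.
#' @param wtp Willingness-to-pay at which to report the most likely
#'   cost-effective strategy (default 160,000 THB/QALY).
#' @param ... Unused.
#' @return One-row tibble: iterations, seed, reference, and the strategy
#'   with the highest acceptability at `wtp` together with its
#'   probability.
#' @method glance cua_psa
#' @export
glance.cua_psa <- function(x, wtp = 160000, ...) {
  grid_wtp <- x$wtp_grid[which.min(abs(x$wtp_grid - wtp))]
  at <- x$ceac[x$ceac$wtp == grid_wtp, ]
  best <- at[which.max(at$probability), ]
  tibble(
    iterations = x$iterations, seed = x$seed, reference = x$reference,
    wtp = grid_wtp, best_strategy = best$strategy,
    best_probability = best$probability
  )
}

#' Tidy a one-way sensitivity analysis
#'
#' @param x A `"cua_owsa"`.
#' @param ... Unused.
#' @return The tornado table with the base-case ICER as a column.
#' @method tidy cua_owsa
#' @export
tidy.cua_owsa <- function(x, ...) {
  as_tibble(x) %>% mutate(base_icer = attr(x, "base_icer"))
}
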
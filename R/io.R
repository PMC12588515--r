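# Reading and writing parameter sets: one CSV per table plus a JSON config
# holding the economic settings and the structural mask.  All scalars
# round-trip bit-exactly (readr writes shortest round-trip doubles; the
# config is written with full precision).

PARAM_TABLES <- c(transitions = "transitions.csv", costs = "costs.csv",
                  utilities = "utilities.csv",
                  uncertainty = "uncertainty.csv")

#' Write a parameter set to disk
#'
#' Writes `transitions.csv`, `costs.csv`, `utilities.csv` and
#' `uncertainty.csv` (long format, UTF-8, `.` decimal separator) plus
#' `config.json` carrying the economic settings, the allowed-transition
#' mask and whether the steady-state rows were derived.  The written set
#' reloads bit-exactly via [load_parameters()].
#'
#' @param params A `"cua_params"` object.
#' @param dir Directory to write into (created if missing).
#' @return The path to `config.json`, invisibly.
#' @export
write_parameters <- function(params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(PARAM_TABLES)) {
    tab <- params[[nm]]
    # write doubles at 17 significant digits so they reload bit-exactly
    # (strtod on the way back in is correctly rounded)
    for (col in names(tab)) {
      if (is.double(tab[[col]])) {
        tab[[col]] <- ifelse(is.na(tab[[col]]), NA_character_,
                             sprintf("%.17g", tab[[col]]))
      }
    }
    readr::write_csv(tab, file.path(dir, PARAM_TABLES[[nm]]))
  }
  mask <- params$mask
  allowed <- which(mask, arr.ind = TRUE)
  cfg <- list(
    settings = unclass(params$settings),
    mask_allowed = sprintf("%s->%s",
                           rownames(mask)[allowed[, 1]],
                           colnames(mask)[allowed[, 2]]),
    steady_derived = isTRUE(params$steady_derived),
    tables = as.list(PARAM_TABLES)
  )
  cfg$settings$cpi_index <- as.list(cfg$settings$cpi_index)
  path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a parameter set from disk
#'
#' Reads a `config.json` written by [write_parameters()] (or assembled by
#' hand to the same schema) together with the CSV tables it references, and
#' returns a validated parameter set.  A missing table raises an error
#' naming the table; any invariant breach raises a validation error naming
#' the offending parameter and rule.
#'
#' @param config_path Path to the JSON config.
#' @param tables_dir Directory holding the CSV tables; defaults to the
#'   config's own directory.
#' @return A validated `"cua_params"` object.
#' @export
load_parameters <- function(config_path, tables_dir = dirname(config_path)) {
  if (!file.exists(config_path)) {
    abort(paste0("config file not found: ", config_path))
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)

  tables <- cfg$tables %||% as.list(PARAM_TABLES)
  paths <- lapply(tables, function(f) file.path(tables_dir, f))
  for (nm in names(PARAM_TABLES)) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      abort(sprintf("parameter table '%s' (%s) not found in %s",
                    nm, tables[[nm]] %||% PARAM_TABLES[[nm]], tables_dir))
    }
  }

  # double columns arrive as text and go through strtod for exactness
  col_specs <- list(
    transitions = readr::cols(strategy = "c", year = "i", from = "c",
                              to = "c", value = "c", provenance = "c"),
    costs = readr::cols(strategy = "c", state = "c", year = "i",
                        component = "c", value = "c", informal_care = "l",
                        provenance = "c"),
    utilities = readr::cols(strategy = "c", state = "c", year = "i",
                            value = "c", provenance = "c"),
    uncertainty = readr::cols(id = "c", target = "c", strategy = "c",
                              state = "c", from = "c", to = "c", year = "i",
                              component = "c", family = "c", mean = "c",
                              se = "c", low = "c", high = "c")
  )
  dbl_cols <- list(transitions = "value", costs = "value",
                   utilities = "value",
                   uncertainty = c("mean", "se", "low", "high"))
  tab <- lapply(names(PARAM_TABLES), function(nm) {
    t <- readr::read_csv(paths[[nm]], col_types = col_specs[[nm]],
                         progress = FALSE)
    for (col in dbl_cols[[nm]]) t[[col]] <- as.numeric(t[[col]])
    attr(t, "spec") <- NULL
    attr(t, "problems") <- NULL
    class(t) <- c("tbl_df", "tbl", "data.frame")
    t
  })
  names(tab) <- names(PARAM_TABLES)

  st <- cfg$settings
  settings <- econ_settings(
    discount_rate = st$discount_rate,
    wtp_threshold = st$wtp_threshold,
    exchange_rate = st$exchange_rate,
    cost_to_charge_ratio = st$cost_to_charge_ratio,
    charge_direction = st$charge_direction %||% "charge_over_cost",
    start_age = st$start_age,
    max_age = st$max_age,
    cycle_length = st$cycle_length %||% 1,
    gni_per_capita = st$gni_per_capita,
    cpi_index = unlist(st$cpi_index),
    psa_row_n = st$psa_row_n %||% 60
  )

  mask <- matrix(FALSE, 6, 6,
                 dimnames = list(from = health_states(),
                                 to = health_states()))
  if (!is.null(cfg$mask_allowed)) {
    pairs <- strsplit(cfg$mask_allowed, "->", fixed = TRUE)
    for (pr in pairs) mask[pr[1], pr[2]] <- TRUE
  } else {
    mask <- transition_mask()
  }

  p <- cua_parameters(tab$transitions, tab$costs, tab$utilities,
                      settings = settings, uncertainty = tab$uncertainty,
                      mask = mask, validate = TRUE)
  p$steady_derived <- isTRUE(cfg$steady_derived)
  p
}
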
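# State space and structural transition mask for the six-state dialysis model.

#' Health states of the dialysis cohort model
#'
#' The model follows a cohort of end-stage renal disease patients through six
#' mutually exclusive health states: three peritoneal dialysis (PD) modalities
#' (glucose-based CAPD, CAPD with one icodextrin exchange, automated PD),
#' in-centre haemodialysis, kidney transplantation, and death.
#'
#' @return Character vector of the six state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("CAPD", "CAPD_ICO", "APD", "HD", "KT", "DEATH")
}

#' Treatment strategies compared by the model
#'
#' Each strategy corresponds to the PD modality a patient is started on; the
#' whole cohort begins in that strategy's own PD state.
#'
#' @return Character vector of the three strategy names.
#' @export
#' @examples
#' strategy_names()
strategy_names <- function() {
  c("CAPD", "CAPD_ICO", "APD")
}

pd_states <- function() c("CAPD", "CAPD_ICO", "APD")

alive_states <- function() setdiff(health_states(), "DEATH")

#' Structural transition mask
#'
#' Logical 6 x 6 matrix marking which annual transitions the model structure
#' permits.  PD patients may switch between PD modalities, transfer
#' permanently to haemodialysis, receive a transplant, or die; haemodialysis
#' patients may stay, receive a transplant, or die; transplanted patients may
#' only stay or die; death is absorbing.  Temporary transfers (e.g. a short
#' haemodialysis spell during peritonitis with return to PD) are not
#' represented, so no transition re-enters a PD state from HD or KT.
#'
#' @param allow_pd_switch Logical; if `FALSE`, transitions between different
#'   PD modalities are forbidden (each arm may only leave PD for HD, KT or
#'   death).  Default `TRUE`.
#' @return A 6 x 6 logical matrix with state labels on both dimensions.
#' @export
#' @examples
#' transition_mask()["KT", ]
transition_mask <- function(allow_pd_switch = TRUE) {
  s <- health_states()
  m <- matrix(FALSE, 6, 6, dimnames = list(from = s, to = s))
  for (p in pd_states()) {
    m[p, pd_states()] <- if (allow_pd_switch) TRUE else FALSE
    m[p, p] <- TRUE
    m[p, c("HD", "KT", "DEATH")] <- TRUE
  }
  m["HD", c("HD", "KT", "DEATH")] <- TRUE
  m["KT", c("KT", "DEATH")] <- TRUE
  m["DEATH", "DEATH"] <- TRUE
  m
}

assert_strategy <- function(strategy) {
  if (!(is.character(strategy) && length(strategy) == 1 &&
        strategy %in% strategy_names())) {
    abort(paste0("`strategy` must be one of ",
                 paste(strategy_names(), collapse = ", ")))
  }
  strategy
}
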
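# State-space constants shared by every module.

#' Alive health states of the CKD model
#'
#' Eight alive states: CKD stages 1/2, 3, 4, stage 5 without renal
#' replacement therapy, and acute/post-acute dialysis and kidney transplant.
#' Death is handled separately as the absorbing state of the cohort trace.
#'
#' @return Character vector of the eight alive state codes, in severity order.
#' @export
#' @examples
#' ckd_states()
ckd_states <- function() {
  c("ckd12", "ckd3", "ckd4", "ckd5", "dial_acute", "dial_post",
    "tx_acute", "tx_post")
}

#' Human-readable labels for the alive states
#' @return Named character vector mapping state codes to display labels.
#' @export
ckd_state_labels <- function() {
  c(ckd12 = "CKD 1/2", ckd3 = "CKD 3", ckd4 = "CKD 4",
    ckd5 = "CKD 5 without RRT",
    dial_acute = "Dialysis (acute)", dial_post = "Dialysis (post-acute)",
    tx_acute = "Kidney transplant (acute)",
    tx_post = "Kidney transplant (post-acute)")
}

#' Treatment strategies
#' @return Character vector of strategy codes: standard of care,
#'   finerenone + SoC, SGLT2i + SoC and triple therapy.
#' @export
ckd_strategies <- function() {
  c("soc", "finerenone", "sglt2i", "triple")
}

# Composite cardiovascular event types (myocardial infarction, ischemic
# stroke, hemorrhagic stroke, hospitalization for heart failure).
cv_event_types <- function() c("mi", "is", "hs", "hf")

# Disutility groups: both stroke types share one decrement.
cv_disutility_groups <- function() c("mi", "stroke", "hf")
cv_event_to_disutility_group <- function() {
  c(mi = "mi", is = "stroke", hs = "stroke", hf = "hf")
}

# Mortality risk groups: dialysis states share one risk, transplant states
# share another.
death_groups <- function() c("ckd12", "ckd3", "ckd4", "ckd5", "dialysis",
                             "transplant")
state_to_death_group <- function() {
  c(ckd12 = "ckd12", ckd3 = "ckd3", ckd4 = "ckd4", ckd5 = "ckd5",
    dial_acute = "dialysis", dial_post = "dialysis",
    tx_acute = "transplant", tx_post = "transplant")
}

# Adverse event types tracked per cycle.
ae_types <- function() c("hyperkalemia", "aki", "discontinuation")

# Pre-RRT states: intervention drug costs stop beyond these by default.
pre_rrt_states <- function() c("ckd12", "ckd3", "ckd4", "ckd5")

# Tunnel states: occupied for exactly one cycle.
tunnel_states <- function() c("dial_acute", "tx_acute")
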
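# Probability/rate conversion and construction of strategy-specific
# transition matrices and event risks from the standard-of-care values and
# relative treatment effects.

#' Convert a probability over a period to an instantaneous annual rate
#'
#' `r = -ln(1 - P) / t`, the standard constant-rate conversion used to move
#' between trial-reported probabilities and model-cycle probabilities.
#'
#' @param p Probability of the event over the period, in `[0, 1)`.
#' @param t Period length in years (default 1).
#' @return Instantaneous rate per year.
#' @export
#' @examples
#' prob_to_rate(0.30)          # -log(0.7)
#' rate_to_prob(prob_to_rate(0.30), 1)  # 0.30
prob_to_rate <- function(p, t = 1) {
  if (any(p < 0) || any(p >= 1)) {
    stop("`p` must lie in [0, 1)", call. = FALSE)
  }
  if (any(t <= 0)) stop("`t` must be > 0", call. = FALSE)
  -log(1 - p) / t
}

#' Convert an instantaneous annual rate to a probability over a period
#'
#' `P = 1 - exp(-r * t)`; exact inverse of [prob_to_rate()].
#'
#' @param r Instantaneous rate per year, non-negative.
#' @param t Period length in years.
#' @return Probability over the period.
#' @export
rate_to_prob <- function(r, t = 1) {
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be > 0", call. = FALSE)
  1 - exp(-r * t)
}

#' Apply a hazard (rate) ratio to a per-cycle probability
#'
#' Ratios act on the rate scale: `p' = 1 - (1 - p)^ratio`, equivalent to
#' multiplying the underlying constant rate by `ratio` and converting back.
#' This keeps the result a probability for any positive ratio, unlike direct
#' multiplication.
#'
#' @param p Per-cycle probability in `[0, 1)`.
#' @param ratio Hazard or rate ratio (> 0, or 0 for the null-risk limit).
#' @return Adjusted per-cycle probability.
#' @export
#' @examples
#' apply_ratio_to_prob(0.0095, 0.57)  # triple-therapy first-CV adjustment
apply_ratio_to_prob <- function(p, ratio) {
  if (any(p < 0) || any(p >= 1)) stop("`p` must lie in [0, 1)", call. = FALSE)
  if (any(ratio < 0)) stop("`ratio` must be >= 0", call. = FALSE)
  1 - (1 - p)^ratio
}

# Transitions scaled by the relative chronic eGFR-decline rate: progression
# among CKD stages 1-4.
progression_edges <- function() {
  list(c("ckd12", "ckd3"), c("ckd12", "ckd4"), c("ckd3", "ckd4"))
}

# Transitions scaled by the renal-composite-outcome HR: entries into late-
# stage renal events (CKD 5 without RRT, dialysis, transplant) from CKD 3-5.
late_stage_edges <- function() {
  from <- c("ckd3", "ckd4", "ckd5")
  to <- c("ckd5", "dial_acute", "tx_acute")
  out <- list()
  for (f in from) for (d in to) if (f != d) out[[length(out) + 1L]] <- c(f, d)
  out
}

# Shared worker: rate-scale each listed off-diagonal edge, then let the
# diagonal absorb the difference so rows re-sum to 1.
scale_edges <- function(m, edges, ratio) {
  if (isTRUE(all.equal(ratio, 1))) return(m)
  touched <- unique(vapply(edges, `[[`, "", 1L))
  for (e in edges) {
    m[e[1L], e[2L]] <- apply_ratio_to_prob(m[e[1L], e[2L]], ratio)
  }
  for (f in touched) {
    others <- sum(m[f, ]) - m[f, f]
    stay <- 1 - others
    if (stay < -1e-12) {
      stop("infeasible transition matrix: adjusted row `", f,
           "` leaves a negative stay probability", call. = FALSE)
    }
    m[f, f] <- max(stay, 0)
  }
  m
}

#' Scale CKD-stage progression by a relative eGFR-decline rate
#'
#' Applies [apply_ratio_to_prob()] with `rel_decline` to every progression
#' transition among CKD stages 1/2-4 (1/2 to 3, 1/2 to 4, 3 to 4). Regression
#' transitions are left unchanged and the stay probability absorbs the
#' difference, so rows remain stochastic.
#'
#' @param m 8x8 alive-state transition matrix.
#' @param rel_decline Ratio of the strategy's chronic eGFR-decline slope to
#'   the standard-of-care slope (> 0; 1 leaves the matrix unchanged).
#' @return Adjusted transition matrix.
#' @export
scale_progression <- function(m, rel_decline) {
  if (rel_decline <= 0) stop("`rel_decline` must be > 0", call. = FALSE)
  scale_edges(m, progression_edges(), rel_decline)
}

#' Scale late-stage renal transitions by a renal-composite hazard ratio
#'
#' Applies [apply_ratio_to_prob()] with `hr_renal` to every entry into CKD 5
#' without RRT, acute dialysis or acute transplant from the CKD 3, CKD 4 and
#' CKD 5 rows. Tunnel rows are untouched.
#'
#' @param m 8x8 alive-state transition matrix.
#' @param hr_renal Hazard ratio for the composite kidney outcome (> 0).
#' @return Adjusted transition matrix.
#' @export
scale_late_stage <- function(m, hr_renal) {
  if (hr_renal <= 0) stop("`hr_renal` must be > 0", call. = FALSE)
  scale_edges(m, late_stage_edges(), hr_renal)
}

#' Build the strategy-specific model inputs
#'
#' Derives a strategy's transition matrix and per-cycle event and death risks
#' from the standard-of-care values: CKD-stage progression is scaled by the
#' strategy's relative eGFR-decline rate, late-stage renal transitions by its
#' renal-composite HR, and first-CV and all-cause-death probabilities by the
#' corresponding HRs — all on the rate scale. The SoC strategy returns the
#' inputs unchanged.
#'
#' @param ps A `ckd_params` object.
#' @param strategy One of `"soc"`, `"finerenone"`, `"sglt2i"`, `"triple"`.
#' @return A list of class `ckd_strategy` with elements `strategy`, `matrix`,
#'   `first_cv`, `subsequent_cv`, `death` (per alive state), `ae`, and the
#'   per-cycle drug cost.
#' @export
#' @examples
#' ps <- reference_parameters(quiet = TRUE)
#' sm <- build_strategy_model(ps, "triple")
#' sm$death[["ckd3"]]  # 1 - (1 - 0.0058)^0.46
build_strategy_model <- function(ps, strategy) {
  strategy <- match.arg(strategy, ckd_strategies())
  eff <- ps$effects[strategy, ]
  m <- scale_late_stage(scale_progression(ps$transition, eff$rel_egfr),
                        eff$hr_renal)
  death8 <- ps$death[state_to_death_group()[ckd_states()]]
  names(death8) <- ckd_states()
  first_cv <- apply_ratio_to_prob(ps$first_cv, eff$hr_first_cv)
  death8 <- apply_ratio_to_prob(death8, eff$hr_mortality)

  drug_states <- ps$costs$drug[["soc"]]  # SoC drug cost, all alive states
  extra <- switch(strategy,
                  soc = 0,
                  finerenone = ps$costs$drug[["finerenone"]],
                  sglt2i = ps$costs$drug[["sglt2i"]],
                  triple = ps$costs$drug[["finerenone"]] +
                           ps$costs$drug[["sglt2i"]])
  structure(
    list(strategy = strategy,
         matrix = m,
         first_cv = first_cv,
         subsequent_cv = ps$subsequent_cv,
         death = death8,
         ae = ps$ae[strategy, ],
         drug_cost_soc = drug_states,
         drug_cost_intervention = extra),
    class = "ckd_strategy")
}
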
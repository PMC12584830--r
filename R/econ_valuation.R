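# Attach discounted costs and QALYs to a cohort trace.

#' Per-cycle discount factor
#'
#' `(1 + annual_rate)^(-cycle_index / cycles_per_year)`: cycle 0 is
#' undiscounted, cycle `cycles_per_year` gets one full year of discounting.
#'
#' @param cycle_index Cycle number (0-based), possibly a vector.
#' @param annual_rate Annual discount rate (default 0.05).
#' @param cycles_per_year Cycles per year (default 3).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(3)   # one year: 1 / 1.05
#' discount_factor(30)  # ten years: 1.05^-10
discount_factor <- function(cycle_index, annual_rate = 0.05,
                            cycles_per_year = 3) {
  stopifnot(all(cycle_index >= 0))
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

#' Composite cardiovascular event economics
#'
#' Collapses the four CV event types (MI, ischemic stroke, hemorrhagic
#' stroke, HF hospitalization) into a single composite event by weighting
#' their acute costs, post-acute per-cycle costs, and acute/post-acute
#' disutilities by the event-mix proportions. Both stroke types share the
#' stroke disutility.
#'
#' @param mix Named weights over `c("mi", "is", "hs", "hf")`, summing to 1.
#' @param costs The `costs` element of a `ckd_params` object.
#' @param utilities The `utilities` element of a `ckd_params` object.
#' @return List with `acute_cost`, `postacute_cost_per_cycle`,
#'   `acute_disutility`, `postacute_disutility`.
#' @export
#' @examples
#' ps <- reference_parameters(quiet = TRUE)
#' composite_cv_economics(c(mi = 1, is = 0, hs = 0, hf = 0),
#'                        ps$costs, ps$utilities)
composite_cv_economics <- function(mix, costs, utilities) {
  if (abs(sum(mix) - 1) > 1e-9) stop("`mix` must sum to 1", call. = FALSE)
  mix <- mix[cv_event_types()]
  grp <- cv_event_to_disutility_group()
  dis_acute <- sum(mix * utilities$disutil_acute[grp])
  dis_post <- sum(mix * utilities$disutil_post[grp])
  list(acute_cost = sum(mix * costs$cv_acute),
       postacute_cost_per_cycle = sum(mix * costs$cv_post),
       acute_disutility = dis_acute,
       postacute_disutility = dis_post)
}

#' Value a cohort trace in costs and QALYs
#'
#' Accrues, per cycle: CKD-state management costs (acute dialysis/transplant
#' compartments carry their one-off cost as the tunnel cycle's cost), drug
#' costs (standard of care in every alive state; finerenone/SGLT2i in
#' pre-RRT states unless `drug_continue_rrt` is set), composite acute CV
#' costs for incident first and subsequent events, post-acute CV costs over
#' established post-CV occupancy, adverse-event costs, and a one-off death
#' cost. QALYs accrue as occupancy times state utility (plus the post-acute
#' CV decrement in the post-CV layer, clamped at 0) times the cycle length,
#' minus an acute decrement for one cycle per incident event. Both streams
#' are discounted with [discount_factor()].
#'
#' State-occupancy accrual uses end-of-cycle occupancy, or the mean of the
#' cycle's start and end occupancy when half-cycle correction is on; incident
#' post-CV cases start paying post-acute costs the cycle after their event.
#'
#' @param trace A `ckd_trace` from [run_model()].
#' @param ps A `ckd_params` object.
#' @param strategy Strategy code; defaults to the trace's strategy.
#' @return A `ckd_valued` tibble, one row per cycle (1..n), with discounted
#'   and undiscounted cost and QALY streams plus cost components.
#' @export
value_trace <- function(trace, ps, strategy = trace$strategy) {
  strategy <- match.arg(strategy, ckd_strategies())
  set <- ps$settings
  cl <- trace$cycle_length_years
  cpy <- round(1 / cl)
  n <- length(trace$new_deaths)
  cvx <- composite_cv_economics(ps$cv_mix, ps$costs, ps$utilities)

  sm_drug <- build_strategy_model(ps, strategy)
  drug_states <- if (set$drug_continue_rrt) ckd_states() else pre_rrt_states()

  s <- ckd_states()
  state_cost <- ps$costs$state[s]
  u_nocv <- ps$utilities$state[s]
  u_postcv <- pmax(u_nocv + cvx$postacute_disutility, 0)

  idx_nocv <- 1:8
  idx_postcv <- 9:16
  drug_mask <- s %in% drug_states

  cost <- qaly <- cost_undisc <- qaly_undisc <- numeric(n)
  comp <- matrix(0, n, 6L, dimnames = list(
    NULL, c("state", "drug", "cv_acute", "cv_post", "ae", "death")))

  for (k in seq_len(n)) {
    occ_end <- trace$occupancy[k + 1L, ]
    occ_start <- trace$occupancy[k, ]
    a_end <- occ_end[idx_nocv]; b_end <- occ_end[idx_postcv]
    if (set$half_cycle_correction) {
      a_use <- (occ_start[idx_nocv] + a_end) / 2
      b_use <- (occ_start[idx_postcv] + b_end) / 2
    } else {
      a_use <- a_end; b_use <- b_end
    }

    c_state <- sum((a_use + b_use) * state_cost)
    alive_use <- sum(a_use + b_use)
    c_drug <- alive_use * sm_drug$drug_cost_soc +
      sum((a_use + b_use)[drug_mask]) * sm_drug$drug_cost_intervention

    events <- trace$new_first_cv[k] + trace$new_subsequent_cv[k]
    c_cv_acute <- events * cvx$acute_cost
    # established post-CV occupancy only: this cycle's incident cases start
    # post-acute accrual next cycle
    b_established <- pmax(sum(b_end) - trace$new_first_cv[k], 0)
    c_cv_post <- b_established * cvx$postacute_cost_per_cycle

    c_ae <- sum(trace$ae[k, ] * ps$costs$ae[ae_types()])
    c_death <- trace$new_deaths[k] * ps$costs$death

    q_state <- (sum(a_use * u_nocv) + sum(b_use * u_postcv)) * cl
    q_acute <- events * cvx$acute_disutility * cl
    q <- max(q_state + q_acute, 0)

    ctot <- c_state + c_drug + c_cv_acute + c_cv_post + c_ae + c_death
    df <- discount_factor(k, set$discount_rate_annual, cpy)
    cost_undisc[k] <- ctot
    qaly_undisc[k] <- q
    cost[k] <- ctot * df
    qaly[k] <- q * df
    comp[k, ] <- c(c_state, c_drug, c_cv_acute, c_cv_post, c_ae, c_death) * df
  }

  out <- tibble::tibble(
    cycle = seq_len(n),
    cost = cost, qaly = qaly,
    cost_undiscounted = cost_undisc, qaly_undiscounted = qaly_undisc,
    cost_state = unname(comp[, "state"]), cost_drug = unname(comp[, "drug"]),
    cost_cv_acute = unname(comp[, "cv_acute"]),
    cost_cv_post = unname(comp[, "cv_post"]),
    cost_ae = unname(comp[, "ae"]), cost_death = unname(comp[, "death"]))
  attr(out, "strategy") <- strategy
  class(out) <- c("ckd_valued", class(out))
  out
}
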
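# Generator of random, structurally valid parameter sets. Emulates the
# statistical structure the analysis assumes — a row-stochastic CKD
# progression matrix with rare late-stage jumps, per-cycle event risks well
# below 1, effect ratios near 1 — so every pipeline stage is testable
# without external data.

# Structural-zero mask of the alive-state transition matrix: TRUE where a
# transition is allowed. Mirrors the published layout, including tunnel rows
# and no return from transplant.
transition_mask <- function() {
  s <- ckd_states()
  m <- matrix(FALSE, 8, 8, dimnames = list(s, s))
  m["ckd12", c("ckd12", "ckd3", "ckd4")] <- TRUE
  m["ckd3", c("ckd12", "ckd3", "ckd4", "ckd5", "dial_acute", "tx_acute")] <- TRUE
  m["ckd4", c("ckd3", "ckd4", "ckd5", "dial_acute")] <- TRUE
  m["ckd5", c("ckd3", "ckd4", "ckd5", "dial_acute", "tx_acute")] <- TRUE
  m["dial_acute", "dial_post"] <- TRUE
  m["dial_post", c("dial_post", "tx_acute")] <- TRUE
  m["tx_acute", "tx_post"] <- TRUE
  m["tx_post", "tx_post"] <- TRUE
  m
}

#' Generate a random valid transition matrix
#'
#' Draws a row-stochastic matrix respecting the structural zeros of the CKD
#' model layout: tunnel rows keep their mandatory successor, the diagonal
#' carries most of the mass (Dirichlet weights concentrated on staying), and
#' late-stage jumps are rare. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @return 8x8 row-stochastic matrix over [ckd_states()].
#' @export
#' @examples
#' m <- random_transition_matrix(42)
#' rowSums(m)  # all 1
random_transition_matrix <- function(seed = 1L) {
  set.seed(seed)
  mask <- transition_mask()
  s <- ckd_states()
  m <- matrix(0, 8, 8, dimnames = list(s, s))
  # Dirichlet concentration: heavy stay, moderate adjacent moves, light jumps
  conc <- matrix(0.5, 8, 8, dimnames = list(s, s))
  diag(conc) <- 40
  conc["ckd12", "ckd3"] <- 8
  conc["ckd3", "ckd4"] <- 6
  conc["ckd4", "ckd5"] <- 4
  conc["ckd5", "dial_acute"] <- 20
  for (i in seq_len(8)) {
    allowed <- which(mask[i, ])
    if (length(allowed) == 1L) {
      m[i, allowed] <- 1
    } else {
      g <- stats::rgamma(length(allowed), shape = conc[i, allowed], rate = 1)
      m[i, allowed] <- g / sum(g)
    }
  }
  m
}

#' Generate a random, fully valid parameter set
#'
#' Produces a complete `ckd_params` object passing [validate_parameters()]
#' with an empty report: random transition matrix, per-cycle risks scaled by
#' `risk_scale`, positive costs scaled by `cost_scale`, utilities in
#' \[0.5, 1\], effect ratios drawn uniformly from `effect_range`, random
#' baseline shares over CKD 1/2-4 and a random CV event mix. Sensitivity
#' ranges are `base * (0.8, 1.2)` clipped to each parameter's support.
#'
#' @param seed Integer seed (deterministic output).
#' @param risk_scale Multiplier on event/death risks (> 0).
#' @param cost_scale Multiplier on costs (> 0).
#' @param effect_range Interval the effect ratios are drawn from.
#' @param settings A [model_settings()] object.
#' @return A validated `ckd_params` object.
#' @export
#' @examples
#' ps <- random_parameter_set(7)
#' nrow(validate_parameters(ps))  # 0
random_parameter_set <- function(seed = 1L, risk_scale = 1, cost_scale = 1,
                                 effect_range = c(0.3, 1.2),
                                 settings = model_settings()) {
  stopifnot(risk_scale > 0, cost_scale > 0, all(effect_range > 0),
            effect_range[1L] <= effect_range[2L])
  tm <- random_transition_matrix(seed)
  set.seed(seed + 1L)
  s <- ckd_states()

  runif_named <- function(nm, lo, hi) stats::setNames(stats::runif(length(nm), lo, hi), nm)
  clip01 <- function(x) pmin(pmax(x, 0), 0.99)

  first_cv <- clip01(runif_named(s, 0.005, 0.03) * risk_scale)
  death <- clip01(runif_named(death_groups(), 0.004, 0.05) * risk_scale)
  subsequent_cv <- clip01(stats::runif(1, 0.05, 0.12) * risk_scale)

  ae <- matrix(0, 4, 3, dimnames = list(ckd_strategies(), ae_types()))
  for (st in c("finerenone", "sglt2i", "triple")) {
    ae[st, ] <- clip01(stats::runif(3, 0.0002, 0.01) * risk_scale)
  }

  effects <- data.frame(row.names = ckd_strategies(),
                        hr_first_cv = c(1, stats::runif(3, effect_range[1L], effect_range[2L])),
                        hr_mortality = c(1, stats::runif(3, effect_range[1L], effect_range[2L])),
                        rel_egfr = c(1, stats::runif(3, effect_range[1L], effect_range[2L])),
                        hr_renal = c(1, stats::runif(3, effect_range[1L], effect_range[2L])))

  costs <- list(
    state = runif_named(s, 200, 60000) * cost_scale,
    cv_acute = runif_named(cv_event_types(), 8000, 50000) * cost_scale,
    cv_post = runif_named(cv_event_types(), 4000, 15000) * cost_scale,
    ae = c(hyperkalemia = stats::runif(1, 500, 2000),
           aki = stats::runif(1, 15000, 90000),
           discontinuation = 0) * cost_scale,
    drug = runif_named(c("soc", "finerenone", "sglt2i"), 300, 2000) * cost_scale,
    death = stats::runif(1, 20000, 50000) * cost_scale)

  utilities <- list(
    state = runif_named(s, 0.5, 1),
    disutil_acute = -runif_named(cv_disutility_groups(), 0.005, 0.09),
    disutil_post = -runif_named(cv_disutility_groups(), 0.005, 0.08))

  share3 <- stats::rgamma(3, shape = 2)
  share <- stats::setNames(numeric(8), s)
  share[c("ckd12", "ckd3", "ckd4")] <- share3 / sum(share3)
  mix4 <- stats::rgamma(4, shape = 2)
  mix <- stats::setNames(mix4 / sum(mix4), cv_event_types())

  ps <- structure(
    list(settings = settings, transition = tm, first_cv = first_cv,
         subsequent_cv = subsequent_cv, death = death, ae = ae,
         effects = effects, costs = costs, utilities = utilities,
         baseline = list(share = share, cv_history = 0),
         cv_mix = mix, ranges = NULL),
    class = "ckd_params")
  ps$ranges <- synthetic_ranges(ps)
  assert_valid_parameters(ps)
  ps
}

# Build a range table for a generated set: base * (0.8, 1.2) clipped to each
# parameter's support, with families assigned by parameter type.
synthetic_ranges <- function(ps) {
  ref <- reference_ranges()
  base <- vapply(ref$id, function(id) get_param(ps, id), 0)
  low <- base * ifelse(base >= 0, 0.8, 1.2)
  high <- base * ifelse(base >= 0, 1.2, 0.8)
  is_prob <- ref$family == "beta" & base >= 0
  high[is_prob] <- pmin(high[is_prob], 1)
  tibble::tibble(id = ref$id, label = ref$label, base = base,
                 low = low, high = high, family = ref$family)
}
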
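# Parameter store: typed container for all model inputs, the published
# Chinese CKD/T2D input set as a built-in fixture, config file I/O and
# validation.

#' Model settings
#'
#' Run-level settings of the Markov cohort model.
#'
#' @param cycle_length_years Cycle length in years. The model uses 4-month
#'   cycles (1/3 year), matching the assessment interval of the underlying
#'   cardiorenal outcome trials.
#' @param horizon_years Time horizon in years; must be an integer multiple of
#'   the cycle length. Base case 10 years, scenario analysis 4 years.
#' @param discount_rate_annual Annual discount rate applied to both costs and
#'   QALYs (default 0.05).
#' @param wtp Willingness-to-pay threshold in CNY per QALY. Default 268,074,
#'   three times the 2023 Chinese GDP per capita.
#' @param psa_iterations Default number of probabilistic sensitivity analysis
#'   iterations (1,000).
#' @param half_cycle_correction Logical; if `TRUE`, state-occupancy cost and
#'   QALY accrual uses the mean of start- and end-of-cycle occupancy.
#'   Default `FALSE`.
#' @param drug_continue_rrt Logical; if `TRUE`, intervention drug costs
#'   (finerenone, SGLT2i) continue in dialysis/transplant states. Default
#'   `FALSE`: they stop at renal replacement therapy, while standard-of-care
#'   drug cost continues in all alive states.
#' @return A list of settings with class `ckd_settings`.
#' @export
model_settings <- function(cycle_length_years = 1 / 3,
                           horizon_years = 10,
                           discount_rate_annual = 0.05,
                           wtp = 268074,
                           psa_iterations = 1000,
                           half_cycle_correction = FALSE,
                           drug_continue_rrt = FALSE) {
  stopifnot(cycle_length_years > 0,
            discount_rate_annual >= 0, discount_rate_annual < 1,
            wtp > 0, psa_iterations >= 1)
  n_cycles <- horizon_years / cycle_length_years
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("`horizon_years` must be an integer multiple of the cycle length",
         call. = FALSE)
  }
  structure(
    list(cycle_length_years = cycle_length_years,
         horizon_years = horizon_years,
         discount_rate_annual = discount_rate_annual,
         wtp = wtp,
         psa_iterations = as.integer(psa_iterations),
         half_cycle_correction = isTRUE(half_cycle_correction),
         drug_continue_rrt = isTRUE(drug_continue_rrt)),
    class = "ckd_settings")
}

# --- the published input set ------------------------------------------------

# Standard-of-care transition matrix among alive states, printed as
# percentages; rows govern survivors only (death is a separate competing
# per-cycle risk). Acute dialysis and transplant are tunnel states whose rows
# place all mass on their mandated successor.
soc_transition_matrix <- function() {
  s <- ckd_states()
  m <- matrix(0, 8, 8, dimnames = list(s, s))
  m["ckd12", ] <- c(59.38, 40.38, 0.24, 0, 0, 0, 0, 0)
  m["ckd3", ]  <- c(2.85, 87.35, 9.51, 0.09, 0.13, 0, 0.07, 0)
  m["ckd4", ]  <- c(0, 10.92, 81.24, 5.22, 2.62, 0, 0, 0)
  m["ckd5", ]  <- c(0, 0.39, 4.25, 43.70, 49.67, 0, 1.99, 0)
  m["dial_acute", "dial_post"] <- 100
  m["dial_post", c("dial_post", "tx_acute")] <- c(98.73, 1.27)
  m["tx_acute", "tx_post"] <- 100
  m["tx_post", "tx_post"] <- 100
  m / 100
}

#' Reference parameter set for CKD with type 2 diabetes in China
#'
#' The complete published base-case input set: the standard-of-care transition
#' matrix, per-cycle cardiovascular event and all-cause death risks, adverse
#' event risks, treatment-effect ratios from the pooled finerenone outcome
#' trials (FIDELITY), 2023 CNY costs and EQ-5D-5L utilities.
#'
#' The baseline CKD-stage distribution and the composite cardiovascular event
#' mix come from supplementary material that is not part of the printed input
#' tables. When not supplied, documented defaults are used (15/60/25% across
#' CKD 1/2, 3 and 4; equal weights across the four CV event types) and a
#' warning is raised so downstream users know the values are package defaults
#' rather than published inputs.
#'
#' @param baseline_share Optional named numeric vector of cycle-0 occupancy
#'   shares over the alive states (codes from [ckd_states()]); must sum to 1.
#' @param cv_mix Optional named numeric vector of composite CV event weights
#'   over `c("mi", "is", "hs", "hf")`; must sum to 1.
#' @param settings A [model_settings()] object.
#' @param quiet Suppress the default-value warnings.
#' @return A validated parameter set of class `ckd_params`.
#' @export
#' @examples
#' ps <- reference_parameters(quiet = TRUE)
#' ps$transition["ckd3", "ckd4"]   # 0.0951
#' ps$costs$drug[["finerenone"]]   # 1445 CNY per cycle
reference_parameters <- function(baseline_share = NULL, cv_mix = NULL,
                                 settings = model_settings(),
                                 quiet = FALSE) {
  s <- ckd_states()

  first_cv <- c(ckd12 = 0.0126, ckd3 = 0.0095, ckd4 = 0.0171, ckd5 = 0.0224,
                dial_acute = 0.0224, dial_post = 0.0224,
                tx_acute = 0.0171, tx_post = 0.0171)
  death <- c(ckd12 = 0.0092, ckd3 = 0.0058, ckd4 = 0.0085, ckd5 = 0.0160,
             dialysis = 0.0501, transplant = 0.0085)

  ae <- matrix(0, nrow = 4, ncol = 3,
               dimnames = list(ckd_strategies(), ae_types()))
  ae["finerenone", ] <- c(0.0016, 0.0040, 0.0075)
  ae["sglt2i", ]     <- c(0.0000, 0.0038, 0.0059)
  ae["triple", ]     <- c(0.0003, 0.0012, 0.0047)

  effects <- data.frame(
    row.names    = ckd_strategies(),
    hr_first_cv  = c(1, 0.87, 0.80, 0.57),
    hr_mortality = c(1, 0.90, 0.70, 0.46),
    rel_egfr     = c(1, 0.68, 0.93, 0.52),
    hr_renal     = c(1, 0.78, 0.52, 0.27))

  costs <- list(
    state = c(ckd12 = 269, ckd3 = 269, ckd4 = 269, ckd5 = 1800,
              dial_acute = 54604, dial_post = 50106,
              tx_acute = 228571, tx_post = 44337),
    cv_acute = c(mi = 31267, is = 10181, hs = 21355, hf = 48429),
    cv_post  = c(mi = 12068, is = 10567, hs = 7455, hf = 6177),
    ae    = c(hyperkalemia = 1000, aki = 40445, discontinuation = 0),
    drug  = c(soc = 1561, finerenone = 1445, sglt2i = 494),
    death = 36487)

  utilities <- list(
    state = c(ckd12 = 0.884, ckd3 = 0.884, ckd4 = 0.884, ckd5 = 0.871,
              dial_acute = 0.804, dial_post = 0.782,
              tx_acute = 0.813, tx_post = 0.972),
    disutil_acute = c(mi = -0.075, stroke = -0.059, hf = -0.012),
    disutil_post  = c(mi = -0.009, stroke = -0.018, hf = -0.070))

  if (is.null(baseline_share)) {
    if (!quiet) {
      warning("baseline CKD-stage distribution not supplied; ",
              "using package default 0.15/0.60/0.25 over CKD 1/2, 3 and 4",
              call. = FALSE)
    }
    baseline_share <- c(ckd12 = 0.15, ckd3 = 0.60, ckd4 = 0.25)
  }
  share <- stats::setNames(numeric(8), s)
  share[names(baseline_share)] <- baseline_share

  if (is.null(cv_mix)) {
    if (!quiet) {
      warning("composite CV event mix not supplied; ",
              "using package default of equal weights over MI, ischemic ",
              "stroke, hemorrhagic stroke and HF hospitalization",
              call. = FALSE)
    }
    cv_mix <- c(mi = 0.25, is = 0.25, hs = 0.25, hf = 0.25)
  }
  mix <- stats::setNames(numeric(4), cv_event_types())
  mix[names(cv_mix)] <- cv_mix

  ps <- structure(
    list(settings = settings,
         transition = soc_transition_matrix(),
         first_cv = first_cv,
         subsequent_cv = 0.085,
         death = death,
         ae = ae,
         effects = effects,
         costs = costs,
         utilities = utilities,
         baseline = list(share = share, cv_history = 0),
         cv_mix = mix,
         ranges = reference_ranges()),
    class = "ckd_params")
  assert_valid_parameters(ps)
  ps
}

# Published base-case / range / distribution-family table for every parameter
# varied in one-way and probabilistic sensitivity analysis. The `id` column is
# the accessor path understood by get_param()/set_param().
reference_ranges <- function() {
  rows <- list(
    # first CV event risk per cycle, SoC (Beta)
    c("first_cv.ckd12", "First CV event risk, CKD 1/2", 0.0126, 0.0041, 0.0256, "beta"),
    c("first_cv.ckd3", "First CV event risk, CKD 3", 0.0095, 0.0069, 0.0126, "beta"),
    c("first_cv.ckd4", "First CV event risk, CKD 4", 0.0171, 0.0112, 0.0242, "beta"),
    c("first_cv.ckd5", "First CV event risk, CKD 5 without RRT", 0.0224, 0.0047, 0.0533, "beta"),
    c("first_cv.dial_acute", "First CV event risk, dialysis (acute)", 0.0224, 0.0047, 0.0533, "beta"),
    c("first_cv.dial_post", "First CV event risk, dialysis (post-acute)", 0.0224, 0.0047, 0.0533, "beta"),
    c("first_cv.tx_acute", "First CV event risk, transplant (acute)", 0.0171, 0.0112, 0.0242, "beta"),
    c("first_cv.tx_post", "First CV event risk, transplant (post-acute)", 0.0171, 0.0112, 0.0242, "beta"),
    c("subsequent_cv", "Subsequent CV event risk", 0.085, 0.0597, 0.1142, "beta"),
    # treatment-effect hazard ratios (Lognormal)
    c("hr_first_cv.finerenone", "HR first CV event, finerenone vs SoC", 0.87, 0.70, 1.04, "lognormal"),
    c("hr_first_cv.sglt2i", "HR first CV event, SGLT2i vs SoC", 0.80, 0.64, 0.96, "lognormal"),
    c("hr_first_cv.triple", "HR first CV event, triple vs SoC", 0.57, 0.46, 0.69, "lognormal"),
    # all-cause death risk per cycle, SoC (Beta)
    c("death.ckd12", "Death risk, CKD 1/2", 0.0092, 0.0060, 0.0166, "beta"),
    c("death.ckd3", "Death risk, CKD 3", 0.0058, 0.0045, 0.0076, "beta"),
    c("death.ckd4", "Death risk, CKD 4", 0.0085, 0.0055, 0.0127, "beta"),
    c("death.ckd5", "Death risk, CKD 5 without RRT", 0.0160, 0.0034, 0.0506, "beta"),
    c("death.dialysis", "Death risk, dialysis", 0.0501, 0.0057, 0.0634, "beta"),
    c("death.transplant", "Death risk, transplant", 0.0085, 0.0055, 0.0127, "beta"),
    c("hr_mortality.finerenone", "HR all-cause mortality, finerenone vs SoC", 0.90, 0.72, 1.08, "lognormal"),
    c("hr_mortality.sglt2i", "HR all-cause mortality, SGLT2i vs SoC", 0.70, 0.56, 0.84, "lognormal"),
    c("hr_mortality.triple", "HR all-cause mortality, triple vs SoC", 0.46, 0.37, 0.55, "lognormal"),
    # adverse event risks per cycle (Beta)
    c("ae.finerenone.hyperkalemia", "Hyperkalemia hospitalization risk, finerenone", 0.0016, 0.0012, 0.0020, "beta"),
    c("ae.finerenone.aki", "Acute kidney injury risk, finerenone", 0.0040, 0.0031, 0.0051, "beta"),
    c("ae.finerenone.discontinuation", "AE discontinuation risk, finerenone", 0.0075, 0.0059, 0.0097, "beta"),
    c("ae.sglt2i.aki", "Acute kidney injury risk, SGLT2i", 0.0038, 0.0030, 0.0050, "beta"),
    c("ae.sglt2i.discontinuation", "AE discontinuation risk, SGLT2i", 0.0059, 0.0047, 0.0077, "beta"),
    c("ae.triple.hyperkalemia", "Hyperkalemia hospitalization risk, triple", 0.0003, 0.0002, 0.0003, "beta"),
    c("ae.triple.aki", "Acute kidney injury risk, triple", 0.0012, 0.0009, 0.0016, "beta"),
    c("ae.triple.discontinuation", "AE discontinuation risk, triple", 0.0047, 0.0037, 0.0061, "beta"),
    # treatment efficacy (Lognormal)
    c("rel_egfr.finerenone", "Relative eGFR decline rate, finerenone vs SoC", 0.68, 0.55, 0.82, "lognormal"),
    c("rel_egfr.sglt2i", "Relative eGFR decline rate, SGLT2i vs SoC", 0.93, 0.74, 1.11, "lognormal"),
    c("rel_egfr.triple", "Relative eGFR decline rate, triple vs SoC", 0.52, 0.41, 0.62, "lognormal"),
    c("hr_renal.finerenone", "HR renal composite outcome, finerenone vs SoC", 0.78, 0.62, 0.94, "lognormal"),
    c("hr_renal.sglt2i", "HR renal composite outcome, SGLT2i vs SoC", 0.52, 0.42, 0.62, "lognormal"),
    c("hr_renal.triple", "HR renal composite outcome, triple vs SoC", 0.27, 0.21, 0.32, "lognormal"),
    # costs, 2023 CNY (Gamma)
    c("cost_state.ckd12", "Cost per cycle, CKD 1/2", 269, 215, 323, "gamma"),
    c("cost_state.ckd3", "Cost per cycle, CKD 3", 269, 215, 323, "gamma"),
    c("cost_state.ckd4", "Cost per cycle, CKD 4", 269, 215, 323, "gamma"),
    c("cost_state.ckd5", "Cost per cycle, CKD 5 without RRT", 1800, 1440, 2160, "gamma"),
    c("cost_state.dial_acute", "Cost per cycle, dialysis (acute)", 54604, 43683, 65525, "gamma"),
    c("cost_state.dial_post", "Cost per cycle, dialysis (post-acute)", 50106, 40085, 60128, "gamma"),
    c("cost_state.tx_acute", "Cost, kidney transplant (acute)", 228571, 182857, 274286, "gamma"),
    c("cost_state.tx_post", "Cost per cycle, transplant (post-acute)", 44337, 35470, 53025, "gamma"),
    c("cost_cv_acute.mi", "Cost, MI (acute)", 31267, 25014, 37520, "gamma"),
    c("cost_cv_post.mi", "Cost per cycle, MI (post-acute)", 12068, 9654, 14482, "gamma"),
    c("cost_cv_acute.is", "Cost, ischemic stroke (acute)", 10181, 8145, 12217, "gamma"),
    c("cost_cv_post.is", "Cost per cycle, ischemic stroke (post-acute)", 10567, 8453, 12680, "gamma"),
    c("cost_cv_acute.hs", "Cost, hemorrhagic stroke (acute)", 21355, 17084, 25626, "gamma"),
    c("cost_cv_post.hs", "Cost per cycle, hemorrhagic stroke (post-acute)", 7455, 5964, 8946, "gamma"),
    c("cost_cv_acute.hf", "Cost, HF hospitalization (acute)", 48429, 38743, 58115, "gamma"),
    c("cost_cv_post.hf", "Cost per cycle, HF (post-acute)", 6177, 4942, 7413, "gamma"),
    c("cost_ae.hyperkalemia", "Cost, hyperkalemia hospitalization", 1000, 800, 1200, "gamma"),
    c("cost_ae.aki", "Cost, acute kidney injury", 40445, 18727, 95320, "gamma"),
    c("cost_drug.soc", "Drug cost per cycle, SoC", 1561, 1249.024, 1874, "gamma"),
    c("cost_drug.finerenone", "Drug cost per cycle, finerenone", 1445, 1156, 1733, "gamma"),
    c("cost_drug.sglt2i", "Drug cost per cycle, SGLT2i", 494, 285, 703, "gamma"),
    c("cost_death", "Cost, death", 36487, 29189, 43784, "gamma"),
    # utilities (Beta)
    c("util_state.ckd12", "Utility, CKD 1/2", 0.884, 0.707, 1.000, "beta"),
    c("util_state.ckd3", "Utility, CKD 3", 0.884, 0.707, 1.000, "beta"),
    c("util_state.ckd4", "Utility, CKD 4", 0.884, 0.707, 1.000, "beta"),
    c("util_state.ckd5", "Utility, CKD 5 without RRT", 0.871, 0.696, 1.000, "beta"),
    c("util_state.dial_acute", "Utility, dialysis (acute)", 0.804, 0.643, 0.964, "beta"),
    c("util_state.dial_post", "Utility, dialysis (post-acute)", 0.782, 0.625, 0.938, "beta"),
    c("util_state.tx_acute", "Utility, transplant (acute)", 0.813, 0.650, 0.975, "beta"),
    c("util_state.tx_post", "Utility, transplant (post-acute)", 0.972, 0.777, 1.000, "beta"),
    # disutilities: negative decrements, Beta on the magnitude
    c("disutil_acute.mi", "Disutility, MI (acute)", -0.075, -0.090, -0.060, "beta"),
    c("disutil_post.mi", "Disutility, MI (post-acute)", -0.009, -0.011, -0.007, "beta"),
    c("disutil_acute.stroke", "Disutility, stroke (acute)", -0.059, -0.071, -0.047, "beta"),
    c("disutil_post.stroke", "Disutility, stroke (post-acute)", -0.018, -0.022, -0.014, "beta"),
    c("disutil_acute.hf", "Disutility, HF hospitalization (acute)", -0.012, -0.014, -0.010, "beta"),
    c("disutil_post.hf", "Disutility, HF (post-acute)", -0.070, -0.084, -0.056, "beta"))
  tibble::tibble(
    id = vapply(rows, `[[`, "", 1L),
    label = vapply(rows, `[[`, "", 2L),
    base = as.numeric(vapply(rows, `[[`, "", 3L)),
    low = as.numeric(vapply(rows, `[[`, "", 4L)),
    high = as.numeric(vapply(rows, `[[`, "", 5L)),
    family = vapply(rows, `[[`, "", 6L))
}

# --- parameter accessors ----------------------------------------------------

# Resolve a range-table id like "ae.finerenone.aki" to a location inside the
# parameter set. Death risks are stored by group; disutilities carry their
# sign in the stored value.
param_path <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  head <- parts[1L]
  switch(head,
    first_cv = list("first_cv", parts[2L]),
    subsequent_cv = list("subsequent_cv"),
    death = list("death", parts[2L]),
    ae = list("ae", parts[2L], parts[3L]),
    hr_first_cv = list("effects", parts[2L], "hr_first_cv"),
    hr_mortality = list("effects", parts[2L], "hr_mortality"),
    rel_egfr = list("effects", parts[2L], "rel_egfr"),
    hr_renal = list("effects", parts[2L], "hr_renal"),
    cost_state = list("costs", "state", parts[2L]),
    cost_cv_acute = list("costs", "cv_acute", parts[2L]),
    cost_cv_post = list("costs", "cv_post", parts[2L]),
    cost_ae = list("costs", "ae", parts[2L]),
    cost_drug = list("costs", "drug", parts[2L]),
    cost_death = list("costs", "death"),
    util_state = list("utilities", "state", parts[2L]),
    disutil_acute = list("utilities", "disutil_acute", parts[2L]),
    disutil_post = list("utilities", "disutil_post", parts[2L]),
    stop("unknown parameter id: ", id, call. = FALSE))
}

#' Read a scalar model parameter by id
#'
#' Parameter ids are the accessor paths used in the sensitivity-analysis
#' range table (`ps$ranges$id`), e.g. `"rel_egfr.triple"`,
#' `"cost_drug.finerenone"`, `"death.dialysis"`.
#'
#' @param ps A `ckd_params` object.
#' @param id Parameter id string.
#' @return The current scalar value.
#' @export
get_param <- function(ps, id) {
  path <- param_path(id)
  if (identical(path[[1L]], "effects")) return(ps$effects[path[[2L]], path[[3L]]])
  if (identical(path[[1L]], "ae")) return(unname(ps$ae[path[[2L]], path[[3L]]]))
  x <- ps
  for (p in path) x <- x[[p]]
  unname(x)
}

#' Set a scalar model parameter by id
#'
#' Returns a modified copy of the parameter set. Setting a grouped mortality
#' risk (e.g. `"death.dialysis"`) changes the risk of every state in that
#' group, mirroring the shared rows of the published input table.
#'
#' @inheritParams get_param
#' @param value New scalar value.
#' @return A modified `ckd_params` object.
#' @export
set_param <- function(ps, id, value) {
  path <- param_path(id)
  if (identical(path[[1L]], "effects")) {
    ps$effects[path[[2L]], path[[3L]]] <- value
    return(ps)
  }
  if (length(path) == 1L) {
    ps[[path[[1L]]]] <- value
  } else if (length(path) == 2L) {
    ps[[path[[1L]]]][[path[[2L]]]] <- value
  } else {
    if (identical(path[[1L]], "ae")) {
      ps$ae[path[[2L]], path[[3L]]] <- value
    } else {
      ps[[path[[1L]]]][[path[[2L]]]][[path[[3L]]]] <- value
    }
  }
  ps
}

# --- validation -------------------------------------------------------------

#' Validate a parameter set
#'
#' Checks every structural invariant: row-stochastic transition matrix with
#' tunnel rows intact, probabilities in \[0, 1\], strictly positive effect
#' ratios, non-negative costs, utilities in \[0, 1\], non-positive
#' disutilities, baseline shares and CV event mix each summing to 1, and
#' consistent range rows (low <= base <= high).
#'
#' @param ps A `ckd_params` object.
#' @return A tibble with columns `table`, `entry`, `message`; zero rows iff
#'   the parameter set is valid.
#' @export
#' @examples
#' nrow(validate_parameters(reference_parameters(quiet = TRUE)))  # 0
validate_parameters <- function(ps) {
  bad <- list()
  flag <- function(table, entry, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(table = table, entry = entry,
                                               message = message)
  }
  s <- ckd_states()

  tm <- ps$transition
  if (!identical(dim(tm), c(8L, 8L))) {
    flag("transition", "dim", "transition matrix must be 8x8")
  } else {
    if (any(tm < -1e-12 | tm > 1 + 1e-12)) {
      flag("transition", "entries", "entries outside [0, 1]")
    }
    rs <- rowSums(tm)
    for (i in which(abs(rs - 1) > 1e-9)) {
      flag("transition", s[i], sprintf("row sums to %.6f, not 1", rs[i]))
    }
    if (!isTRUE(all.equal(unname(tm["dial_acute", "dial_post"]), 1)))
      flag("transition", "dial_acute", "tunnel row must move all mass to dial_post")
    if (!isTRUE(all.equal(unname(tm["tx_acute", "tx_post"]), 1)))
      flag("transition", "tx_acute", "tunnel row must move all mass to tx_post")
  }

  chk_prob <- function(v, table) {
    for (nm in names(v)) {
      if (v[[nm]] < 0 || v[[nm]] > 1)
        flag(table, nm, sprintf("probability %g outside [0, 1]", v[[nm]]))
    }
  }
  chk_prob(ps$first_cv, "first_cv")
  chk_prob(c(subsequent = ps$subsequent_cv), "subsequent_cv")
  chk_prob(ps$death, "death")
  chk_prob(stats::setNames(as.vector(ps$ae),
                           paste(rep(rownames(ps$ae), ncol(ps$ae)),
                                 rep(colnames(ps$ae), each = nrow(ps$ae)),
                                 sep = ".")), "ae")

  for (st in rownames(ps$effects)) {
    for (col in colnames(ps$effects)) {
      if (ps$effects[st, col] <= 0)
        flag("effects", paste(st, col, sep = "."), "effect ratio must be > 0")
    }
  }

  costs <- c(ps$costs$state, ps$costs$cv_acute, ps$costs$cv_post,
             ps$costs$ae, ps$costs$drug, death = ps$costs$death)
  for (nm in names(costs)) {
    if (costs[[nm]] < 0) flag("costs", nm, "cost must be >= 0")
  }

  for (nm in names(ps$utilities$state)) {
    u <- ps$utilities$state[[nm]]
    if (u < 0 || u > 1) flag("utilities", nm, sprintf("utility %g outside [0, 1]", u))
  }
  dis <- c(ps$utilities$disutil_acute, ps$utilities$disutil_post)
  for (nm in names(dis)) {
    if (dis[[nm]] > 0) flag("utilities", nm, "disutility must be <= 0")
  }

  sh <- ps$baseline$share
  if (any(sh < 0)) flag("baseline", "share", "shares must be >= 0")
  if (abs(sum(sh) - 1) > 1e-9) flag("baseline", "share", "shares must sum to 1")
  if (ps$baseline$cv_history < 0 || ps$baseline$cv_history > 1)
    flag("baseline", "cv_history", "share outside [0, 1]")

  if (any(ps$cv_mix < 0)) flag("cv_mix", "weights", "weights must be >= 0")
  if (abs(sum(ps$cv_mix) - 1) > 1e-9) flag("cv_mix", "weights", "weights must sum to 1")

  r <- ps$ranges
  if (!is.null(r) && nrow(r)) {
    bad_rows <- which(!(r$low <= r$base & r$base <= r$high))
    for (i in bad_rows) flag("ranges", r$id[i], "requires low <= base <= high")
  }

  if (length(bad)) do.call(rbind, bad)
  else tibble::tibble(table = character(), entry = character(),
                      message = character())
}

assert_valid_parameters <- function(ps) {
  rep <- validate_parameters(ps)
  if (nrow(rep)) {
    stop("invalid parameter set:\n",
         paste(sprintf("  [%s/%s] %s", rep$table, rep$entry, rep$message),
               collapse = "\n"), call. = FALSE)
  }
  invisible(ps)
}

# --- config file I/O --------------------------------------------------------

params_to_list <- function(ps) {
  list(
    settings = unclass(ps$settings),
    transition = stats::setNames(
      lapply(seq_len(nrow(ps$transition)),
             function(i) as.list(ps$transition[i, ])),
      rownames(ps$transition)),
    first_cv = as.list(ps$first_cv),
    subsequent_cv = ps$subsequent_cv,
    death = as.list(ps$death),
    ae = stats::setNames(
      lapply(rownames(ps$ae), function(st) as.list(ps$ae[st, ])),
      rownames(ps$ae)),
    effects = stats::setNames(
      lapply(rownames(ps$effects), function(st) as.list(ps$effects[st, ])),
      rownames(ps$effects)),
    costs = list(state = as.list(ps$costs$state),
                 cv_acute = as.list(ps$costs$cv_acute),
                 cv_post = as.list(ps$costs$cv_post),
                 ae = as.list(ps$costs$ae),
                 drug = as.list(ps$costs$drug),
                 death = ps$costs$death),
    utilities = list(state = as.list(ps$utilities$state),
                     disutil_acute = as.list(ps$utilities$disutil_acute),
                     disutil_post = as.list(ps$utilities$disutil_post)),
    baseline = list(share = as.list(ps$baseline$share),
                    cv_history = ps$baseline$cv_history),
    cv_mix = as.list(ps$cv_mix),
    ranges = lapply(seq_len(nrow(ps$ranges)), function(i) as.list(ps$ranges[i, ])))
}

list_to_params <- function(x) {
  s <- ckd_states()
  tm <- do.call(rbind, lapply(x$transition, function(row) unlist(row)[s]))
  rownames(tm) <- names(x$transition)
  tm <- tm[s, s]
  eff <- do.call(rbind, lapply(x$effects, as.data.frame))
  rownames(eff) <- names(x$effects)
  ranges <- if (length(x$ranges)) {
    do.call(rbind, lapply(x$ranges, function(r) tibble::as_tibble(r)))
  } else reference_ranges()[0, ]
  ae <- do.call(rbind, lapply(x$ae, function(row) unlist(row)[ae_types()]))
  rownames(ae) <- names(x$ae)
  settings <- do.call(model_settings, x$settings[
    intersect(names(x$settings), names(formals(model_settings)))])
  structure(
    list(settings = settings,
         transition = tm,
         first_cv = unlist(x$first_cv)[s],
         subsequent_cv = x$subsequent_cv,
         death = unlist(x$death)[death_groups()],
         ae = ae[ckd_strategies(), , drop = FALSE],
         effects = eff[ckd_strategies(), ],
         costs = list(state = unlist(x$costs$state)[s],
                      cv_acute = unlist(x$costs$cv_acute)[cv_event_types()],
                      cv_post = unlist(x$costs$cv_post)[cv_event_types()],
                      ae = unlist(x$costs$ae)[ae_types()],
                      drug = unlist(x$costs$drug)[c("soc", "finerenone", "sglt2i")],
                      death = x$costs$death),
         utilities = list(
           state = unlist(x$utilities$state)[s],
           disutil_acute = unlist(x$utilities$disutil_acute)[cv_disutility_groups()],
           disutil_post = unlist(x$utilities$disutil_post)[cv_disutility_groups()]),
         baseline = list(share = unlist(x$baseline$share)[s],
                         cv_history = x$baseline$cv_history),
         cv_mix = unlist(x$cv_mix)[cv_event_types()],
         ranges = ranges),
    class = "ckd_params")
}

#' Write a parameter set to a config file
#'
#' The format is chosen from the file extension: `.json` (full double
#' precision; recommended for exact round trips) or `.yaml`/`.yml`.
#'
#' @param ps A `ckd_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  x <- params_to_list(ps)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    stop("unsupported config extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Load a parameter set from a config file
#'
#' Reads a YAML or JSON config mirroring the parameter-set structure (as
#' written by [write_parameter_set()]) and validates it. A config may instead
#' contain `use_reference: true` plus optional `baseline_share` / `cv_mix`
#' overrides to request the packaged published input set.
#'
#' @param path Config file path.
#' @return A validated `ckd_params` object.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: .", ext, call. = FALSE)
  }
  if (isTRUE(x$use_reference)) {
    args <- list(quiet = isTRUE(x$quiet))
    if (!is.null(x$baseline_share)) args$baseline_share <- unlist(x$baseline_share)
    if (!is.null(x$cv_mix)) args$cv_mix <- unlist(x$cv_mix)
    if (!is.null(x$settings)) {
      args$settings <- do.call(model_settings, x$settings[
        intersect(names(x$settings), names(formals(model_settings)))])
    }
    return(do.call(reference_parameters, args))
  }
  required <- c("settings", "transition", "first_cv", "subsequent_cv",
                "death", "ae", "effects", "costs", "utilities", "baseline",
                "cv_mix")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("config is missing required table(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ps <- tryCatch(list_to_params(x), error = function(e) {
    stop("malformed config `", path, "`: ", conditionMessage(e), call. = FALSE)
  })
  assert_valid_parameters(ps)
  ps
}

#' @export
print.ckd_params <- function(x, ...) {
  cat("<ckd_params>\n")
  cat(sprintf("  horizon %g y, cycle %.4g y, discount %.1f%%, WTP %s CNY/QALY\n",
              x$settings$horizon_years, x$settings$cycle_length_years,
              100 * x$settings$discount_rate_annual,
              format(x$settings$wtp, big.mark = ",")))
  cat(sprintf("  baseline: %s\n",
              paste(sprintf("%s %.0f%%",
                            names(x$baseline$share)[x$baseline$share > 0],
                            100 * x$baseline$share[x$baseline$share > 0]),
                    collapse = ", ")))
  cat(sprintf("  %d ranged parameters for sensitivity analysis\n",
              nrow(x$ranges)))
  invisible(x)
}
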
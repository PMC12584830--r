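test_that("discount factors follow the annual rate at cycle resolution", {
  expect_equal(discount_factor(0), 1)
  expect_equal(discount_factor(3), 0.952380952381, tolerance = 1e-12)
  expect_equal(discount_factor(30), 0.613913253541, tolerance = 1e-12)
  expect_equal(discount_factor(6, annual_rate = 0), 1)
})

test_that("composite CV economics weights the event mix correctly", {
  ps <- ref_ps()
  mi_only <- composite_cv_economics(c(mi = 1, is = 0, hs = 0, hf = 0),
                                    ps$costs, ps$utilities)
  expect_equal(mi_only$acute_cost, 31267)
  expect_equal(mi_only$acute_disutility, -0.075)
  expect_equal(mi_only$postacute_cost_per_cycle, 12068)

  eq <- composite_cv_economics(c(mi = .25, is = .25, hs = .25, hf = .25),
                               ps$costs, ps$utilities)
  expect_equal(eq$acute_cost, 27808)
  # both stroke types share the stroke disutility
  expect_equal(eq$acute_disutility,
               0.25 * (-0.075) + 0.5 * (-0.059) + 0.25 * (-0.012))

  hf_only <- composite_cv_economics(c(mi = 0, is = 0, hs = 0, hf = 1),
                                    ps$costs, ps$utilities)
  expect_equal(hf_only$postacute_cost_per_cycle, 6177)
  expect_error(composite_cv_economics(c(mi = .5, is = 0, hs = 0, hf = 0),
                                      ps$costs, ps$utilities), "sum to 1")
})

# hand-built single-cycle trace: whole cohort sits in one compartment
one_cycle_trace <- function(compartment, strategy = "soc") {
  occ <- matrix(0, 2, 17, dimnames = list(NULL, c(
    paste0(ckd_states(), "_nocv"), paste0(ckd_states(), "_postcv"), "dead")))
  occ[, compartment] <- 1
  structure(list(occupancy = occ, new_deaths = 0, new_first_cv = 0,
                 new_subsequent_cv = 0,
                 ae = matrix(0, 1, 3, dimnames = list(NULL, c(
                   "hyperkalemia", "aki", "discontinuation"))),
                 strategy = strategy, cycle_length_years = 1 / 3,
                 horizon_years = 1 / 3),
            class = "ckd_trace")
}

test_that("valuation reproduces direct per-cycle products", {
  ps <- ref_ps()
  ps$settings <- model_settings(discount_rate_annual = 0, horizon_years = 10)

  vt <- value_trace(one_cycle_trace("ckd3_nocv"), ps, "soc")
  expect_equal(vt$qaly, 0.884 / 3, tolerance = 1e-12)
  expect_equal(vt$cost, 269 + 1561, tolerance = 1e-12)  # management + SoC drug

  # entering acute dialysis accrues the acute cost that cycle
  vt <- value_trace(one_cycle_trace("dial_acute_nocv"), ps, "soc")
  expect_equal(vt$cost_state, 54604, tolerance = 1e-12)

  # intervention drug cost stops at RRT by default, continues when enabled
  vt <- value_trace(one_cycle_trace("dial_post_nocv"), ps, "triple")
  expect_equal(vt$cost_drug, 1561, tolerance = 1e-12)
  ps_cont <- ps
  ps_cont$settings <- model_settings(discount_rate_annual = 0,
                                     drug_continue_rrt = TRUE)
  vt <- value_trace(one_cycle_trace("dial_post_nocv"), ps_cont, "triple")
  expect_equal(vt$cost_drug, 1561 + 1445 + 494, tolerance = 1e-12)

  # dead cohort accrues nothing
  vt <- value_trace(one_cycle_trace("dead"), ps, "soc")
  expect_equal(vt$cost + vt$qaly, 0)
})

test_that("post-CV occupancy pays post-acute costs; incident events pay acute", {
  ps <- ref_ps()
  ps$settings <- model_settings(discount_rate_annual = 0)
  cvx <- composite_cv_economics(ps$cv_mix, ps$costs, ps$utilities)

  tr <- one_cycle_trace("ckd3_postcv")
  vt <- value_trace(tr, ps, "soc")
  expect_equal(vt$cost_cv_post, cvx$postacute_cost_per_cycle,
               tolerance = 1e-12)
  expect_equal(vt$qaly, (0.884 + cvx$postacute_disutility) / 3,
               tolerance = 1e-12)

  # an incident event this cycle pays acute, not yet post-acute
  tr$new_first_cv <- 1
  vt <- value_trace(tr, ps, "soc")
  expect_equal(vt$cost_cv_acute, cvx$acute_cost, tolerance = 1e-12)
  expect_equal(vt$cost_cv_post, 0, tolerance = 1e-12)
})

test_that("zero discounting makes the streams identical; QALYs bounded by horizon", {
  ps <- ref_ps()
  ps$settings <- model_settings(discount_rate_annual = 0)
  tr <- run_model(ps, "triple")
  vt <- value_trace(tr, ps, "triple")
  expect_equal(vt$cost, vt$cost_undiscounted, tolerance = 1e-12)
  expect_equal(vt$qaly, vt$qaly_undiscounted, tolerance = 1e-12)

  # perfect health, no deaths, no events: undiscounted QALYs equal horizon
  ideal <- ps
  ideal$death[] <- 0
  ideal$first_cv[] <- 0
  ideal$subsequent_cv <- 0
  ideal$utilities$state[] <- 1
  vt <- value_trace(run_model(ideal, "soc"), ideal, "soc")
  expect_equal(sum(vt$qaly_undiscounted), 10, tolerance = 1e-9)
})

test_that("totals respond monotonically to cost and disutility inputs", {
  ps <- ref_ps()
  base_cost <- sum(value_trace(run_model(ps, "triple"), ps, "triple")$cost)
  for (id in c("cost_state.dial_post", "cost_drug.soc", "cost_ae.aki",
               "cost_death")) {
    up <- set_param(ps, id, get_param(ps, id) * 1.5)
    expect_gte(sum(value_trace(run_model(up, "triple"), up, "triple")$cost),
               base_cost)
  }
  base_q <- sum(value_trace(run_model(ps, "triple"), ps, "triple")$qaly)
  deeper <- set_param(ps, "disutil_post.mi", -0.05)
  expect_lt(sum(value_trace(run_model(deeper, "triple"), deeper,
                            "triple")$qaly), base_q)
})

test_that("half-cycle correction averages start and end occupancy", {
  ps <- ref_ps()
  ps$settings <- model_settings(discount_rate_annual = 0,
                                half_cycle_correction = TRUE)
  # cohort fully alive at cycle 0, half dies during cycle 1
  occ <- matrix(0, 2, 17, dimnames = list(NULL, c(
    paste0(ckd_states(), "_nocv"), paste0(ckd_states(), "_postcv"), "dead")))
  occ[1, "ckd3_nocv"] <- 1
  occ[2, "ckd3_nocv"] <- 0.5
  occ[2, "dead"] <- 0.5
  tr <- structure(list(occupancy = occ, new_deaths = 0.5, new_first_cv = 0,
                       new_subsequent_cv = 0,
                       ae = matrix(0, 1, 3, dimnames = list(NULL, c(
                         "hyperkalemia", "aki", "discontinuation"))),
                       strategy = "soc", cycle_length_years = 1 / 3,
                       horizon_years = 1 / 3), class = "ckd_trace")
  vt <- value_trace(tr, ps, "soc")
  expect_equal(vt$qaly, 0.75 * 0.884 / 3, tolerance = 1e-12)
})
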
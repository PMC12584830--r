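test_that("reference set carries the published base-case values", {
  ps <- ref_ps()
  # spot checks across all four input tables
  expect_equal(ps$transition["ckd3", "ckd4"], 0.0951)
  expect_equal(ps$transition["ckd12", "ckd3"], 0.4038)
  expect_equal(ps$transition["ckd5", "dial_acute"], 0.4967)
  expect_equal(unname(ps$first_cv["ckd3"]), 0.0095)
  expect_equal(ps$subsequent_cv, 0.085)
  expect_equal(unname(ps$death["dialysis"]), 0.0501)
  expect_equal(ps$effects["triple", "hr_mortality"], 0.46)
  expect_equal(ps$effects["sglt2i", "rel_egfr"], 0.93)
  expect_equal(ps$effects["finerenone", "hr_renal"], 0.78)
  expect_equal(unname(ps$costs$drug["finerenone"]), 1445)
  expect_equal(unname(ps$costs$state["dial_acute"]), 54604)
  expect_equal(unname(ps$costs$cv_acute["hf"]), 48429)
  expect_equal(ps$costs$death, 36487)
  expect_equal(unname(ps$utilities$state["dial_post"]), 0.782)
  expect_equal(unname(ps$utilities$disutil_acute["mi"]), -0.075)
  expect_equal(unname(ps$ae["triple", "aki"]), 0.0012)
})

test_that("table-driven range rows match the printed base/low/high values", {
  r <- ref_ps()$ranges
  pick <- function(id) r[r$id == id, ]
  cases <- list(
    list("first_cv.ckd5", 0.0224, 0.0047, 0.0533, "beta"),
    list("hr_mortality.triple", 0.46, 0.37, 0.55, "lognormal"),
    list("cost_ae.aki", 40445, 18727, 95320, "gamma"),
    list("cost_drug.soc", 1561, 1249.024, 1874, "gamma"),
    list("util_state.tx_post", 0.972, 0.777, 1.000, "beta"),
    list("disutil_post.hf", -0.070, -0.084, -0.056, "beta"))
  for (cs in cases) {
    row <- pick(cs[[1]])
    expect_equal(nrow(row), 1L, info = cs[[1]])
    expect_equal(c(row$base, row$low, row$high), unlist(cs[2:4]),
                 info = cs[[1]])
    expect_identical(row$family, cs[[5]], info = cs[[1]])
  }
  expect_true(all(r$low <= r$base & r$base <= r$high))
})

test_that("every transition row sums to one and tunnels are intact", {
  tm <- ref_ps()$transition
  expect_equal(unname(rowSums(tm)), rep(1, 8), tolerance = 1e-9)
  expect_equal(unname(tm["dial_acute", "dial_post"]), 1)
  expect_equal(unname(tm["tx_acute", "tx_post"]), 1)
  expect_equal(unname(tm["tx_post", "tx_post"]), 1)
})

test_that("validation flags injected invariant violations and passes the reference set", {
  ps <- ref_ps()
  expect_equal(nrow(validate_parameters(ps)), 0L)

  bad <- ps
  bad$transition["ckd4", "ckd3"] <- 0.009  # row now sums to 0.898
  rep <- validate_parameters(bad)
  expect_true(any(rep$table == "transition" & rep$entry == "ckd4"))

  bad <- ps
  bad$utilities$state["ckd3"] <- 1.2
  expect_true(any(validate_parameters(bad)$entry == "ckd3"))

  bad <- ps
  bad$costs$state["ckd5"] <- -5
  expect_true(any(validate_parameters(bad)$table == "costs"))

  bad <- ps
  bad$death["dialysis"] <- 1.4
  expect_true(any(validate_parameters(bad)$table == "death"))
})

test_that("missing baseline distribution and CV mix fall back to documented defaults with a warning", {
  expect_warning(ps <- reference_parameters(cv_mix = c(mi = 1)),
                 "baseline CKD-stage distribution")
  expect_equal(unname(ps$baseline$share[c("ckd12", "ckd3", "ckd4")]),
               c(0.15, 0.60, 0.25))
  expect_warning(reference_parameters(baseline_share = c(ckd3 = 1)),
                 "CV event mix")
})

test_that("parameter sets round-trip through JSON and YAML configs", {
  ps <- ref_ps()
  for (ext in c(".json", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_parameter_set(ps, f)
    ps2 <- load_parameter_set(f)
    expect_equal(ps2$transition, ps$transition, tolerance = 1e-12)
    expect_equal(ps2$first_cv, ps$first_cv, tolerance = 1e-12)
    expect_equal(ps2$death, ps$death, tolerance = 1e-12)
    expect_equal(ps2$costs, ps$costs, tolerance = 1e-12)
    expect_equal(ps2$utilities, ps$utilities, tolerance = 1e-12)
    expect_equal(ps2$effects, ps$effects, tolerance = 1e-12)
    expect_equal(ps2$baseline$share, ps$baseline$share, tolerance = 1e-12)
    expect_equal(ps2$ranges$base, ps$ranges$base, tolerance = 1e-12)
    expect_equal(ps2$settings$wtp, ps$settings$wtp)
  }
})

test_that("loading rejects missing files, missing tables and invalid values", {
  expect_error(load_parameter_set("no/such/file.yaml"), "not found")

  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(settings = list(wtp = 1)), f)
  expect_error(load_parameter_set(f), "missing required table")

  ps <- ref_ps()
  ps$transition["ckd4", "ckd3"] <- 0.009
  f2 <- withr::local_tempfile(fileext = ".json")
  write_parameter_set(ps, f2)
  expect_error(load_parameter_set(f2), "invalid parameter set")
})

test_that("a config can request the packaged reference set with overrides", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(use_reference = TRUE, quiet = TRUE,
                        baseline_share = list(ckd3 = 0.5, ckd4 = 0.5),
                        settings = list(horizon_years = 4)), f)
  ps <- load_parameter_set(f)
  expect_equal(unname(ps$baseline$share["ckd3"]), 0.5)
  expect_equal(ps$settings$horizon_years, 4)
  expect_equal(ps$transition["ckd3", "ckd4"], 0.0951)
})

test_that("get_param and set_param address every ranged parameter", {
  ps <- ref_ps()
  for (id in ps$ranges$id) {
    expect_equal(get_param(ps, id), ps$ranges$base[ps$ranges$id == id],
                 info = id)
    ps2 <- set_param(ps, id, get_param(ps, id) * 0.999)
    expect_equal(get_param(ps2, id),
                 ps$ranges$base[ps$ranges$id == id] * 0.999, info = id)
  }
  # grouped mortality rows move every state in the group
  ps3 <- set_param(ps, "death.dialysis", 0.02)
  sm <- build_strategy_model(ps3, "soc")
  expect_equal(unname(sm$death["dial_acute"]), 0.02)
  expect_equal(unname(sm$death["dial_post"]), 0.02)
})
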
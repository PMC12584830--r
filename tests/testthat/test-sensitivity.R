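test_that("distribution fitting matches method-of-moments closed forms", {
  g <- fit_distribution(1445, 1156, 1733, "gamma")
  expect_identical(g$family, "gamma")
  expect_equal(g$params$shape, 96.373182750677, tolerance = 1e-9)
  expect_equal(g$params$scale, 14.993797639104, tolerance = 1e-9)
  expect_equal(dist_mean(g), 1445, tolerance = 1e-9)

  # symmetric beta: mean 0.5, sd 0.1 (range = mean +/- 1.96 sd) -> a = b = 12
  b <- fit_distribution(0.5, 0.5 - 1.96 * 0.1, 0.5 + 1.96 * 0.1, "beta")
  expect_equal(b$params$shape1, 12, tolerance = 1e-9)
  expect_equal(b$params$shape2, 12, tolerance = 1e-9)

  ln <- fit_distribution(0.57, 0.46, 0.69, "lognormal")
  expect_equal(dist_mean(ln), 0.57, tolerance = 1e-9)

  # degenerate range collapses to a point mass
  p <- fit_distribution(3, 3, 3, "gamma")
  expect_identical(p$family, "point")
  expect_equal(draw_distribution(p, 5), rep(3, 5))

  # negative disutility: fitted on the magnitude, sign restored
  d <- fit_distribution(-0.075, -0.090, -0.060, "beta")
  expect_equal(dist_mean(d), -0.075, tolerance = 1e-9)
  set.seed(1)
  expect_true(all(draw_distribution(d, 100) < 0))

  # infeasible beta (variance >= m(1-m)) falls back to uniform with a warning
  expect_warning(u <- fit_distribution(0.5, -0.6, 1.6, "beta"), "uniform")
  expect_identical(u$family, "uniform")
})

test_that("sample means of fitted distributions converge to the base case", {
  set.seed(20260919)
  n <- 10000
  cases <- list(c("first_cv.ckd3"), c("cost_drug.finerenone"),
                c("hr_mortality.triple"), c("disutil_acute.mi"),
                c("cost_ae.aki"))
  r <- ref_ps()$ranges
  for (id in cases) {
    row <- r[r$id == id, ]
    d <- fit_distribution(row$base, row$low, row$high, row$family)
    x <- draw_distribution(d, n)
    mc_se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - row$base), 3 * mc_se + 0.02 * abs(row$base))
  }
})

test_that("tornado entries rank parameters by NMB swing", {
  ps <- ref_ps()
  ids <- c("rel_egfr.sglt2i", "cost_drug.finerenone", "death.dialysis",
           "util_state.ckd3")
  ow <- owsa(ps, c("triple", "sglt2i"), param_ids = ids)
  expect_setequal(ow$table$id, ids)
  expect_true(all(diff(ow$table$swing) <= 1e-9))
  expect_equal(ow$table$swing, abs(ow$table$nmb_high - ow$table$nmb_low),
               tolerance = 1e-12)
  # symmetric-range, monotone-response parameters bracket the base NMB
  row <- ow$table[ow$table$id == "cost_drug.finerenone", ]
  expect_true(min(row$nmb_low, row$nmb_high) <= ow$nmb_base + 1e-6 &&
                ow$nmb_base <= max(row$nmb_low, row$nmb_high) + 1e-6)
})

test_that("parameters consumed by neither arm have zero swing", {
  ps <- ref_ps()
  # finerenone-only effects cannot move a triple-vs-SGLT2i comparison
  ow <- owsa(ps, c("triple", "sglt2i"),
             param_ids = c("rel_egfr.finerenone", "hr_mortality.finerenone"))
  expect_equal(ow$table$swing, c(0, 0), tolerance = 1e-9)
  expect_warning(owsa(ps, c("triple", "sglt2i"),
                      param_ids = c("not.a.param", "rel_egfr.triple")),
                 "without a range")
})

test_that("NMB responds linearly to the willingness-to-pay threshold", {
  ps <- ref_ps()
  res1 <- run_cea(ps, wtp = 100000)
  res2 <- run_cea(ps, wtp = 300000)
  dq <- res1$incrementals$incr_qalys
  expect_equal(res2$incrementals$nmb - res1$incrementals$nmb,
               dq * 200000, tolerance = 1e-6)
})

test_that("PSA is seed-reproducible and degenerate ranges recover the base case", {
  ps <- ref_ps()
  a <- run_psa(ps, n = 5, seed = 42)
  b <- run_psa(ps, n = 5, seed = 42)
  expect_identical(a$draws, b$draws)
  c <- run_psa(ps, n = 5, seed = 43)
  expect_false(identical(a$draws, c$draws))

  # point-mass ranges: one iteration equals the deterministic base case
  psd <- ps
  psd$ranges$low <- psd$ranges$base
  psd$ranges$high <- psd$ranges$base
  one <- run_psa(psd, n = 1, seed = 7)
  base <- run_cea(ps)
  expect_equal(one$draws$incr_cost,
               base$incrementals$incr_cost[match(
                 c("sglt2i", "finerenone"),
                 base$incrementals$comparator)], tolerance = 1e-9)
  expect_equal(one$draws$nmb,
               base$incrementals$nmb[match(
                 c("sglt2i", "finerenone"),
                 base$incrementals$comparator)], tolerance = 1e-9)
})

test_that("CEAC fractions match brute-force enumeration on a hand-built PSA", {
  draws <- tibble::tibble(
    iteration = 1:4,
    comparison = rep("a_vs_b", 4),
    incr_cost = c(-100, 50, 200, -10),
    incr_qalys = c(0.01, 0.02, -0.01, 0.001))
  psa <- structure(list(draws = draws, seed = 1L, n = 4L, wtp = 1e4,
                        n_redrawn = 0L), class = "ckd_psa")
  # nmb(w) = q*w - c checked by hand for each draw at each wtp:
  # w=0 -> draws 1,4 positive; w=1e4 -> 1,2,4; w=1e6 -> 1,2,4
  cc <- ceac(psa, c(0, 1e4, 1e6))
  expect_equal(cc$prob_cost_effective, c(2 / 4, 3 / 4, 3 / 4))
  # wtp = 0 reduces to the fraction of cost-saving draws
  expect_equal(cc$prob_cost_effective[1], mean(draws$incr_cost < 0))
  dom <- psa_dominance(psa)
  expect_equal(dom$prob_dominant, 2 / 4)
  expect_error(ceac(psa, numeric(0)), "non-empty")
})
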
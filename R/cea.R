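# Per-arm totals and pairwise incremental cost-effectiveness results.

#' Summarize a valued trace into per-arm totals
#'
#' @param vt A `ckd_valued` tibble from [value_trace()].
#' @param strategy Strategy label (defaults to the trace's).
#' @return List of class `ckd_arm`: `strategy`, `total_cost`, `total_qalys`
#'   (discounted), plus undiscounted twins.
#' @export
summarize_arm <- function(vt, strategy = attr(vt, "strategy")) {
  structure(
    list(strategy = strategy,
         total_cost = sum(vt$cost),
         total_qalys = sum(vt$qaly),
         total_cost_undiscounted = sum(vt$cost_undiscounted),
         total_qalys_undiscounted = sum(vt$qaly_undiscounted)),
    class = "ckd_arm")
}

#' Pairwise incremental cost-effectiveness result
#'
#' Net monetary benefit is `incr_qalys * wtp - incr_cost`. A strategy is
#' "dominant" when it saves costs and gains QALYs, "dominated" in the
#' opposite case. The ICER (`incr_cost / incr_qalys`) is reported only when
#' neither dominance applies and the QALY difference is non-degenerate.
#'
#' @param a Intervention [summarize_arm()] result.
#' @param b Comparator [summarize_arm()] result.
#' @param wtp Willingness-to-pay threshold (currency per QALY).
#' @return List of class `ckd_incremental`: `reference`, `comparator`,
#'   `incr_cost`, `incr_qalys`, `nmb`, `icer`, `dominance`.
#' @export
#' @examples
#' a <- structure(list(strategy = "x", total_cost = 90, total_qalys = 1.1),
#'                class = "ckd_arm")
#' b <- structure(list(strategy = "y", total_cost = 100, total_qalys = 1.0),
#'                class = "ckd_arm")
#' incremental(a, b, wtp = 100000)
incremental <- function(a, b, wtp) {
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qalys - b$total_qalys
  nmb <- dq * wtp - dc
  dominance <- if (dc < 0 && dq > 0) "dominant"
               else if (dc > 0 && dq < 0) "dominated"
               else "none"
  icer <- if (dominance != "none" || abs(dq) < 1e-12) NA_real_ else dc / dq
  structure(
    list(reference = a$strategy, comparator = b$strategy,
         incr_cost = dc, incr_qalys = dq, nmb = nmb, icer = icer,
         dominance = dominance),
    class = "ckd_incremental")
}

#' Run the full cost-effectiveness analysis
#'
#' Runs the cohort model and valuation for every requested strategy and
#' computes pairwise incrementals of the reference strategy against each
#' comparator.
#'
#' @param ps A `ckd_params` object.
#' @param strategies Arms to run (default: triple, SGLT2i, finerenone).
#' @param reference The intervention compared against the others (default
#'   `"triple"`).
#' @param horizon_years Optional override of the settings horizon.
#' @param wtp Optional override of the settings willingness-to-pay.
#' @return List of class `ckd_cea` with `arms` (tibble: strategy, cost,
#'   QALYs) and `incrementals` (tibble: comparison, incr_cost, incr_qalys,
#'   NMB, ICER, dominance), plus the per-arm objects in `detail`.
#' @export
#' @examples
#' ps <- reference_parameters(quiet = TRUE)
#' res <- run_cea(ps)
#' res$incrementals
run_cea <- function(ps, strategies = c("triple", "sglt2i", "finerenone"),
                    reference = "triple", horizon_years = NULL, wtp = NULL) {
  if (is.null(wtp)) wtp <- ps$settings$wtp
  stopifnot(reference %in% strategies)
  arms <- lapply(stats::setNames(strategies, strategies), function(st) {
    tr <- run_model(ps, st, horizon_years = horizon_years)
    summarize_arm(value_trace(tr, ps, st))
  })
  arm_tbl <- tibble::tibble(
    strategy = strategies,
    total_cost = vapply(arms, `[[`, 0, "total_cost"),
    total_qalys = vapply(arms, `[[`, 0, "total_qalys"))
  comparators <- setdiff(strategies, reference)
  incr <- lapply(comparators, function(cmp) {
    incremental(arms[[reference]], arms[[cmp]], wtp)
  })
  incr_tbl <- tibble::tibble(
    reference = reference,
    comparator = comparators,
    incr_cost = vapply(incr, `[[`, 0, "incr_cost"),
    incr_qalys = vapply(incr, `[[`, 0, "incr_qalys"),
    nmb = vapply(incr, `[[`, 0, "nmb"),
    icer = vapply(incr, `[[`, 0, "icer"),
    dominance = vapply(incr, `[[`, "", "dominance"))
  structure(list(arms = arm_tbl, incrementals = incr_tbl,
                 wtp = wtp, detail = arms),
            class = "ckd_cea")
}

#' @export
print.ckd_cea <- function(x, ...) {
  cat("Cost-effectiveness results (discounted)\n")
  a <- x$arms
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-11s cost %14s CNY   QALYs %6.3f\n", a$strategy[i],
                format(round(a$total_cost[i], 2), big.mark = ","),
                a$total_qalys[i]))
  }
  cat(sprintf("Incrementals at WTP %s CNY/QALY\n",
              format(x$wtp, big.mark = ",")))
  b <- x$incrementals
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %s vs %-11s dCost %12.2f  dQALY %6.3f  NMB %12.2f  [%s]\n",
                b$reference[i], b$comparator[i], b$incr_cost[i],
                b$incr_qalys[i], b$nmb[i], b$dominance[i]))
  }
  invisible(x)
}
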
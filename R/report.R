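# Report assembly: write traces, results tables, tornado, PSA scatter and
# CEAC files, with a run manifest. A thin command-line wrapper over these
# functions ships in inst/cli/ckdcea.R.

write_manifest <- function(out_dir, command, seed, files, extra = list()) {
  manifest <- c(list(
    command = command,
    package_version = as.character(utils::packageVersion("ckdcea")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = files), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(files, path)
}

#' Run the model and write all base-case outputs
#'
#' Writes, per strategy, the occupancy/event trace and the valued
#' (cost/QALY) trace as CSV, plus a results table in the published layout
#' (cost, incremental cost, QALYs, incremental QALYs, NMB; costs rounded to
#' 2 decimals, QALYs to 3) and a JSON manifest.
#'
#' @param ps A `ckd_params` object.
#' @param out_dir Output directory (created if needed).
#' @param strategies Arms to run.
#' @param reference Reference strategy for incrementals.
#' @param horizon_years,wtp Optional overrides.
#' @return Character vector of files written, invisibly.
#' @export
write_run_outputs <- function(ps, out_dir,
                              strategies = c("triple", "sglt2i", "finerenone"),
                              reference = "triple",
                              horizon_years = NULL, wtp = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_cea(ps, strategies, reference, horizon_years, wtp)
  files <- character()
  for (st in strategies) {
    tr <- run_model(ps, st, horizon_years = horizon_years)
    f1 <- file.path(out_dir, paste0("trace_", st, ".csv"))
    utils::write.csv(trace_table(tr), f1, row.names = FALSE)
    f2 <- file.path(out_dir, paste0("valued_", st, ".csv"))
    utils::write.csv(value_trace(tr, ps, st), f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  # published layout: one block per comparison, comparator row first with
  # zero incrementals, then the reference row with its incrementals
  a <- res$arms
  b <- res$incrementals
  blocks <- lapply(seq_len(nrow(b)), function(i) {
    cmp <- b$comparator[i]
    data.frame(
      strategy = c(cmp, reference),
      cost = round(a$total_cost[match(c(cmp, reference), a$strategy)], 2),
      incr_cost = c(0, round(b$incr_cost[i], 2)),
      qalys = round(a$total_qalys[match(c(cmp, reference), a$strategy)], 3),
      incr_qalys = c(0, round(b$incr_qalys[i], 3)),
      nmb = c(0, round(b$nmb[i], 2)))
  })
  results <- do.call(rbind, blocks)
  f <- file.path(out_dir, "results.csv")
  utils::write.csv(results, f, row.names = FALSE)
  files <- c(files, f)
  files <- write_manifest(out_dir, "run", seed = NA, files,
                          extra = list(horizon_years = horizon_years %||%
                                         ps$settings$horizon_years,
                                       wtp = wtp %||% ps$settings$wtp))
  invisible(files)
}

#' Write one-way sensitivity (tornado) outputs
#'
#' @param ps A `ckd_params` object.
#' @param out_dir Output directory.
#' @param comparison `c(reference, comparator)` pair.
#' @param ... Passed to [owsa()].
#' @return Files written, invisibly.
#' @export
write_owsa_outputs <- function(ps, out_dir,
                               comparison = c("triple", "sglt2i"), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ow <- owsa(ps, comparison, ...)
  f <- file.path(out_dir, sprintf("tornado_%s_vs_%s.csv",
                                  comparison[1L], comparison[2L]))
  utils::write.csv(ow$table, f, row.names = FALSE)
  files <- write_manifest(out_dir, "owsa", seed = NA, f,
                          extra = list(nmb_base = ow$nmb_base))
  invisible(files)
}

#' Write probabilistic sensitivity analysis outputs
#'
#' Writes the cost-effectiveness plane draws, the acceptability curve over a
#' WTP grid, a dominance summary and the manifest.
#'
#' @param ps A `ckd_params` object.
#' @param out_dir Output directory.
#' @param n Iterations.
#' @param seed Integer seed (drawn at random and recorded when omitted).
#' @param wtp_grid WTP grid for the CEAC (default 0 to 2x the threshold).
#' @param ... Passed to [run_psa()].
#' @return Files written, invisibly.
#' @export
write_psa_outputs <- function(ps, out_dir, n = NULL, seed = NULL,
                              wtp_grid = NULL, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  psa <- run_psa(ps, n = n, seed = seed, ...)
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 2 * ps$settings$wtp, length.out = 41)
  }
  f1 <- file.path(out_dir, "ce_plane.csv")
  utils::write.csv(psa$draws, f1, row.names = FALSE)
  f2 <- file.path(out_dir, "ceac.csv")
  utils::write.csv(ceac(psa, wtp_grid), f2, row.names = FALSE)
  f3 <- file.path(out_dir, "psa_summary.csv")
  utils::write.csv(psa_dominance(psa), f3, row.names = FALSE)
  files <- write_manifest(out_dir, "psa", seed = seed, c(f1, f2, f3),
                          extra = list(n = psa$n, n_redrawn = psa$n_redrawn))
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tornado diagram
#'
#' Horizontal bars from the base-case NMB to the NMB at each parameter
#' bound, for the top-ranked parameters.
#'
#' @param ow A `ckd_owsa` result.
#' @param top Number of parameters shown (default 10).
#' @return A ggplot object.
#' @export
plot_tornado <- function(ow, top = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tab <- utils::head(ow$table, top)
  long <- rbind(
    data.frame(label = tab$label, bound = "low", nmb = tab$nmb_low),
    data.frame(label = tab$label, bound = "high", nmb = tab$nmb_high))
  long$label <- factor(long$label, levels = rev(tab$label))
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(ggplot2::aes(
      x = ow$nmb_base, xend = .data$nmb, y = .data$label,
      yend = .data$label, colour = .data$bound), linewidth = 4) +
    ggplot2::geom_vline(xintercept = ow$nmb_base, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(low = "grey55", high = "firebrick")) +
    ggplot2::labs(x = "Net monetary benefit (CNY)", y = NULL,
                  colour = "Bound",
                  title = sprintf("%s vs %s", ow$comparison[1L],
                                  ow$comparison[2L]))
}

#' Cost-effectiveness plane scatter
#'
#' @param psa A `ckd_psa` result.
#' @param wtp Willingness-to-pay line (default from the PSA).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = psa$wtp) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(psa$draws, ggplot2::aes(.data$incr_qalys, .data$incr_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)")
}
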
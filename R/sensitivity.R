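# One-way sensitivity analysis with tornado ranking, sampling-distribution
# fitting from base case + range, and probabilistic sensitivity analysis.

#' Fit a probabilistic sampling distribution from a base case and range
#'
#' The (low, high) range is read as a 95% interval, so the standard
#' deviation is `(high - low) / 3.92`, and the family is fitted by method of
#' moments around the base-case mean:
#' beta `alpha = m * (m(1-m)/s^2 - 1)`, `beta = (1-m) * (m(1-m)/s^2 - 1)`;
#' gamma `shape = m^2/s^2`, `scale = s^2/m`; lognormal `sigma^2 =
#' log(1 + s^2/m^2)`, `mu = log(m) - sigma^2/2` (moments on the natural
#' scale). Negative parameters (disutilities) are fitted on their magnitude
#' and drawn with the sign restored. A degenerate range collapses to a point
#' mass; an infeasible beta falls back to uniform(low, high) with a warning.
#'
#' @param base Base-case value.
#' @param low,high Range bounds (low <= base <= high).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`.
#' @param lognormal_ci If `TRUE`, fit lognormal parameters from the range as
#'   a 95% CI on the log scale (`meanlog = log(base)`,
#'   `sdlog = (log(high) - log(low)) / 3.92`) instead of natural-scale
#'   moment matching.
#' @return List of class `ckd_dist`: `family`, `params`, `base`, `sign`.
#' @export
#' @examples
#' fit_distribution(1445, 1156, 1733, "gamma")  # finerenone cycle cost
fit_distribution <- function(base, low, high, family, lognormal_ci = FALSE) {
  stopifnot(low <= base, base <= high)
  sign <- if (base < 0) -1 else 1
  if (sign < 0) {
    tmp <- -low; low <- -high; high <- tmp; base <- -base
  }
  s <- (high - low) / 3.92
  if (s == 0) {
    return(structure(list(family = "point", params = list(value = base),
                          base = sign * base, sign = sign),
                     class = "ckd_dist"))
  }
  m <- base
  spec <- switch(family,
    beta = {
      v <- s^2
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
        warning("beta fit infeasible for base ", sign * m,
                "; falling back to uniform", call. = FALSE)
        list(family = "uniform", params = list(min = low, max = high))
      } else {
        nu <- m * (1 - m) / v - 1
        list(family = "beta", params = list(shape1 = m * nu,
                                            shape2 = (1 - m) * nu))
      }
    },
    gamma = list(family = "gamma",
                 params = list(shape = m^2 / s^2, scale = s^2 / m)),
    lognormal = {
      if (lognormal_ci) {
        list(family = "lognormal",
             params = list(meanlog = log(m),
                           sdlog = (log(high) - log(low)) / 3.92))
      } else {
        sdlog2 <- log(1 + (s / m)^2)
        list(family = "lognormal",
             params = list(meanlog = log(m) - sdlog2 / 2,
                           sdlog = sqrt(sdlog2)))
      }
    },
    stop("unknown distribution family: ", family, call. = FALSE))
  structure(list(family = spec$family, params = spec$params,
                 base = sign * m, sign = sign),
            class = "ckd_dist")
}

#' Draw from a fitted sampling distribution
#'
#' @param dist A `ckd_dist` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws (sign restored for negative
#'   parameters).
#' @export
draw_distribution <- function(dist, n = 1) {
  x <- switch(dist$family,
    point = rep(dist$params$value, n),
    beta = stats::rbeta(n, dist$params$shape1, dist$params$shape2),
    gamma = stats::rgamma(n, shape = dist$params$shape,
                          scale = dist$params$scale),
    lognormal = stats::rlnorm(n, dist$params$meanlog, dist$params$sdlog),
    uniform = stats::runif(n, dist$params$min, dist$params$max),
    stop("unknown fitted family: ", dist$family, call. = FALSE))
  dist$sign * x
}

#' Theoretical mean of a fitted sampling distribution
#' @param dist A `ckd_dist`.
#' @return The distribution mean (signed).
#' @export
dist_mean <- function(dist) {
  m <- switch(dist$family,
    point = dist$params$value,
    beta = dist$params$shape1 / (dist$params$shape1 + dist$params$shape2),
    gamma = dist$params$shape * dist$params$scale,
    lognormal = exp(dist$params$meanlog + dist$params$sdlog^2 / 2),
    uniform = (dist$params$min + dist$params$max) / 2)
  dist$sign * m
}

# NMB of reference vs comparator for one parameter set.
nmb_for <- function(ps, comparison, wtp, horizon_years = NULL) {
  res <- run_cea(ps, strategies = comparison, reference = comparison[1L],
                 horizon_years = horizon_years, wtp = wtp)
  res$incrementals$nmb[1L]
}

#' One-way sensitivity analysis with tornado ranking
#'
#' Re-runs the pairwise comparison with each ranged parameter set to its low
#' and then high bound (all other parameters at base case), recording the
#' net monetary benefit at each bound. Entries are ranked by the NMB swing
#' `|nmb_high - nmb_low|`; the base-case NMB is the tornado's expected-value
#' line.
#'
#' @param ps A `ckd_params` object.
#' @param comparison Character pair `c(reference, comparator)`, e.g.
#'   `c("triple", "sglt2i")`.
#' @param wtp Willingness-to-pay (default from settings).
#' @param param_ids Parameter ids to vary (default: all ranged parameters).
#' @param horizon_years Optional horizon override.
#' @return List of class `ckd_owsa`: `table` (tibble sorted by descending
#'   swing: id, label, low, high, nmb_low, nmb_high, swing) and `nmb_base`.
#' @export
#' @examples
#' ps <- reference_parameters(quiet = TRUE)
#' ow <- owsa(ps, c("triple", "sglt2i"),
#'            param_ids = c("rel_egfr.sglt2i", "cost_drug.finerenone"))
#' ow$table
owsa <- function(ps, comparison = c("triple", "sglt2i"), wtp = NULL,
                 param_ids = NULL, horizon_years = NULL) {
  if (is.null(wtp)) wtp <- ps$settings$wtp
  r <- ps$ranges
  if (is.null(param_ids)) param_ids <- r$id
  missing <- setdiff(param_ids, r$id)
  if (length(missing)) {
    warning("skipping parameter(s) without a range: ",
            paste(missing, collapse = ", "), call. = FALSE)
    param_ids <- setdiff(param_ids, missing)
  }
  nmb_base <- nmb_for(ps, comparison, wtp, horizon_years)
  rows <- lapply(param_ids, function(id) {
    ri <- r[r$id == id, ]
    lo <- nmb_for(set_param(ps, id, ri$low), comparison, wtp, horizon_years)
    hi <- nmb_for(set_param(ps, id, ri$high), comparison, wtp, horizon_years)
    tibble::tibble(id = id, label = ri$label, low = ri$low, high = ri$high,
                   nmb_low = lo, nmb_high = hi, swing = abs(hi - lo))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$swing), ]
  structure(list(table = tab, nmb_base = nmb_base, comparison = comparison,
                 wtp = wtp),
            class = "ckd_owsa")
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: each iteration independently draws every ranged
#' parameter from its fitted distribution ([fit_distribution()]), rebuilds
#' all strategy models, runs the full cohort model, and records the pairwise
#' incremental cost, QALYs and NMB. Identical seeds give identical draws. An
#' iteration whose sampled effects make a transition row infeasible is
#' redrawn (counted in `n_redrawn`).
#'
#' @param ps A `ckd_params` object.
#' @param n Number of iterations (default `ps$settings$psa_iterations`).
#' @param seed Integer seed for reproducibility.
#' @param wtp Willingness-to-pay (default from settings).
#' @param comparisons List of `c(reference, comparator)` pairs.
#' @param horizon_years Optional horizon override.
#' @return List of class `ckd_psa`: `draws` (tibble: iteration, comparison,
#'   incr_cost, incr_qalys, nmb), `seed`, `n`, `wtp`, `n_redrawn`.
#' @export
run_psa <- function(ps, n = NULL, seed = 1L, wtp = NULL,
                    comparisons = list(c("triple", "sglt2i"),
                                       c("triple", "finerenone")),
                    horizon_years = NULL) {
  if (is.null(n)) n <- ps$settings$psa_iterations
  if (is.null(wtp)) wtp <- ps$settings$wtp
  stopifnot(n >= 1)
  set.seed(seed)
  r <- ps$ranges
  dists <- lapply(seq_len(nrow(r)), function(i) {
    fit_distribution(r$base[i], r$low[i], r$high[i], r$family[i])
  })
  names(dists) <- r$id
  strategies <- unique(unlist(comparisons))
  cmp_names <- vapply(comparisons, paste, "", collapse = "_vs_")

  out <- vector("list", n)
  n_redrawn <- 0L
  for (it in seq_len(n)) {
    repeat {
      psi <- ps
      for (id in names(dists)) {
        psi <- set_param(psi, id, draw_distribution(dists[[id]], 1L))
      }
      res <- tryCatch({
        arms <- lapply(stats::setNames(strategies, strategies), function(st) {
          tr <- run_model(psi, st, horizon_years = horizon_years)
          summarize_arm(value_trace(tr, psi, st))
        })
        lapply(comparisons, function(cm) {
          incremental(arms[[cm[1L]]], arms[[cm[2L]]], wtp)
        })
      }, error = function(e) {
        if (grepl("infeasible", conditionMessage(e))) NULL else stop(e)
      })
      if (!is.null(res)) break
      n_redrawn <- n_redrawn + 1L
    }
    out[[it]] <- tibble::tibble(
      iteration = it,
      comparison = cmp_names,
      incr_cost = vapply(res, `[[`, 0, "incr_cost"),
      incr_qalys = vapply(res, `[[`, 0, "incr_qalys"),
      nmb = vapply(res, `[[`, 0, "nmb"))
  }
  structure(list(draws = do.call(rbind, out), seed = seed, n = as.integer(n),
                 wtp = wtp, n_redrawn = n_redrawn),
            class = "ckd_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with a
#' positive net monetary benefit (recomputed at that WTP from the stored
#' incremental costs and QALYs).
#'
#' @param psa A `ckd_psa` result.
#' @param wtp_grid Numeric vector of WTP values.
#' @return Tibble: comparison, wtp, prob_cost_effective.
#' @export
ceac <- function(psa, wtp_grid) {
  if (!length(wtp_grid)) stop("`wtp_grid` must be non-empty", call. = FALSE)
  d <- psa$draws
  rows <- lapply(unique(d$comparison), function(cm) {
    di <- d[d$comparison == cm, ]
    tibble::tibble(
      comparison = cm,
      wtp = wtp_grid,
      prob_cost_effective = vapply(wtp_grid, function(w) {
        mean(di$incr_qalys * w - di$incr_cost > 0)
      }, 0))
  })
  do.call(rbind, rows)
}

#' Proportion of PSA draws in which the reference strategy is dominant
#'
#' @param psa A `ckd_psa` result.
#' @return Tibble: comparison, prob_dominant (draws with cost saving and
#'   QALY gain).
#' @export
psa_dominance <- function(psa) {
  d <- psa$draws
  rows <- lapply(unique(d$comparison), function(cm) {
    di <- d[d$comparison == cm, ]
    tibble::tibble(comparison = cm,
                   prob_dominant = mean(di$incr_cost < 0 & di$incr_qalys > 0))
  })
  do.call(rbind, rows)
}
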
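# Cohort simulation: 17 compartments = 8 alive states x {no-CV, post-CV}
# plus absorbing Dead. Each cycle applies, in order, all-cause death, the
# survivor state transition, and the CV-event layer switch; adverse events
# are tallied without moving occupancy.

compartment_names <- function() {
  s <- ckd_states()
  c(paste0(s, "_nocv"), paste0(s, "_postcv"), "dead")
}

#' Initialize the cohort occupancy
#'
#' Places the baseline CKD-stage shares in the no-CV layer at cycle 0 (or
#' splits each share proportionally into the post-CV layer when
#' `baseline$cv_history > 0`), with nobody dead.
#'
#' @param baseline List with `share` (named over [ckd_states()], summing
#'   to 1) and `cv_history` (proportion starting with a prior CV event).
#' @return Named occupancy vector over the 17 compartments.
#' @export
initialize_cohort <- function(baseline) {
  share <- baseline$share
  if (abs(sum(share) - 1) > 1e-9) {
    stop("baseline shares must sum to 1", call. = FALSE)
  }
  h <- baseline$cv_history
  occ <- stats::setNames(numeric(17), compartment_names())
  occ[1:8] <- share * (1 - h)
  occ[9:16] <- share * h
  occ
}

#' Advance the cohort by one cycle
#'
#' Within-cycle event order: (1) all-cause death by current state; (2) among
#' survivors, first CV events strike the no-CV layer at the origin state's
#' per-cycle risk; (3) everyone transitions among alive states, with first-CV
#' cases landing in the post-CV layer of their destination and subsequent CV
#' events tallied (no layer change) for pre-existing post-CV survivors;
#' (4) adverse events accrue as survivor occupancy times per-cycle AE risks.
#'
#' @param occ Occupancy vector over the 17 compartments, summing to 1.
#' @param sm A `ckd_strategy` model from [build_strategy_model()].
#' @return List with `occ` (next-cycle occupancy) and the cycle tallies
#'   `new_deaths`, `new_first_cv`, `new_subsequent_cv`, `ae` (by type).
#' @export
step_cycle <- function(occ, sm) {
  if (abs(sum(occ) - 1) > 1e-9) {
    stop("occupancy must sum to 1", call. = FALSE)
  }
  a <- occ[1:8]    # no-CV layer
  b <- occ[9:16]   # post-CV layer
  dead <- occ[17]

  da <- a * sm$death
  db <- b * sm$death
  sa <- a - da
  sb <- b - db
  new_deaths <- sum(da) + sum(db)

  e <- sa * sm$first_cv          # first CV events, by origin state
  new_first <- sum(e)
  new_subseq <- sum(sb) * sm$subsequent_cv

  a2 <- as.vector((sa - e) %*% sm$matrix)
  b2 <- as.vector((sb + e) %*% sm$matrix)

  alive <- sum(sa) + sum(sb)
  ae <- alive * sm$ae

  out <- stats::setNames(c(a2, b2, dead + new_deaths), compartment_names())
  list(occ = out,
       new_deaths = new_deaths,
       new_first_cv = new_first,
       new_subsequent_cv = new_subseq,
       ae = ae)
}

#' Run the cohort model
#'
#' Simulates the cohort for `horizon_years` of 4-month cycles under one
#' strategy, recording per-cycle occupancy of every compartment and tallies
#' of deaths, first and subsequent CV events, and adverse events. The run is
#' deterministic for fixed inputs.
#'
#' @param ps A `ckd_params` object.
#' @param strategy Strategy code (see [ckd_strategies()]).
#' @param horizon_years Time horizon in years; defaults to the value in
#'   `ps$settings`. Must be a positive integer multiple of the cycle length.
#' @return A `ckd_trace` list: `occupancy` ((cycles + 1) x 17 matrix, row 1 =
#'   cycle 0), `new_deaths`, `new_first_cv`, `new_subsequent_cv` (length
#'   cycles), `ae` (cycles x 3), `strategy`, `cycle_length_years`.
#' @export
#' @examples
#' ps <- reference_parameters(quiet = TRUE)
#' tr <- run_model(ps, "triple")
#' nrow(tr$occupancy)  # 31: cycle 0 plus 30 four-month cycles
run_model <- function(ps, strategy, horizon_years = NULL) {
  if (is.null(horizon_years)) horizon_years <- ps$settings$horizon_years
  cl <- ps$settings$cycle_length_years
  n <- horizon_years / cl
  if (horizon_years <= 0 || abs(n - round(n)) > 1e-9) {
    stop("`horizon_years` must be a positive integer multiple of the ",
         "cycle length", call. = FALSE)
  }
  n <- as.integer(round(n))
  sm <- if (inherits(strategy, "ckd_strategy")) strategy
        else build_strategy_model(ps, strategy)

  occ <- initialize_cohort(ps$baseline)
  occupancy <- matrix(0, n + 1L, 17L,
                      dimnames = list(NULL, compartment_names()))
  occupancy[1L, ] <- occ
  new_deaths <- new_first <- new_subseq <- numeric(n)
  ae <- matrix(0, n, 3L, dimnames = list(NULL, ae_types()))

  for (k in seq_len(n)) {
    st <- step_cycle(occ, sm)
    occ <- st$occ
    occupancy[k + 1L, ] <- occ
    new_deaths[k] <- st$new_deaths
    new_first[k] <- st$new_first_cv
    new_subseq[k] <- st$new_subsequent_cv
    ae[k, ] <- st$ae
  }

  structure(
    list(occupancy = occupancy,
         new_deaths = new_deaths,
         new_first_cv = new_first,
         new_subsequent_cv = new_subseq,
         ae = ae,
         strategy = sm$strategy,
         cycle_length_years = cl,
         horizon_years = horizon_years),
    class = "ckd_trace")
}

#' Export a cohort trace as a tidy per-cycle table
#'
#' @param trace A `ckd_trace` object.
#' @return A tibble with one row per cycle: compartment occupancies and the
#'   event tallies (tallies are `NA` at cycle 0).
#' @export
trace_table <- function(trace) {
  n <- length(trace$new_deaths)
  tibble::as_tibble(cbind(
    data.frame(cycle = 0:n),
    as.data.frame(trace$occupancy),
    data.frame(new_deaths = c(NA, trace$new_deaths),
               new_first_cv = c(NA, trace$new_first_cv),
               new_subsequent_cv = c(NA, trace$new_subsequent_cv)),
    as.data.frame(rbind(NA, trace$ae))))
}
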
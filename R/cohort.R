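#' Treatment-arm cost and discounting parameters
#'
#' @param drug drug label.
#' @param unit_price RMB per injection.
#' @param injections_per_year annual injection count; fractional averages
#'   (e.g. 4.8) are allowed.
#' @param other_annual_cost non-drug annual cost in RMB (inspection,
#'   surgical, nursing and treatment costs are acknowledged but never
#'   itemized in the source material, so the default is 0).
#' @param discount_rate annual discount rate applied to both costs and
#'   QALYs; default 0.035.
#' @param horizon integer number of annual cycles; default 10.
#' @return an object of class `arm_parameters`.
#' @export
arm_parameters <- function(drug, unit_price, injections_per_year,
                           other_annual_cost = 0, discount_rate = 0.035,
                           horizon = 10L) {
  stopifnot(is.character(drug), length(drug) == 1L)
  for (v in list(unit_price = unit_price,
                 injections_per_year = injections_per_year,
                 other_annual_cost = other_annual_cost)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("unit_price, injections_per_year and other_annual_cost must be single finite numbers",
           call. = FALSE)
    }
  }
  if (unit_price < 0 || injections_per_year < 0 || other_annual_cost < 0) {
    stop("prices, injection counts and costs must be non-negative",
         call. = FALSE)
  }
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("discount_rate must lie in [0, 1)", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) {
    stop("horizon must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(drug = drug, unit_price = unit_price,
         injections_per_year = injections_per_year,
         other_annual_cost = other_annual_cost,
         discount_rate = discount_rate, horizon = horizon),
    class = "arm_parameters"
  )
}

#' Discounted sum of a per-cycle value stream
#'
#' Annuity-due timing by default: cycle t contributes
#' \code{value_t / (1 + rate)^t} with t = 0 for the first cycle, so the first
#' year is undiscounted. Set `discount_first_cycle = TRUE` for the
#' annuity-immediate convention (t starts at 1).
#'
#' @param per_cycle numeric vector, one value per cycle.
#' @param rate discount rate per cycle, >= 0.
#' @param discount_first_cycle logical; default `FALSE`.
#' @return the discounted total.
#' @examples
#' discounted_sum(c(100, 100), 0.035) # 100 + 100/1.035
#' @export
discounted_sum <- function(per_cycle, rate, discount_first_cycle = FALSE) {
  stopifnot(is.numeric(per_cycle))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0) {
    stop("rate must be a single non-negative number", call. = FALSE)
  }
  t0 <- if (discount_first_cycle) 1L else 0L
  t <- seq_along(per_cycle) - 1L + t0
  sum(per_cycle / (1 + rate)^t)
}

#' Propagate the baseline cohort through annual Markov cycles
#'
#' Occupancy starts at the renormalized baseline shares and is propagated
#' through the annual transition matrix once per cycle. The per-cycle QALY is
#' the occupancy-weighted mean utility at the start of each cycle (no
#' half-cycle correction unless requested, in which case the mean of
#' start-of-cycle and end-of-cycle occupancy is used).
#'
#' @param space a [state_space()].
#' @param matrix a [build_transition_matrix()] result.
#' @param horizon number of annual cycles.
#' @param half_cycle_correction logical; default `FALSE`.
#' @return an object of class `cohort_trace`: `occupancy` is a
#'   (horizon + 1) x K matrix of state shares (row 1 = baseline),
#'   `per_cycle_qaly` the undiscounted QALY accrued in each of the `horizon`
#'   cycles.
#' @export
simulate_cohort <- function(space, matrix, horizon,
                            half_cycle_correction = FALSE) {
  stopifnot(inherits(space, "state_space"),
            inherits(matrix, "transition_matrix"))
  m <- matrix$matrix
  k <- length(space$states)
  if (!identical(dim(m), c(k, k))) {
    stop("transition matrix dimensions do not match the state space",
         call. = FALSE)
  }
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 1L)
  occ <- base::matrix(NA_real_, horizon + 1L, k,
                      dimnames = list(NULL, space$state_names))
  occ[1L, ] <- space$baseline_shares
  for (t in seq_len(horizon)) {
    occ[t + 1L, ] <- as.numeric(occ[t, , drop = FALSE] %*% m)
  }
  w <- if (half_cycle_correction) {
    (occ[seq_len(horizon), , drop = FALSE] +
       occ[seq_len(horizon) + 1L, , drop = FALSE]) / 2
  } else {
    occ[seq_len(horizon), , drop = FALSE]
  }
  structure(
    list(occupancy = occ,
         per_cycle_qaly = as.numeric(w %*% space$utilities)),
    class = "cohort_trace"
  )
}

#' Run one treatment arm: discounted cost and QALY totals
#'
#' Annual cost is `unit_price * injections_per_year + other_annual_cost`,
#' constant over the horizon; both cost and QALY streams are discounted at
#' the arm's rate with the same timing convention.
#'
#' @param space a [state_space()].
#' @param matrix a transition matrix for this arm's drug.
#' @param arm an [arm_parameters()] object.
#' @param half_cycle_correction,discount_first_cycle conventions passed
#'   through; defaults `FALSE`.
#' @return an object of class `arm_result` with `drug`, `total_cost`,
#'   `total_qaly` and the `cohort_trace` (including `per_cycle_cost`).
#' @export
run_arm <- function(space, matrix, arm, half_cycle_correction = FALSE,
                    discount_first_cycle = FALSE) {
  stopifnot(inherits(arm, "arm_parameters"))
  trace <- simulate_cohort(space, matrix, arm$horizon,
                           half_cycle_correction = half_cycle_correction)
  annual_cost <- arm$unit_price * arm$injections_per_year +
    arm$other_annual_cost
  trace$per_cycle_cost <- rep(annual_cost, arm$horizon)
  structure(
    list(drug = arm$drug,
         total_cost = discounted_sum(trace$per_cycle_cost, arm$discount_rate,
                                     discount_first_cycle),
         total_qaly = discounted_sum(trace$per_cycle_qaly, arm$discount_rate,
                                     discount_first_cycle),
         trace = trace, arm = arm),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost %.3f RMB, %.4f QALYs over %d years\n",
              x$drug, x$total_cost, x$total_qaly, x$arm$horizon))
  invisible(x)
}

#' Export a per-cycle cohort trace as CSV
#'
#' Columns: cycle, one share column per state, cycle QALY, cycle cost, and
#' discounted cumulative cost/QALY.
#'
#' @param result an `arm_result`.
#' @param path output file path.
#' @param discount_first_cycle timing convention used for the cumulatives.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path, discount_first_cycle = FALSE) {
  stopifnot(inherits(result, "arm_result"))
  tr <- result$trace
  h <- length(tr$per_cycle_qaly)
  r <- result$arm$discount_rate
  t0 <- if (discount_first_cycle) 1L else 0L
  disc <- (1 + r)^-(seq_len(h) - 1L + t0)
  df <- data.frame(cycle = seq_len(h) - 1L,
                   tr$occupancy[seq_len(h), , drop = FALSE],
                   cycle_qaly = tr$per_cycle_qaly,
                   cycle_cost = tr$per_cycle_cost,
                   cum_disc_qaly = cumsum(tr$per_cycle_qaly * disc),
                   cum_disc_cost = cumsum(tr$per_cycle_cost * disc),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
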
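#' Specification for a synthetic scenario
#'
#' Describes the random-but-valid scenario family used for property testing:
#' simplex-distributed baseline shares and outcome probabilities, a monotone
#' utility ladder, and positive costs.
#'
#' @param n_states number of BCVA-band states, 2-8.
#' @param outcome_categories 3 (gain/stay/lose one band) or 5 (adds two-band
#'   shifts, as in the PM model).
#' @param utility_range length-2 increasing vector within [0, 1].
#' @param price_range length-2 increasing vector of unit prices (RMB).
#' @param injection_range length-2 increasing vector of annual injections.
#' @param horizon cycles, default 10.
#' @param discount_rate default 0.035.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_states = 5L, outcome_categories = 3L,
                           utility_range = c(0.3, 0.95),
                           price_range = c(1000, 10000),
                           injection_range = c(1, 12),
                           horizon = 10L, discount_rate = 0.035, seed = 1L) {
  n_states <- as.integer(n_states)
  if (is.na(n_states) || n_states < 2L || n_states > 8L) {
    stop("n_states must be an integer in [2, 8]", call. = FALSE)
  }
  if (!outcome_categories %in% c(3L, 5L)) {
    stop("outcome_categories must be 3 or 5", call. = FALSE)
  }
  chk_range <- function(r, lo, hi, nm) {
    if (length(r) != 2L || r[1] >= r[2] || r[1] < lo || r[2] > hi) {
      stop(sprintf("%s must be an increasing pair within [%g, %g]",
                   nm, lo, hi), call. = FALSE)
    }
  }
  chk_range(utility_range, 0, 1, "utility_range")
  chk_range(price_range, 0, Inf, "price_range")
  chk_range(injection_range, 0, Inf, "injection_range")
  structure(list(n_states = n_states,
                 outcome_categories = as.integer(outcome_categories),
                 utility_range = utility_range, price_range = price_range,
                 injection_range = injection_range, horizon = horizon,
                 discount_rate = discount_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Flat (symmetric Dirichlet, concentration 1) draw from the k-simplex.
.rsimplex <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}

#' Generate a random, structurally valid scenario
#'
#' Baseline shares and outcome probabilities come from flat simplex draws
#' (stressing the boundary-folding logic), utilities are sampled uniformly
#' then sorted decreasing, and prices/injections are uniform within their
#' ranges. Deterministic under the spec's seed. The synthetic disease label
#' is `"DME"` for 3-category outcomes and `"PM"` for 5-category (the labels
#' carry the category convention; the parameters are random).
#'
#' @param spec a [synthetic_spec()].
#' @return a validated `cea_scenario`.
#' @examples
#' sc <- generate_scenario(synthetic_spec(seed = 42))
#' run_scenario(sc)
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  k <- spec$n_states
  disease <- if (spec$outcome_categories == 5L) "PM" else "DME"
  shares <- .rsimplex(k)
  util <- sort(stats::runif(k, spec$utility_range[1], spec$utility_range[2]),
               decreasing = TRUE)
  # synthetic letter bands: equal 15-letter bands below an open top band
  hi <- c(Inf, 15 * (k - 1:(k - 1)))
  lo <- c(hi[-1], -Inf)
  states <- lapply(seq_len(k), function(i)
    health_state(sprintf("state_%d", i), lo[i], hi[i], util[i], shares[i]))
  space <- state_space(disease, states)
  cats <- if (spec$outcome_categories == 5L) c("+30", "+15", "0", "-15", "-30")
          else c("+15", "0", "-15")
  draw_outcomes <- function(drug) {
    p <- .rsimplex(length(cats))
    names(p) <- cats
    outcome_distribution(drug, disease, p)
  }
  draw_arm <- function(drug) {
    arm_parameters(drug,
                   stats::runif(1, spec$price_range[1], spec$price_range[2]),
                   stats::runif(1, spec$injection_range[1],
                                spec$injection_range[2]),
                   discount_rate = spec$discount_rate,
                   horizon = spec$horizon)
  }
  cea_scenario(disease, "synthetic", space,
               draw_outcomes("drug_a"), draw_outcomes("drug_b"),
               draw_arm("drug_a"), draw_arm("drug_b"), wtp_threshold())
}

#' Closed-form QALY total under identity transitions
#'
#' Independent oracle for the cohort engine: when every state keeps all its
#' mass, the per-cycle QALY is constant at baseline . utilities, so the
#' discounted total is that dot product times the annuity factor
#' \code{sum((1 + r)^-(0:(T-1)))}. Computed without touching the engine.
#'
#' @param scenario a `cea_scenario` (its transition structure is ignored;
#'   the oracle assumes stay-probability 1).
#' @param discount_first_cycle timing convention, default `FALSE`.
#' @return the closed-form discounted QALY total.
#' @export
closed_form_qaly_oracle <- function(scenario, discount_first_cycle = FALSE) {
  stopifnot(inherits(scenario, "cea_scenario"))
  r <- scenario$arm_a$discount_rate
  horizon <- scenario$arm_a$horizon
  t0 <- if (discount_first_cycle) 1L else 0L
  annuity <- sum((1 + r)^-(seq_len(horizon) - 1L + t0))
  sum(scenario$space$baseline_shares * scenario$space$utilities) * annuity
}
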
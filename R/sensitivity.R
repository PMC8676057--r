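#' Deterministic sweep specification
#'
#' Either an explicit value list or relative fluctuations around the
#' scenario's point estimate (e.g. `fluctuations = c(-0.10, -0.05, 0, 0.05,
#' 0.10)` for the +/-5%/+/-10% price analysis).
#'
#' @param parameter one of `"unit_price_a"`, `"unit_price_b"`,
#'   `"injections_a"`, `"injections_b"`.
#' @param values explicit swept values (>= 0), or `NULL`.
#' @param fluctuations relative changes applied to the point estimate, or
#'   `NULL`. Exactly one of `values`/`fluctuations` must be given.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, values = NULL, fluctuations = NULL) {
  parameter <- match.arg(parameter, c("unit_price_a", "unit_price_b",
                                      "injections_a", "injections_b"))
  if (is.null(values) == is.null(fluctuations)) {
    stop("give exactly one of `values` or `fluctuations`", call. = FALSE)
  }
  if (!is.null(values) && (!length(values) || any(values < 0))) {
    stop("swept values must be a non-empty vector of non-negative numbers",
         call. = FALSE)
  }
  if (!is.null(fluctuations) && !length(fluctuations)) {
    stop("`fluctuations` must be non-empty", call. = FALSE)
  }
  structure(list(parameter = parameter, values = values,
                 fluctuations = fluctuations),
            class = "sweep_spec")
}

.sweep_point_estimate <- function(scenario, parameter) {
  switch(parameter,
         unit_price_a = scenario$arm_a$unit_price,
         unit_price_b = scenario$arm_b$unit_price,
         injections_a = scenario$arm_a$injections_per_year,
         injections_b = scenario$arm_b$injections_per_year)
}

.sweep_values <- function(scenario, spec) {
  if (!is.null(spec$values)) return(spec$values)
  pe <- .sweep_point_estimate(scenario, spec$parameter)
  v <- pe * (1 + spec$fluctuations)
  if (any(v < 0)) stop("fluctuations produce negative values", call. = FALSE)
  v
}

.apply_sweep_value <- function(scenario, parameter, value) {
  side <- if (endsWith(parameter, "_a")) "arm_a" else "arm_b"
  field <- if (startsWith(parameter, "unit_price")) "unit_price"
           else "injections_per_year"
  scenario[[side]][[field]] <- value
  scenario
}

#' One-way deterministic sensitivity sweep
#'
#' Re-runs the full comparison at each swept value with every other
#' parameter held at its point estimate.
#'
#' @param scenario a `cea_scenario`.
#' @param spec a [sweep_spec()].
#' @return data.frame with one row per swept value: the parameter value,
#'   delta cost/QALY, ICER, dominance and the cost-effectiveness decision.
#' @examples
#' sc <- suppressWarnings(load_builtin("DME"))
#' one_way_sweep(sc, sweep_spec("unit_price_a",
#'                              fluctuations = c(-0.1, -0.05, 0, 0.05, 0.1)))
#' @export
one_way_sweep <- function(scenario, spec) {
  stopifnot(inherits(scenario, "cea_scenario"), inherits(spec, "sweep_spec"))
  values <- .sweep_values(scenario, spec)
  rows <- lapply(values, function(v) {
    cmp <- run_scenario(.apply_sweep_value(scenario, spec$parameter, v))
    data.frame(parameter = spec$parameter, value = v,
               cost_a = cmp$cost_a, cost_b = cmp$cost_b,
               qaly_a = cmp$qaly_a, qaly_b = cmp$qaly_b,
               delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
               icer = cmp$icer, dominance = cmp$dominance,
               cost_effective = cmp$cost_effective,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way deterministic sensitivity sweep
#'
#' Cartesian grid over two swept parameters; every cell is a full
#' comparison.
#'
#' @param scenario a `cea_scenario`.
#' @param spec_a,spec_b [sweep_spec()]s for the two parameters.
#' @param max_cells guard against runaway grids; default 10,000.
#' @return data.frame with one row per grid cell.
#' @export
two_way_sweep <- function(scenario, spec_a, spec_b, max_cells = 10000L) {
  stopifnot(inherits(scenario, "cea_scenario"),
            inherits(spec_a, "sweep_spec"), inherits(spec_b, "sweep_spec"))
  va <- .sweep_values(scenario, spec_a)
  vb <- .sweep_values(scenario, spec_b)
  if (length(va) * length(vb) > max_cells) {
    stop(sprintf("grid has %d cells; raise `max_cells` or sweep fewer values",
                 length(va) * length(vb)), call. = FALSE)
  }
  grid <- expand.grid(value_a = va, value_b = vb)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- .apply_sweep_value(scenario, spec_a$parameter, grid$value_a[i])
    sc <- .apply_sweep_value(sc, spec_b$parameter, grid$value_b[i])
    cmp <- run_scenario(sc)
    data.frame(parameter_a = spec_a$parameter, value_a = grid$value_a[i],
               parameter_b = spec_b$parameter, value_b = grid$value_b[i],
               delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
               icer = cmp$icer, dominance = cmp$dominance,
               cost_effective = cmp$cost_effective,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply the negotiated drug prices to a scenario
#'
#' Named preset for the reimbursement prices negotiated for 2020-2021:
#' conbercept 4,160 RMB, ranibizumab 3,950 RMB per injection.
#'
#' @param scenario a `cea_scenario`.
#' @return the scenario with both unit prices replaced.
#' @export
negotiated_price_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  scenario$arm_a$unit_price <- .negotiated_prices[["conbercept"]]
  scenario$arm_b$unit_price <- .negotiated_prices[["ranibizumab"]]
  scenario
}

#' PSA configuration
#'
#' Only costs are randomized: each arm's total discounted cost is drawn from
#' a gamma distribution with mean equal to the deterministic total and the
#' configured coefficient of variation (shape = 1/cv^2, scale = mean * cv^2),
#' so the draw mean equals the point estimate. Utilities and transition
#' probabilities stay fixed. No published variance exists for the costs, so
#' `cost_cv` is an explicit modelling choice (default 0.2).
#'
#' @param iterations Monte-Carlo iterations, default 10,000.
#' @param seed integer RNG seed.
#' @param cost_cv coefficient of variation of the gamma cost draws, > 0.
#' @param wtp_grid WTP values (RMB/QALY) at which the CEAC is evaluated.
#' @return an object of class `psa_config`.
#' @export
psa_config <- function(iterations = 10000L, seed = 1L, cost_cv = 0.2,
                       wtp_grid = seq(0, 400000, by = 20000)) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("iterations must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cost_cv) || cost_cv <= 0) {
    stop("cost_cv must be positive", call. = FALSE)
  }
  structure(list(iterations = iterations, seed = as.integer(seed),
                 cost_cv = cost_cv, wtp_grid = wtp_grid),
            class = "psa_config")
}

# Gamma draws with mean m and coefficient of variation cv; degenerate at m
# when m == 0 (gamma scale would be 0).
.rgamma_mean_cv <- function(n, m, cv) {
  if (m == 0) return(rep(0, n))
  stats::rgamma(n, shape = 1 / cv^2, scale = m * cv^2)
}

#' Probabilistic sensitivity analysis with gamma-distributed costs
#'
#' Runs the deterministic model once, then draws both arms' total costs
#' independently from gamma distributions centred on the deterministic
#' totals. The CEAC point at each WTP is the fraction of iterations in which
#' arm a's net monetary benefit strictly exceeds arm b's (ties count against
#' arm a).
#'
#' @param scenario a `cea_scenario`.
#' @param config a [psa_config()].
#' @return an object of class `psa_result`: `sample` (data.frame with one
#'   row per iteration), `ceac` (data.frame wtp / prob_a / prob_b),
#'   `base_case` (the deterministic comparison) and `config`.
#' @export
run_psa <- function(scenario, config = psa_config()) {
  stopifnot(inherits(scenario, "cea_scenario"), inherits(config, "psa_config"))
  base <- run_scenario(scenario)
  n <- config$iterations
  # one seeded generator; arm draws taken as separate independent vectors
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  cost_a <- .rgamma_mean_cv(n, base$cost_a, config$cost_cv)
  cost_b <- .rgamma_mean_cv(n, base$cost_b, config$cost_cv)
  sample <- data.frame(
    iteration = seq_len(n),
    cost_a = cost_a, cost_b = cost_b,
    qaly_a = base$qaly_a, qaly_b = base$qaly_b,
    delta_cost = cost_a - cost_b,
    delta_qaly = base$qaly_a - base$qaly_b
  )
  structure(
    list(sample = sample,
         ceac = ceac_curve(sample, config$wtp_grid),
         base_case = base, config = config),
    class = "psa_result"
  )
}

#' Cost-effectiveness acceptability curve from a PSA sample
#'
#' @param psa_sample a `psa_result` or its `sample` data.frame (columns
#'   `cost_a`, `cost_b`, `qaly_a`, `qaly_b`).
#' @param wtp_grid non-empty vector of WTP values.
#' @return data.frame with columns `wtp`, `prob_a`, `prob_b`
#'   (`prob_a + prob_b = 1` at every point; ties count toward arm b).
#' @export
ceac_curve <- function(psa_sample, wtp_grid) {
  if (inherits(psa_sample, "psa_result")) psa_sample <- psa_sample$sample
  stopifnot(is.data.frame(psa_sample), nrow(psa_sample) >= 1L,
            length(wtp_grid) >= 1L)
  prob_a <- vapply(wtp_grid, function(w) {
    nmb_a <- net_monetary_benefit(psa_sample$cost_a, psa_sample$qaly_a, w)
    nmb_b <- net_monetary_benefit(psa_sample$cost_b, psa_sample$qaly_b, w)
    mean(nmb_a > nmb_b)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_a = prob_a, prob_b = 1 - prob_a)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, cost CV %.2f, seed %d\n",
              x$config$iterations, x$config$cost_cv, x$config$seed))
  w <- x$base_case$wtp
  i <- which.min(abs(x$ceac$wtp - w))
  cat(sprintf("  P(%s cost-effective) ~ %.3f near WTP %s RMB/QALY\n",
              x$base_case$label_a, x$ceac$prob_a[i],
              formatC(x$ceac$wtp[i], format = "d", big.mark = ",")))
  invisible(x)
}

#' Export a PSA sample and CEAC as CSV
#'
#' @param psa a `psa_result`.
#' @param sample_path,ceac_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_psa <- function(psa, sample_path = NULL, ceac_path = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (!is.null(sample_path)) {
    utils::write.csv(psa$sample, sample_path, row.names = FALSE)
  }
  if (!is.null(ceac_path)) {
    utils::write.csv(psa$ceac, ceac_path, row.names = FALSE)
  }
  invisible(c(sample_path, ceac_path))
}
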
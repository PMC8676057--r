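# Built-in parameter library: annual letter-change outcome probabilities per
# drug/disease, injection counts per scenario mode, and unit prices.

.builtin_outcomes <- list(
  AMD = list(
    conbercept  = c("+15" = 0.3210, "0" = 0.5062, "-15" = 0.1728),
    ranibizumab = c("+15" = 0.4300, "0" = 0.4820, "-15" = 0.0880)
  ),
  DME = list(
    conbercept  = c("+15" = 0.2500, "0" = 0.7232, "-15" = 0.0268),
    ranibizumab = c("+15" = 0.1850, "0" = 0.7850, "-15" = 0.0300)
  ),
  PM = list(
    conbercept  = c("+30" = 0.1832, "+15" = 0.5344, "0" = 0.2519,
                    "-15" = 0.0305, "-30" = 0.0000),
    ranibizumab = c("+30" = 0.2003, "+15" = 0.4913, "0" = 0.2755,
                    "-15" = 0.0320, "-30" = 0.0007)
  )
)

# Annual injections: real-world averages and RCT first-year counts (applied
# to every model year under the constant-injection assumption).
.builtin_injections <- list(
  real_world = list(AMD = c(conbercept = 4.8,  ranibizumab = 5.4),
                    DME = c(conbercept = 5.5,  ranibizumab = 6.2),
                    PM  = c(conbercept = 1.8,  ranibizumab = 1.92)),
  rct        = list(AMD = c(conbercept = 5.8,  ranibizumab = 11.5),
                    DME = c(conbercept = 9.48, ranibizumab = 7.9),
                    PM  = c(conbercept = 3.76, ranibizumab = 3.9))
)

# Per-injection prices (RMB): 2019 reimbursement list, and the prices
# negotiated for 2020-2021.
.builtin_prices <- c(conbercept = 5550, ranibizumab = 5700)
.negotiated_prices <- c(conbercept = 4160, ranibizumab = 3950)

#' Assemble a comparison scenario
#'
#' Bundles a state space, both arms' outcome distributions and cost
#' parameters, and the willingness-to-pay threshold into one runnable unit.
#'
#' @param disease one of `"AMD"`, `"DME"`, `"PM"`.
#' @param mode `"real_world"` or `"rct"` (or any label for user scenarios).
#' @param space a [state_space()].
#' @param outcomes_a,outcomes_b [outcome_distribution()]s for arm a/b.
#' @param arm_a,arm_b [arm_parameters()] for arm a/b.
#' @param wtp a [wtp_threshold()].
#' @param blindness_absorbing logical model-structure toggle, default FALSE.
#' @return an object of class `cea_scenario`.
#' @export
cea_scenario <- function(disease, mode, space, outcomes_a, outcomes_b,
                         arm_a, arm_b, wtp = wtp_threshold(),
                         blindness_absorbing = FALSE) {
  sc <- structure(
    list(disease = disease, mode = mode, space = space,
         outcomes_a = outcomes_a, outcomes_b = outcomes_b,
         arm_a = arm_a, arm_b = arm_b, wtp = wtp,
         blindness_absorbing = isTRUE(blindness_absorbing)),
    class = "cea_scenario"
  )
  problems <- validate_scenario(sc)
  if (length(problems)) {
    stop(paste0("invalid scenario:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  sc
}

#' Validate a scenario, collecting every violation
#'
#' @param scenario a `cea_scenario` (or a bare list with the same fields).
#' @return character vector of violations; empty when valid.
#' @export
validate_scenario <- function(scenario) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(inherits(scenario$space, "state_space"), "space: not a state_space")
  for (side in c("a", "b")) {
    od <- scenario[[paste0("outcomes_", side)]]
    arm <- scenario[[paste0("arm_", side)]]
    chk(inherits(od, "outcome_distribution"),
        sprintf("outcomes_%s: not an outcome_distribution", side))
    chk(inherits(arm, "arm_parameters"),
        sprintf("arm_%s: not arm_parameters", side))
    if (inherits(od, "outcome_distribution")) {
      s <- sum(od$probs)
      chk(abs(s - 1) <= 5e-4,
          sprintf("outcomes_%s: probabilities sum to %.4f (must be 1 within 5e-4)",
                  side, s))
      chk(inherits(scenario$space, "state_space") &&
            od$disease == scenario$space$disease,
          sprintf("outcomes_%s: disease does not match the state space", side))
    }
  }
  if (inherits(scenario$arm_a, "arm_parameters") &&
      inherits(scenario$arm_b, "arm_parameters")) {
    chk(scenario$arm_a$horizon == scenario$arm_b$horizon,
        "arms: horizons differ")
  }
  chk(inherits(scenario$wtp, "wtp_threshold"), "wtp: not a wtp_threshold")
  problems
}

#' Load one of the six built-in scenarios
#'
#' Three diseases crossed with two injection-count settings: `real_world`
#' (10-year average annual injections) and `rct` (trial first-year counts,
#' held constant). Arm a is always conbercept, arm b ranibizumab, both at
#' the 2019 reimbursement-list prices.
#'
#' @param disease one of `"AMD"`, `"DME"`, `"PM"`.
#' @param mode `"real_world"` (default) or `"rct"`.
#' @param discount_rate,horizon overrides for the defaults 0.035 and 10.
#' @param prices named vector with `conbercept` and `ranibizumab` unit
#'   prices; default the reimbursement-list prices (5,550 / 5,700 RMB).
#' @return a `cea_scenario`.
#' @examples
#' sc <- load_builtin("AMD")
#' sc$arm_a$injections_per_year # 4.8
#' @export
load_builtin <- function(disease, mode = c("real_world", "rct"),
                         discount_rate = 0.035, horizon = 10L,
                         prices = .builtin_prices) {
  if (!disease %in% c("AMD", "DME", "PM")) {
    stop(sprintf("unknown disease '%s'; valid: AMD, DME, PM", disease),
         call. = FALSE)
  }
  mode <- match.arg(mode)
  space <- build_state_space(disease)
  inj <- .builtin_injections[[mode]][[disease]]
  od <- .builtin_outcomes[[disease]]
  cea_scenario(
    disease = disease, mode = mode, space = space,
    outcomes_a = outcome_distribution("conbercept", disease, od$conbercept),
    outcomes_b = outcome_distribution("ranibizumab", disease, od$ranibizumab),
    arm_a = arm_parameters("conbercept", prices[["conbercept"]],
                           inj[["conbercept"]], discount_rate = discount_rate,
                           horizon = horizon),
    arm_b = arm_parameters("ranibizumab", prices[["ranibizumab"]],
                           inj[["ranibizumab"]], discount_rate = discount_rate,
                           horizon = horizon),
    wtp = wtp_threshold()
  )
}

#' List the built-in scenario keys
#' @return data.frame of disease/mode combinations with injection counts.
#' @export
list_builtin_scenarios <- function() {
  rows <- expand.grid(disease = c("AMD", "DME", "PM"),
                      mode = c("real_world", "rct"),
                      stringsAsFactors = FALSE)
  rows$injections_conbercept <- mapply(function(d, m)
    .builtin_injections[[m]][[d]][["conbercept"]], rows$disease, rows$mode)
  rows$injections_ranibizumab <- mapply(function(d, m)
    .builtin_injections[[m]][[d]][["ranibizumab"]], rows$disease, rows$mode)
  rows
}

#' Run a scenario end to end
#'
#' Builds both arms' transition matrices, propagates the cohort, and returns
#' the comparison (with the two `arm_result`s attached as attributes
#' `result_a` / `result_b`).
#'
#' @param scenario a `cea_scenario`.
#' @param half_cycle_correction,discount_first_cycle convention toggles.
#' @return a [compare_arms()] result.
#' @export
run_scenario <- function(scenario, half_cycle_correction = FALSE,
                         discount_first_cycle = FALSE) {
  stopifnot(inherits(scenario, "cea_scenario"))
  tm_a <- build_transition_matrix(scenario$outcomes_a, scenario$space,
                                  scenario$blindness_absorbing)
  tm_b <- build_transition_matrix(scenario$outcomes_b, scenario$space,
                                  scenario$blindness_absorbing)
  ra <- run_arm(scenario$space, tm_a, scenario$arm_a,
                half_cycle_correction, discount_first_cycle)
  rb <- run_arm(scenario$space, tm_b, scenario$arm_b,
                half_cycle_correction, discount_first_cycle)
  cmp <- compare_arms(ra, rb, scenario$wtp)
  attr(cmp, "result_a") <- ra
  attr(cmp, "result_b") <- rb
  cmp
}

# --- scenario config (JSON) -------------------------------------------------

scenario_to_list <- function(scenario) {
  sp <- as.data.frame(scenario$space)
  arm_list <- function(arm) arm[c("drug", "unit_price", "injections_per_year",
                                  "other_annual_cost", "discount_rate",
                                  "horizon")]
  list(
    disease = scenario$disease, mode = scenario$mode,
    blindness_absorbing = scenario$blindness_absorbing,
    states = sp,
    outcomes_a = list(drug = scenario$outcomes_a$drug,
                      probs = as.list(scenario$outcomes_a$probs)),
    outcomes_b = list(drug = scenario$outcomes_b$drug,
                      probs = as.list(scenario$outcomes_b$probs)),
    arm_a = arm_list(scenario$arm_a), arm_b = arm_list(scenario$arm_b),
    wtp = scenario$wtp[c("gdp_per_capita", "multiplier")]
  )
}

#' Write a scenario to a JSON config file
#'
#' Full-precision, human-editable; round-trips losslessly through
#' [read_scenario_config()].
#'
#' @param scenario a `cea_scenario`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "cea_scenario"))
  jsonlite::write_json(scenario_to_list(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario from a JSON config file
#'
#' When `base` names a built-in disease/mode, fields present in the file
#' override the built-in scenario and everything else keeps its default
#' (layered-override semantics); a full config stands alone. All invariant
#' violations are reported together.
#'
#' @param path config file path.
#' @return a validated `cea_scenario`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("cannot parse '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  scenario_from_list(cfg)
}

scenario_from_list <- function(cfg) {
  if (is.null(cfg$disease)) stop("config missing 'disease'", call. = FALSE)
  # layered overrides: start from the builtin when disease/mode are known
  base <- NULL
  if (cfg$disease %in% c("AMD", "DME", "PM") &&
      !is.null(cfg$mode) && cfg$mode %in% c("real_world", "rct")) {
    base <- suppressWarnings(load_builtin(cfg$disease, cfg$mode))
  }
  space <- if (!is.null(cfg$states)) {
    st <- cfg$states
    state_space(cfg$disease, lapply(seq_len(nrow(st)), function(i) {
      health_state(st$state[i],
                   if (is.na(st$letters_low[i])) -Inf else st$letters_low[i],
                   if (is.na(st$letters_high[i])) Inf else st$letters_high[i],
                   st$utility[i], st$baseline_share[i])
    }))
  } else if (!is.null(base)) base$space else build_state_space(cfg$disease)

  get_outcomes <- function(side) {
    o <- cfg[[paste0("outcomes_", side)]]
    if (is.null(o)) return(base[[paste0("outcomes_", side)]])
    outcome_distribution(o$drug %||% side, cfg$disease, unlist(o$probs))
  }
  get_arm <- function(side) {
    a <- cfg[[paste0("arm_", side)]]
    b <- if (!is.null(base)) base[[paste0("arm_", side)]] else NULL
    if (is.null(a) && is.null(b)) {
      stop(sprintf("config missing 'arm_%s' and no builtin base applies", side),
           call. = FALSE)
    }
    pick <- function(field, default) a[[field]] %||%
      (if (!is.null(b)) b[[field]] else default)
    arm_parameters(pick("drug", side), pick("unit_price", NULL),
                   pick("injections_per_year", NULL),
                   pick("other_annual_cost", 0),
                   pick("discount_rate", 0.035), pick("horizon", 10L))
  }
  wtp <- if (!is.null(cfg$wtp)) {
    wtp_threshold(cfg$wtp$gdp_per_capita %||% 70892, cfg$wtp$multiplier %||% 3)
  } else if (!is.null(base)) base$wtp else wtp_threshold()

  cea_scenario(cfg$disease, cfg$mode %||% "custom", space,
               get_outcomes("a"), get_outcomes("b"),
               get_arm("a"), get_arm("b"), wtp,
               blindness_absorbing = isTRUE(cfg$blindness_absorbing))
}

# --- reports ----------------------------------------------------------------

#' Write comparison results as CSV or JSON
#'
#' CSV mirrors the published table layout (Strategy, Cost (RMB), Incremental
#' costs, Effectiveness (QALYs), Incremental effectiveness, CER, ICER) with
#' 3-decimal rounding; JSON keeps full precision.
#'
#' @param results a `cea_comparison`, or a named list of them (one section
#'   per element).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "cea_comparison")) results <- list(results)
  if (!length(results)) {
    if (format == "csv") {
      header <- data.frame(Strategy = character(),
                           `Cost (RMB)` = numeric(),
                           `Incremental costs` = numeric(),
                           `Effectiveness (QALYs)` = numeric(),
                           `Incremental effectiveness` = numeric(),
                           CER = numeric(), ICER = numeric(),
                           check.names = FALSE)
      utils::write.csv(header, path, row.names = FALSE, na = "")
    } else {
      jsonlite::write_json(list(), path, auto_unbox = TRUE)
    }
    return(invisible(path))
  }
  if (format == "csv") {
    dfs <- lapply(seq_along(results), function(i) {
      df <- as.data.frame(results[[i]])
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], round, 3)
      if (!is.null(names(results)) && nzchar(names(results)[i])) {
        df <- cbind(Scenario = c(names(results)[i], ""), df)
      }
      df
    })
    utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, na = "")
  } else {
    out <- lapply(results, function(x)
      unclass(x)[c("label_a", "label_b", "cost_a", "cost_b", "qaly_a",
                   "qaly_b", "delta_cost", "delta_qaly", "cer_a", "cer_b",
                   "icer", "dominance", "wtp", "nmb_a", "nmb_b",
                   "cost_effective")])
    if (is.null(names(results))) names(out) <- seq_along(out)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
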
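#' Willingness-to-pay threshold from per-capita GDP
#'
#' The conventional developing-country ceiling of three times per-capita
#' GDP per QALY gained. The default GDP is China's 2019 per-capita figure,
#' 70,892 RMB, giving a threshold of 212,676 RMB/QALY.
#'
#' @param gdp_per_capita per-capita GDP in RMB; must be > 0.
#' @param multiplier threshold multiplier, default 3.
#' @return an object of class `wtp_threshold` with `threshold =
#'   gdp_per_capita * multiplier`.
#' @examples
#' wtp_threshold()$threshold # 212676
#' @export
wtp_threshold <- function(gdp_per_capita = 70892, multiplier = 3) {
  if (gdp_per_capita <= 0 || multiplier <= 0) {
    stop("gdp_per_capita and multiplier must be positive", call. = FALSE)
  }
  structure(list(gdp_per_capita = gdp_per_capita, multiplier = multiplier,
                 threshold = gdp_per_capita * multiplier),
            class = "wtp_threshold")
}

#' Net monetary benefit
#'
#' \code{NMB = wtp * qaly - cost}. NMB comparisons give decision rules that
#' remain interpretable when the ICER is negative (sign alone cannot
#' distinguish a dominant from a dominated strategy).
#'
#' @param cost total cost (RMB).
#' @param qaly total QALYs.
#' @param wtp willingness to pay (RMB/QALY), >= 0.
#' @return NMB in RMB.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  wtp * qaly - cost
}

#' Compare two treatment arms: ICER, CERs, dominance, NMB decision
#'
#' Computes incremental cost and effect of arm a over arm b, their
#' cost-effectiveness ratios, the ICER (undefined when the QALY difference
#' is zero), a dominance classification, and the NMB-based cost-effectiveness
#' decision at the supplied willingness-to-pay threshold.
#'
#' Dominance: `a_dominant` when a costs less without losing QALYs (or saves
#' money at equal effect); `b_dominant` in the mirror case; `trade_off` when
#' one arm is both costlier and more effective. The decision routes through
#' NMB, which for a positive QALY difference is equivalent to ICER <= WTP.
#'
#' @param result_a,result_b [run_arm()] results, or lists with `total_cost`
#'   and `total_qaly` (so published totals can be fed directly).
#' @param wtp a [wtp_threshold()] object or a single RMB/QALY number.
#' @return an object of class `cea_comparison`.
#' @examples
#' a <- list(drug = "conbercept", total_cost = 285285.597, total_qaly = 7.825)
#' b <- list(drug = "ranibizumab", total_cost = 329620.521, total_qaly = 8.490)
#' compare_arms(a, b, wtp_threshold())
#' @export
compare_arms <- function(result_a, result_b, wtp = wtp_threshold()) {
  if (inherits(wtp, "wtp_threshold")) wtp <- wtp$threshold
  stopifnot(is.numeric(wtp), length(wtp) == 1L, wtp >= 0)
  ca <- result_a$total_cost; cb <- result_b$total_cost
  qa <- result_a$total_qaly; qb <- result_b$total_qaly
  if (qa <= 0 || qb <= 0) {
    stop("total QALYs must be positive in both arms", call. = FALSE)
  }
  dc <- ca - cb
  de <- qa - qb
  icer <- if (de != 0) dc / de else NA_real_
  dominance <- if (dc < 0 && de > 0) "a_dominant"
    else if (dc > 0 && de < 0) "b_dominant"
    else if (de == 0 && dc < 0) "a_dominant"
    else if (de == 0 && dc > 0) "b_dominant"
    else "trade_off"
  nmb_a <- net_monetary_benefit(ca, qa, wtp)
  nmb_b <- net_monetary_benefit(cb, qb, wtp)
  if (dc == 0 && de == 0) {
    warning("arms are exactly indifferent; reporting not cost-effective",
            call. = FALSE)
  }
  structure(
    list(label_a = result_a$drug %||% "a", label_b = result_b$drug %||% "b",
         cost_a = ca, cost_b = cb, qaly_a = qa, qaly_b = qb,
         delta_cost = dc, delta_qaly = de,
         cer_a = ca / qa, cer_b = cb / qb, icer = icer,
         dominance = dominance, wtp = wtp, nmb_a = nmb_a, nmb_b = nmb_b,
         cost_effective = nmb_a > nmb_b),
    class = "cea_comparison"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Cost-effectiveness decision at the willingness-to-pay threshold
#'
#' Arm a is cost-effective versus arm b iff \code{NMB_a > NMB_b} at the
#' comparison's threshold. For a positive QALY difference this is ICER < WTP;
#' for a negative one it is ICER > WTP (forgone QALYs must be cheaper than
#' the savings). Exact ties report not cost-effective.
#'
#' @param comparison a [compare_arms()] result.
#' @return logical scalar.
#' @export
decision_at_wtp <- function(comparison) {
  stopifnot(inherits(comparison, "cea_comparison"))
  comparison$cost_effective
}

#' @export
print.cea_comparison <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 3, big.mark = ",")
  cat(sprintf("<cea_comparison> %s vs %s (WTP %s RMB/QALY)\n",
              x$label_a, x$label_b, fmt(x$wtp)))
  cat(sprintf("  cost:  %s vs %s  (delta %s)\n",
              fmt(x$cost_a), fmt(x$cost_b), fmt(x$delta_cost)))
  cat(sprintf("  QALY:  %.3f vs %.3f  (delta %.3f)\n",
              x$qaly_a, x$qaly_b, x$delta_qaly))
  cat(sprintf("  CER:   %s vs %s\n", fmt(x$cer_a), fmt(x$cer_b)))
  cat(sprintf("  ICER:  %s\n",
              if (is.na(x$icer)) "undefined (equal effect)" else fmt(x$icer)))
  cat(sprintf("  dominance: %s; %s cost-effective at WTP: %s\n",
              x$dominance, x$label_a,
              if (x$cost_effective) "yes" else "no"))
  invisible(x)
}

#' @export
as.data.frame.cea_comparison <- function(x, ...) {
  data.frame(
    Strategy = c(x$label_a, x$label_b),
    `Cost (RMB)` = c(x$cost_a, x$cost_b),
    `Incremental costs` = c(x$delta_cost, NA_real_),
    `Effectiveness (QALYs)` = c(x$qaly_a, x$qaly_b),
    `Incremental effectiveness` = c(x$delta_qaly, NA_real_),
    CER = c(x$cer_a, x$cer_b),
    ICER = c(x$icer, NA_real_),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
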
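test_that("WTP threshold is GDP times multiplier", {
  expect_equal(wtp_threshold()$threshold, 212676)
  expect_equal(wtp_threshold(70892, 3)$threshold, 212676)
  expect_equal(wtp_threshold(1, 1)$threshold, 1)
  expect_equal(wtp_threshold(50000, 3)$threshold, 150000)
  expect_error(wtp_threshold(0), "positive")
  expect_error(wtp_threshold(1, -2), "positive")
})

test_that("NMB arithmetic", {
  expect_equal(net_monetary_benefit(0, 1, 212676), 212676)
  expect_equal(net_monetary_benefit(212676, 1, 212676), 0)
  expect_equal(net_monetary_benefit(100, 0.5, 200), 0)
  expect_error(net_monetary_benefit(1, 1, -1), "non-negative")
})

test_that("compare_arms reproduces published real-world comparison arithmetic", {
  for (i in seq_len(nrow(published_table6))) {
    row <- published_table6[i, ]
    cmp <- compare_arms(
      list(drug = "conbercept", total_cost = row$cost_a, total_qaly = row$qaly_a),
      list(drug = "ranibizumab", total_cost = row$cost_b, total_qaly = row$qaly_b),
      wtp_threshold())
    expect_equal(cmp$delta_cost, row$delta_cost, tolerance = 1e-9)
    expect_equal(cmp$delta_qaly, row$delta_qaly, tolerance = 1e-9)
    expect_equal(cmp$icer, row$delta_cost / row$delta_qaly, tolerance = 1e-12)
    expect_equal(cmp$cer_a, row$cost_a / row$qaly_a, tolerance = 1e-12)
    expect_equal(cmp$cer_b, row$cost_b / row$qaly_b, tolerance = 1e-12)
  }
  # AMD: cheaper and less effective -> trade-off quadrant
  amd <- compare_arms(list(total_cost = 285285.597, total_qaly = 7.825),
                      list(total_cost = 329620.521, total_qaly = 8.490))
  expect_equal(amd$dominance, "trade_off")
  expect_equal(amd$icer, 66669.059, tolerance = 1e-5)
  # DME/PM: cheaper and more effective -> dominant
  dme <- compare_arms(list(total_cost = 322763.734, total_qaly = 6.973),
                      list(total_cost = 378453.191, total_qaly = 6.758))
  expect_equal(dme$dominance, "a_dominant")
  expect_true(dme$cost_effective)
})

test_that("equal-effect comparisons leave the ICER undefined", {
  cmp <- compare_arms(list(total_cost = 100, total_qaly = 5),
                      list(total_cost = 200, total_qaly = 5), 100)
  expect_true(is.na(cmp$icer))
  expect_equal(cmp$dominance, "a_dominant") # strictly cheaper, equal effect
  expect_true(cmp$cost_effective)
  expect_error(compare_arms(list(total_cost = 1, total_qaly = 0),
                            list(total_cost = 1, total_qaly = 1)), "positive")
})

test_that("exact indifference warns and reports not cost-effective", {
  expect_warning(cmp <- compare_arms(list(total_cost = 100, total_qaly = 5),
                                     list(total_cost = 100, total_qaly = 5),
                                     100), "indifferent")
  expect_false(cmp$cost_effective)
})

test_that("dominant arms are cost-effective at any threshold", {
  for (w in c(0, 1, 212676, 1e7)) {
    cmp <- compare_arms(list(total_cost = 50, total_qaly = 2),
                        list(total_cost = 100, total_qaly = 1), w)
    expect_equal(cmp$dominance, "a_dominant")
    expect_true(cmp$cost_effective)
  }
})

test_that("ICER is scale-equivariant and dominance classes are exhaustive", {
  set.seed(101)
  for (i in seq_len(200)) {
    # de bounded below so that qb + k*de stays positive for k up to 10
    dc <- rnorm(1, 0, 1e5); de <- runif(1, -0.15, 1)
    qb <- runif(1, 2, 10); cb <- runif(1, 1e4, 1e6)
    cmp <- compare_arms(list(total_cost = cb + dc, total_qaly = qb + de),
                        list(total_cost = cb, total_qaly = qb), 212676)
    expect_true(cmp$dominance %in% c("a_dominant", "b_dominant", "trade_off"))
    if (de != 0) {
      k <- runif(1, 0.1, 10)
      scaled <- compare_arms(
        list(total_cost = cb + k * dc, total_qaly = qb + k * de),
        list(total_cost = cb, total_qaly = qb), 212676)
      expect_equal(scaled$icer, cmp$icer, tolerance = 1e-8)
    }
  }
})

test_that("NMB and ICER decisions agree when the QALY difference is positive", {
  set.seed(202)
  n <- 10000
  dc <- rnorm(n, 0, 2e5)
  de <- abs(rnorm(n, 0.3, 0.5)) + 1e-6
  w <- 212676
  nmb_rule <- (w * de - dc) > 0
  icer_rule <- (dc / de) < w
  expect_equal(nmb_rule, icer_rule)
  # spot-check through the engine on a subsample
  for (i in sample.int(n, 25)) {
    cmp <- compare_arms(list(total_cost = 1e5 + dc[i], total_qaly = 5 + de[i]),
                        list(total_cost = 1e5, total_qaly = 5), w)
    expect_equal(cmp$cost_effective, nmb_rule[i])
  }
})

test_that("comparisons are antisymmetric", {
  a <- list(drug = "a", total_cost = 120, total_qaly = 4)
  b <- list(drug = "b", total_cost = 100, total_qaly = 5)
  ab <- compare_arms(a, b, 100)
  ba <- compare_arms(b, a, 100)
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_qaly, -ba$delta_qaly)
  expect_equal(ab$icer, ba$icer) # ratio of negated terms
  swap <- c(a_dominant = "b_dominant", b_dominant = "a_dominant",
            trade_off = "trade_off")
  expect_equal(unname(swap[ab$dominance]), ba$dominance)
})

test_that("the south-west AMD comparison is not cost-effective under NMB", {
  # cheaper but less effective: savings 44,334.9 < forgone QALY value
  # 0.665 * 212,676 = 141,429.5, so the NMB rule rejects arm a even though
  # the ICER (66,669) is numerically below the threshold.
  amd <- compare_arms(list(total_cost = 285285.597, total_qaly = 7.825),
                      list(total_cost = 329620.521, total_qaly = 8.490),
                      wtp_threshold())
  expect_false(decision_at_wtp(amd))
  expect_equal(amd$nmb_b - amd$nmb_a, 0.665 * 212676 - 44334.924,
               tolerance = 1e-6)
})
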
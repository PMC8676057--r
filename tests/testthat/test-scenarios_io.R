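test_that("builtin library carries the published parameters", {
  amd <- builtin_quietly("AMD", "real_world")
  expect_equal(amd$arm_a$unit_price, 5550)
  expect_equal(amd$arm_b$unit_price, 5700)
  expect_equal(amd$arm_a$injections_per_year, 4.8)
  expect_equal(amd$arm_b$injections_per_year, 5.4)
  expect_equal(amd$arm_a$discount_rate, 0.035)
  expect_equal(amd$arm_a$horizon, 10L)
  expect_equal(amd$wtp$threshold, 212676)

  dme_rct <- builtin_quietly("DME", "rct")
  expect_equal(dme_rct$arm_a$injections_per_year, 9.48)
  expect_equal(dme_rct$arm_b$injections_per_year, 7.9)

  pm <- builtin_quietly("PM", "real_world")
  expect_equal(pm$arm_a$injections_per_year, 1.8)
  expect_equal(pm$arm_b$injections_per_year, 1.92)

  expect_error(load_builtin("XYZ"), "valid")
  expect_equal(nrow(list_builtin_scenarios()), 6)
})

test_that("only the two documented renormalizations warn across the library", {
  # AMD baseline shares sum to 0.9999 -> warning at build time
  expect_warning(load_builtin("AMD"), "0.9999")
  # DME and PM builds are silent
  expect_silent(load_builtin("DME"))
  expect_silent(load_builtin("PM"))
  # PM ranibizumab outcome column (0.9998) warns when normalized at run time
  expect_warning(run_scenario(load_builtin("PM")), "0.9998")
  expect_silent(run_scenario(load_builtin("DME")))
})

test_that("scenario configs round-trip losslessly through JSON", {
  for (key in list(c("AMD", "real_world"), c("DME", "rct"),
                   c("PM", "real_world"))) {
    sc <- builtin_quietly(key[1], key[2])
    path <- withr::local_tempfile(fileext = ".json")
    write_scenario_config(sc, path)
    rt <- suppressWarnings(read_scenario_config(path))
    expect_equal(rt$space$utilities, sc$space$utilities, tolerance = 1e-12)
    expect_equal(rt$space$baseline_shares, sc$space$baseline_shares,
                 tolerance = 1e-12)
    expect_equal(rt$outcomes_a$probs, sc$outcomes_a$probs, tolerance = 1e-12)
    expect_equal(rt$outcomes_b$probs, sc$outcomes_b$probs, tolerance = 1e-12)
    expect_equal(rt$arm_a[2:6], sc$arm_a[2:6], tolerance = 1e-12)
    expect_equal(rt$wtp$threshold, sc$wtp$threshold)
    cmp_a <- run_quietly(sc); cmp_b <- run_quietly(rt)
    expect_equal(cmp_b$icer, cmp_a$icer, tolerance = 1e-12)
  }
})

test_that("partial configs layer over the builtin defaults", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(disease = "DME", mode = "real_world",
                            arm_a = list(unit_price = 4000)),
                       path, auto_unbox = TRUE)
  sc <- read_scenario_config(path)
  expect_equal(sc$arm_a$unit_price, 4000)      # overridden
  expect_equal(sc$arm_a$injections_per_year, 5.5) # builtin default
  expect_equal(sc$arm_b$unit_price, 5700)      # untouched arm
})

test_that("invalid configs report the violation", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(disease = "DME", mode = "real_world",
         outcomes_a = list(drug = "x",
                           probs = list(`+15` = 0.5, `0` = 0.4))),
    path, auto_unbox = TRUE)
  expect_error(read_scenario_config(path), "outcomes_a")
  expect_error(read_scenario_config("no/such/file.json"), "not found")
})

test_that("reports mirror the published table layout", {
  cmp <- run_quietly(builtin_quietly("AMD"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(cmp, csv, "csv")
  tab <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(names(tab),
               c("Strategy", "Cost (RMB)", "Incremental costs",
                 "Effectiveness (QALYs)", "Incremental effectiveness",
                 "CER", "ICER"))
  expect_equal(tab$Strategy, c("conbercept", "ranibizumab"))
  expect_equal(tab$`Cost (RMB)`[1], round(cmp$cost_a, 3))

  js <- withr::local_tempfile(fileext = ".json")
  write_report(list(amd = cmp), js, "json")
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$amd$icer, cmp$icer, tolerance = 1e-12)
  expect_equal(back$amd$cost_a, cmp$cost_a, tolerance = 1e-12)

  empty <- withr::local_tempfile(fileext = ".csv")
  write_report(list(), empty, "csv")
  expect_equal(nrow(utils::read.csv(empty, check.names = FALSE)), 0)
})

test_that("trace and matrix CSV exports are readable and consistent", {
  sc <- builtin_quietly("DME")
  tm <- build_transition_matrix(sc$outcomes_a, sc$space)
  mcsv <- withr::local_tempfile(fileext = ".csv")
  write_transition_matrix(tm, mcsv)
  m <- utils::read.csv(mcsv, check.names = FALSE)
  expect_equal(nrow(m), 5)
  expect_equal(unname(rowSums(m[, -1])), rep(1, 5), tolerance = 1e-12)

  res <- run_arm(sc$space, tm, sc$arm_a)
  tcsv <- withr::local_tempfile(fileext = ".csv")
  write_trace(res, tcsv)
  tr <- utils::read.csv(tcsv, check.names = FALSE)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$cum_disc_cost[10], res$total_cost, tolerance = 1e-9)
  expect_equal(tr$cum_disc_qaly[10], res$total_qaly, tolerance = 1e-9)
})

test_that("CLI verbs run end to end", {
  out <- withr::local_tempfile(fileext = ".csv")
  code <- NULL
  capture.output(code <- suppressWarnings(suppressMessages(
    cea_cli(c("run", "--disease", "AMD", "--out", out)))))
  expect_equal(code, 0L)
  expect_true(file.exists(out))

  expect_equal(suppressMessages(cea_cli(character())), 2L)
  expect_equal(suppressMessages(cea_cli(c("validate"))), 2L)

  gen <- withr::local_tempfile(fileext = ".json")
  expect_equal(suppressMessages(cea_cli(c("generate", "--seed", "5",
                                          "--out", gen))), 0L)
  expect_equal(suppressMessages(cea_cli(c("validate", "--config", gen))), 0L)

  ceac <- withr::local_tempfile(fileext = ".csv")
  code <- suppressWarnings(suppressMessages(capture.output(
    cea_cli(c("psa", "--disease", "DME", "--iterations", "500",
              "--seed", "2", "--out", ceac)))))
  expect_true(file.exists(ceac))
})
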
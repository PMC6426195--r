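test_that("patient cost sums quantity times unit cost within components", {
  prices <- toy_prices()
  # empty utilization
  empty <- patient_cost("A", data.frame(item = character(), quantity = numeric()),
                        prices)
  expect_equal(empty$total, 0)
  expect_equal(empty$drug_cost + empty$laboratory_cost +
                 empty$routine_cost + empty$operation_cost, 0)

  # a typical PPH case: drug 4.45, laboratory 9.78, routine 1.60, operation 10.37
  util <- data.frame(
    item = c("amoxicillin", "saline_bag", "cp_test", "gm_test",
             "opd_visit", "operation"),
    quantity = c(5, 1.625, 5, (9.78 - 5 * 1.67) / 0.42, 1, 1))
  pc <- patient_cost("pph_case", util, prices)
  expect_equal(pc$drug_cost, 4.45)
  expect_equal(pc$laboratory_cost, 9.78, tolerance = 1e-9)
  expect_equal(pc$routine_cost, 1.60)
  expect_equal(pc$operation_cost, 10.37)
  expect_equal(pc$total, 26.20, tolerance = 0.01)

  # random utilization against an independent dot-product oracle
  set.seed(5)
  for (i in 1:10) {
    k <- sample(nrow(prices), sample(2:7, 1))
    util <- data.frame(item = prices$item[k],
                       quantity = runif(length(k), 0, 10))
    pc <- patient_cost("X", util, prices)
    expect_equal(pc$total, sum(util$quantity * prices$unit_cost[k]),
                 tolerance = 1e-12)
  }

  expect_error(patient_cost("P9", data.frame(item = "unicorn_serum",
                                             quantity = 1), prices),
               "unicorn_serum.*P9|P9.*unicorn_serum")
})

test_that("cohort totals, means and singleton SDs match the worked example", {
  # seven category totals distributed over the reported category sizes
  counts <- c(incomplete_abortion = 26, pid = 1, pih = 23, aph = 11,
              pph = 17, prolonged_labor = 9, septicemia = 4)
  totals <- c(incomplete_abortion = 921.74, pid = 16.01, pih = 483.46,
              aph = 156.59, pph = 459.73, prolonged_labor = 337.99,
              septicemia = 66.04)
  patients <- toy_patients(sum(counts),
                           categories = rep(names(counts), counts),
                           ages = rep(25, sum(counts)))
  per_patient <- unlist(lapply(names(counts),
                               function(cat) rep(totals[[cat]] / counts[[cat]],
                                                 counts[[cat]])))
  costs <- costs_from_totals(patients, per_patient)
  s <- cost_summary(costs, patients)
  overall <- s[s$stratum == "overall", ]
  expect_equal(overall$total_total, 2441.56, tolerance = 1e-6)
  expect_equal(overall$n, 91)
  expect_equal(round(overall$total_mean, 2), 26.83)
  # stratum totals over categories add up to the overall total
  expect_equal(sum(s$total_total[s$stratum == "category"]),
               overall$total_total)
  # singleton stratum: mean equals total, SD reported as 0
  pid_row <- s[s$stratum == "category" & s$category == "pid", ]
  expect_equal(pid_row$n, 1)
  expect_equal(pid_row$total_mean, pid_row$total_total)
  expect_identical(pid_row$total_sd, 0)
})

test_that("category shares match the worked percentages and sum to 100", {
  counts <- c(incomplete_abortion = 26, pid = 1, pih = 23, aph = 11,
              pph = 17, prolonged_labor = 9, septicemia = 4)
  totals <- c(incomplete_abortion = 921.74, pid = 16.01, pih = 483.46,
              aph = 156.59, pph = 459.73, prolonged_labor = 337.99,
              septicemia = 66.04)
  patients <- toy_patients(sum(counts), categories = rep(names(counts), counts))
  per_patient <- unlist(lapply(names(counts),
                               function(cat) rep(totals[[cat]] / counts[[cat]],
                                                 counts[[cat]])))
  shares <- cost_shares(cost_summary(costs_from_totals(patients, per_patient),
                                     patients))
  expect_equal(shares$share[shares$category == "incomplete_abortion"], 37.75)
  expect_equal(shares$share[shares$category == "pih"], 19.80)
  # unrounded shares sum to exactly 100
  expect_equal(sum(100 * shares$total / sum(shares$total)), 100)

  # equal totals over k categories give each 100/k
  p_eq <- toy_patients(4, categories = c("aph", "pih", "pph", "septicemia"))
  sh_eq <- cost_shares(cost_summary(costs_from_totals(p_eq, rep(10, 4)), p_eq))
  expect_true(all(sh_eq$share == 25))
})

test_that("age groups split at 30 and empty inputs summarize to nothing", {
  patients <- toy_patients(4, ages = c(29, 30, 31, 19))
  costs <- costs_from_totals(patients, c(10, 20, 30, 40))
  s <- cost_summary(costs, patients)
  young <- s[s$stratum == "age_group" & s$age_group == "<30", ]
  old <- s[s$stratum == "age_group" & s$age_group == ">=30", ]
  expect_equal(young$n, 2)
  expect_equal(old$n, 2)
  expect_equal(young$total_total, 50)
  expect_equal(old$total_total, 50)

  empty <- cost_summary(costs[0, ], patients[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("costing is currency-equivariant", {
  sim <- generate_cohort(cohort_params(n = 40), seed = 9)
  prices_usd <- default_price_table()
  util <- realize_utilization(sim$patients, sim$latent, prices_usd)
  usd_then_convert <- convert_costs(
    compute_treatment_costs(sim$patients, util, prices_usd), "MMK")
  prices_mmk <- convert_prices(prices_usd, "MMK")
  mmk_direct <- compute_treatment_costs(sim$patients, util, prices_mmk)
  expect_equal(usd_then_convert$total, mmk_direct$total, tolerance = 1e-9)
  expect_equal(usd_then_convert$drug_cost, mmk_direct$drug_cost,
               tolerance = 1e-9)
})

test_that("component additivity holds exactly for whole cohorts", {
  sim <- generate_cohort(cohort_params(n = 30), seed = 13)
  util <- realize_utilization(sim$patients, sim$latent)
  costs <- compute_treatment_costs(sim$patients, util, default_price_table())
  expect_equal(costs$total,
               costs$drug_cost + costs$laboratory_cost +
                 costs$routine_cost + costs$operation_cost)
  expect_true(all(costs[c("drug_cost", "laboratory_cost", "routine_cost",
                          "operation_cost")] >= 0))
})
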
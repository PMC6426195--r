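test_that("annuity factor matches hand-computed values and its limits", {
  expect_equal(annuity_factor(0, 7), 7)
  expect_equal(annuity_factor(0.03, 1), 1 / 1.03)
  expect_equal(annuity_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  # brute-force sum of five discount factors
  expect_equal(annuity_factor(0.03, 5), sum(1.03^-(1:5)))
  expect_equal(annuity_factor(0.03, 5), 4.579707, tolerance = 1e-6)
  expect_error(annuity_factor(-0.01, 5), "non-negative")
  expect_error(annuity_factor(0.03, 0), "years")
})

test_that("annuity factor is decreasing in rate and increasing in years", {
  rates <- c(0, 0.01, 0.03, 0.05, 0.10)
  for (y in c(1L, 5L, 20L)) {
    vals <- vapply(rates, annuity_factor, numeric(1), years = y)
    expect_true(all(diff(vals) < 0) || y == 1L && all(diff(vals) < 0))
  }
  for (r in rates)
    expect_true(all(diff(vapply(1:25, function(y) annuity_factor(r, y),
                                numeric(1))) > 0))
})

test_that("asset annualization divides replacement cost by the annuity factor", {
  expect_equal(annualize_asset(1000, 5, 0.03), 1000 / 4.5797072, tolerance = 1e-6)
  expect_equal(annualize_asset(1000, 5, 0.03), 218.35, tolerance = 1e-4)
  expect_equal(annualize_asset(0, 12, 0.03), 0)
  expect_equal(annualize_asset(123.4, 1, 0), 123.4)
})

test_that("direct costs add capital, labor and material and are additive", {
  centers <- data.frame(center = c("acc1"), role = "ACC",
                        labor_cost = 45334.2, material_cost = 20486.6)
  assets <- data.frame(asset = "plant", center = "acc1",
                       replacement_cost = 22636.1 * annuity_factor(0.03, 10),
                       useful_life = 10L)
  bases <- data.frame(provider = character(), receiver = character(),
                      volume = numeric())
  outputs <- data.frame(center = "acc1", volume = 100)
  ledger <- cost_ledger(centers, assets, bases, outputs)
  dc <- center_direct_costs(ledger, rate = 0.03)
  expect_equal(dc$direct_cost, 22636.1 + 45334.2 + 20486.6, tolerance = 1e-8)
  expect_equal(dc$direct_cost, 88456.9, tolerance = 1e-4)

  # splitting labor across two pseudo-centers preserves the sum
  centers2 <- data.frame(center = c("acc1", "acc2"), role = "ACC",
                         labor_cost = c(20000, 25334.2),
                         material_cost = c(10000, 10486.6))
  ledger2 <- cost_ledger(centers2, assets,
                         bases, data.frame(center = c("acc1", "acc2"),
                                           volume = c(1, 1)))
  dc2 <- center_direct_costs(ledger2, rate = 0.03)
  expect_equal(sum(dc2$direct_cost), sum(dc$direct_cost))

  # all-zero center costs nothing
  zero <- cost_ledger(data.frame(center = "z", role = "ACC",
                                 labor_cost = 0, material_cost = 0),
                      NULL, bases, data.frame(center = "z", volume = 1))
  expect_equal(center_direct_costs(zero)$direct_cost, 0)
})

test_that("the two-TCC reciprocal system matches the hand solution", {
  # TCC1 (D=100) sends 10% of base to TCC2, TCC2 (D=50) sends 20% to TCC1,
  # the rest to a single ACC with D = 0:
  #   X1 = 100 + 0.2 X2, X2 = 50 + 0.1 X1  =>  X1 = 110/0.98
  centers <- data.frame(center = c("t1", "t2", "acc"),
                        role = c("TCC", "TCC", "ACC"),
                        labor_cost = c(100, 50, 0), material_cost = 0)
  bases <- data.frame(provider = c("t1", "t1", "t2", "t2"),
                      receiver = c("t2", "acc", "t1", "acc"),
                      volume = c(10, 90, 20, 80))
  ledger <- cost_ledger(centers, NULL, bases,
                        data.frame(center = "acc", volume = 1))
  alloc <- reciprocal_allocation(ledger)
  expect_equal(unname(alloc$tcc_full_costs["t1"]), 110 / 0.98)
  expect_equal(unname(alloc$tcc_full_costs["t2"]), 50 + 0.1 * 110 / 0.98)
  expect_equal(unname(alloc$acc_full_costs["acc"]), 150)
  # cross-check with the iterative oracle
  expect_equal(alloc$acc_full_costs, iterative_allocation(ledger),
               tolerance = 1e-10)
})

test_that("without TCC-to-TCC service the allocation is one-step direct", {
  centers <- data.frame(center = c("t1", "a1", "a2"),
                        role = c("TCC", "ACC", "ACC"),
                        labor_cost = c(60, 10, 20), material_cost = 0)
  bases <- data.frame(provider = "t1", receiver = c("a1", "a2"),
                      volume = c(30, 10))
  ledger <- cost_ledger(centers, NULL, bases,
                        data.frame(center = c("a1", "a2"), volume = c(1, 1)))
  alloc <- reciprocal_allocation(ledger)
  expect_equal(unname(alloc$acc_full_costs), c(10 + 45, 20 + 15))
})

test_that("reciprocal allocation conserves money and equals fixed-point iteration", {
  set.seed(101)
  for (i in 1:25) {
    ledger <- random_ledger()
    alloc <- reciprocal_allocation(ledger)
    total_direct <- sum(alloc$direct_costs$direct_cost)
    expect_lt(abs(sum(alloc$acc_full_costs) - total_direct) / total_direct, 1e-6)
    expect_equal(alloc$acc_full_costs, iterative_allocation(ledger),
                 tolerance = 1e-8)
  }
})

test_that("average unit cost is full cost over volume, homogeneous in volume", {
  expect_equal(unit_cost_average(100, 50), 2)
  expect_equal(unit_cost_average(100, 100), unit_cost_average(100, 50) / 2)
  expect_error(unit_cost_average(100, 0), "positive")
})

test_that("unit costs are invariant to ledger currency up to the rate", {
  set.seed(7)
  ledger_usd <- random_ledger()
  rate <- 1199.07
  ledger_mmk <- ledger_usd
  ledger_mmk$centers$labor_cost <- ledger_usd$centers$labor_cost * rate
  ledger_mmk$centers$material_cost <- ledger_usd$centers$material_cost * rate
  ledger_mmk$assets$replacement_cost <- ledger_usd$assets$replacement_cost * rate
  ledger_mmk$currency <- "MMK"
  uc_usd <- compute_unit_costs(ledger_usd)
  uc_mmk <- compute_unit_costs(ledger_mmk)
  expect_equal(uc_mmk$unit_cost / rate, uc_usd$unit_cost, tolerance = 1e-9)
})

test_that("inadmissible ledgers are rejected with the offending center named", {
  centers <- data.frame(center = c("t1", "a1"), role = c("TCC", "ACC"),
                        labor_cost = c(10, 5), material_cost = 0)
  # TCC with no positive base
  expect_error(cost_ledger(centers, NULL,
                           data.frame(provider = "t1", receiver = "a1",
                                      volume = 0),
                           data.frame(center = "a1", volume = 1)),
               "t1")
  # self-allocation
  expect_error(cost_ledger(centers, NULL,
                           data.frame(provider = "t1",
                                      receiver = c("t1", "a1"),
                                      volume = c(5, 5)),
                           data.frame(center = "a1", volume = 1)),
               "itself")
})
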
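test_that("unit costs inflate geometrically from the base year", {
  fp <- finance_params()
  expect_equal(unit_cost("hbdc", 2024, fp), 14400)
  expect_equal(unit_cost("hbdc", 2025, fp), 14400 * 1.0225)
  k <- 17
  f <- 1.0225^k
  for (s in names(fp$unit_costs_monthly))
    expect_equal(unit_cost(s, 2024 + k, fp),
                 unit_cost(s, 2024, fp) * f, tolerance = 1e-12)
  expect_error(unit_cost("hospice", 2024, fp), "unknown service")
})

test_that("expenditure matches a per-person enumeration oracle", {
  fp <- finance_params()
  expect_identical(ltce(0, 2024, fp), 0)
  # one beneficiary in 2024: enumerate the service mix person by person
  # out of 1000 beneficiaries (900 hbdc, 30 institutional, 70 home-
  # medical/nursing at equal cost), then divide
  per1000 <- 900 * 14400 + 30 * (12 * 2100) + 70 * (12 * 1680)
  expect_equal(ltce(1, 2024, fp), per1000 / 1000, tolerance = 1e-9)
  expect_equal(ltce(1, 2024, fp), 15127.2, tolerance = 1e-9)
  # linearity
  expect_equal(ltce(246810, 2024, fp), 246810 * ltce(1, 2024, fp),
               tolerance = 1e-9)
  expect_error(ltce(-5, 2024, fp), "negative")
})

test_that("premium income compounds its growth rate", {
  fp <- finance_params()
  expect_equal(premium_income(1, 2023, 0.0525, fp), 90)
  expect_equal(premium_income(c(100, 200), c(2024, 2030), 0, fp),
               90 * c(100, 200))
  # closed form vs iterated multiplication
  p <- 90
  for (i in 1:10) p <- p * 1.0525
  expect_equal(premium_income(1, 2033, 0.0525, fp), p,
               tolerance = 1e-10)
  expect_error(premium_income(1, 2022, 0, fp), "base year")
})

test_that("the ledger recursion holds and degenerates correctly", {
  fp <- finance_params()
  yrs <- 2023:2080
  cp <- stats::setNames(rep(1e6, length(yrs)), yrs)
  sev <- stats::setNames(rep(1e4, length(yrs)), yrs)
  led <- run_ledger(sev, cp, 0.03, fp)
  # recursion exact at every year
  acc <- led$accumulated_balance
  expect_equal(acc[-1], acc[-length(acc)] * 1.025 +
                 led$current_balance[-1], tolerance = 1e-9)
  expect_equal(acc[1], led$current_balance[1])
  expect_equal(led$current_balance,
               led$premium_income - led$ltce, tolerance = 1e-9)

  # no expenditure: accumulated is a compounding annuity of premiums
  led0 <- run_ledger(stats::setNames(rep(0, 58), yrs), cp, 0.03, fp)
  annuity <- 0
  for (i in seq_along(yrs))
    annuity <- annuity * 1.025 + led0$premium_income[i]
  expect_equal(led0$accumulated_balance[58], annuity, tolerance = 1e-9)

  # zero interest: accumulated = cumulative sum of current balances
  fp0 <- finance_params(interest = 0)
  ledz <- run_ledger(sev, cp, 0.03, fp0)
  expect_equal(ledz$accumulated_balance, cumsum(ledz$current_balance),
               tolerance = 1e-9)

  # no premiums: strictly decreasing accumulated balance
  ledn <- run_ledger(sev, stats::setNames(rep(0, 58), yrs), 0, fp)
  expect_true(all(diff(ledn$accumulated_balance) < 0))
})

test_that("accumulated balance is monotone in the growth rate", {
  fp <- finance_params()
  yrs <- 2023:2080
  cp <- stats::setNames(rep(5e7, length(yrs)), yrs)
  sev <- stats::setNames(3e5 * 1.03^(yrs - 2023), yrs)
  lams <- seq(0, 0.09, 0.015)
  accs <- sapply(lams, function(l)
    run_ledger(sev, cp, l, fp)$accumulated_balance)
  for (j in seq_len(ncol(accs) - 1))
    expect_true(all(accs[, j + 1] >= accs[, j] - 1e-9))
})

test_that("minimal sustainable growth matches a brute-force grid oracle", {
  fp <- finance_params()
  yrs <- 2023:2080
  cp <- stats::setNames(rep(5e7, length(yrs)), yrs)
  # expenditure engineered to grow ~4%/yr total: beneficiaries growing
  # at 1.0175/yr on top of 2.25% unit-cost inflation
  sev <- stats::setNames(2.8e5 * 1.0175^(yrs - 2023), yrs)
  grid <- seq(0, 0.10, by = 5e-4)
  res <- min_sustainable_growth(sev, cp, fp, grid)
  # independent oracle: plain arithmetic scan of the whole grid
  percap <- function(y) {
    (0.90 * 1200 + 0.03 * 2100 + 0.07 * 1680) * 12 *
      1.0225^(y - 2024)
  }
  ok <- vapply(grid, function(l) {
    acc <- 0
    for (y in yrs) {
      cur <- 90 * (1 + l)^(y - 2023) * 5e7 -
        percap(y) * 2.8e5 * 1.0175^(y - 2023)
      acc <- acc * 1.025 + cur
      if (acc < 0) return(FALSE)
    }
    TRUE
  }, logical(1))
  expect_identical(res$lambda_star, grid[which(ok)[1]])
  expect_true(res$verified)
  expect_true(res$below_fails)
  expect_gte(res$lambda_star, 0.035)
  expect_lte(res$lambda_star, 0.045)
  # no expenditure at all: zero growth suffices
  res0 <- min_sustainable_growth(stats::setNames(rep(0, 58), yrs), cp,
                                 fp, grid)
  expect_identical(res0$lambda_star, 0)
})

test_that("finance configuration round-trips through YAML", {
  dir <- withr::local_tempdir()
  paths <- make_fixtures(dir, synth_config(seed = 3, adl_n = 500))
  fp <- read_finance_yaml(paths[["finance"]])
  expect_equal(fp$unit_costs_monthly[["institutional"]], 2100)
  expect_equal(fp$interest, 0.025)
  expect_equal(fp$premium_t0, 90)
  expect_true(file.exists(paths[["censuses"]]))
  cen <- utils::read.csv(paths[["censuses"]])
  expect_true(all(c("sex", "year", "age_group_start", "population",
                    "deaths") %in% names(cen)))
})
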
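#' Financing parameters of the long-term care insurance scheme
#'
#' Defaults follow a representative Chinese pilot-city scheme: monthly
#' unit costs in 2024 of 1200 CNY for home-based daily care (hbdc), 2100
#' for institutional care, and 1680 for both home-based daily & medical
#' care (hbdmc) and nursing-hospital care; service utilisation shares
#' 90\% / 3\% / 3.5\% / 3.5\% (the latter two grouped in practice since
#' their costs are equal, the "9073" elder-care mix); unit-cost inflation
#' 2.25\%/year; a fixed premium of 90 CNY per contributor per year at the
#' base year; and fund interest of 2.5\%/year.
#'
#' @param unit_costs_monthly named vector (hbdc, institutional, hbdmc,
#'   nursing_hospital), CNY/month at \code{cost_base_year}.
#' @param shares utilisation shares, same names, summing to 1.
#' @param cost_inflation annual growth of unit costs (default 0.0225).
#' @param premium_t0 premium at the base year, CNY/person/year
#'   (default 90).
#' @param premium_base_year first premium year t0 (default 2023; the
#'   first grown premium falls in 2024).
#' @param interest annual fund interest rate gamma (default 0.025).
#' @param cost_base_year year of the quoted unit costs (default 2024).
#' @param participation_rate share of the population 20+ contributing
#'   (default 1).
#' @return a \code{finance_params} list.
#' @export
finance_params <- function(unit_costs_monthly = c(hbdc = 1200,
                                                  institutional = 2100,
                                                  hbdmc = 1680,
                                                  nursing_hospital = 1680),
                           shares = c(hbdc = 0.90, institutional = 0.03,
                                      hbdmc = 0.035,
                                      nursing_hospital = 0.035),
                           cost_inflation = 0.0225, premium_t0 = 90,
                           premium_base_year = 2023, interest = 0.025,
                           cost_base_year = 2024,
                           participation_rate = 1) {
  nm <- c("hbdc", "institutional", "hbdmc", "nursing_hospital")
  stopifnot(all(nm %in% names(unit_costs_monthly)),
            all(nm %in% names(shares)),
            abs(sum(shares) - 1) < 1e-8,
            all(unit_costs_monthly > 0), cost_inflation > -1,
            interest > -1, premium_t0 > 0,
            participation_rate > 0, participation_rate <= 1)
  structure(list(unit_costs_monthly = unit_costs_monthly[nm],
                 shares = shares[nm], cost_inflation = cost_inflation,
                 premium_t0 = premium_t0,
                 premium_base_year = premium_base_year,
                 interest = interest, cost_base_year = cost_base_year,
                 participation_rate = participation_rate),
            class = "finance_params")
}

#' Annual unit cost of a care service
#'
#' Twelve times the monthly base cost, inflated at the scheme's annual
#' cost-growth rate from the cost base year.
#'
#' @param service one of hbdc, institutional, hbdmc, nursing_hospital.
#' @param year calendar year (>= cost base year).
#' @param fp a \code{finance_params}.
#' @return cost in CNY per beneficiary per year.
#' @export
unit_cost <- function(service, year, fp = finance_params()) {
  if (!service %in% names(fp$unit_costs_monthly))
    stop("unknown service: ", service)
  # years before the base year deflate by the same geometric rate
  12 * fp$unit_costs_monthly[[service]] *
    (1 + fp$cost_inflation)^(year - fp$cost_base_year)
}

#' Annual long-term care expenditure
#'
#' Share-weighted average of the four annual service unit costs times the
#' number of severely disabled older beneficiaries.
#'
#' @param severe_count beneficiaries (persons, not thousands).
#' @param year calendar year.
#' @param fp a \code{finance_params}.
#' @return expenditure in CNY.
#' @export
ltce <- function(severe_count, year, fp = finance_params()) {
  if (any(severe_count < 0)) stop("negative beneficiary count")
  costs <- vapply(names(fp$shares), unit_cost, numeric(length(year)),
                  year = year, fp = fp)
  percap <- if (is.matrix(costs)) drop(costs %*% fp$shares)
            else sum(costs * fp$shares)
  percap * severe_count
}

#' Annual premium income
#'
#' Fixed-amount premium grown geometrically from the base year times the
#' number of contributors: premium_t0 (1 + lambda)^(t - t0) CP_t.
#'
#' @param cp contributors in year t.
#' @param year calendar year (>= premium base year).
#' @param lambda annual premium growth rate.
#' @param fp a \code{finance_params}.
#' @return income in CNY.
#' @export
premium_income <- function(cp, year, lambda, fp = finance_params()) {
  if (any(year < fp$premium_base_year))
    stop("year before premium base year")
  fp$premium_t0 * (1 + lambda)^(year - fp$premium_base_year) * cp
}

#' Contributor series from a population projection
#'
#' Contributors are the population aged 20 and above times the
#' participation rate.
#'
#' @param proj a \code{population_projection}.
#' @param fp a \code{finance_params}.
#' @return named numeric vector of contributors by year.
#' @export
contributor_series <- function(proj, fp = finance_params()) {
  population_older(proj, min_age = 20) * fp$participation_rate
}

#' Run the fund ledger
#'
#' Simulates the insurance fund year by year: expenditure from
#' beneficiary counts, premium income under growth rate lambda, the
#' current balance (income minus expenditure), and the accumulated
#' balance compounded at the fund interest rate,
#' accumulated_t = accumulated_(t-1) (1 + gamma) + current_t, starting
#' from zero before the first year.
#'
#' @param severe_counts named vector of beneficiaries (persons) by year.
#' @param cp named vector of contributors by year (same years).
#' @param lambda annual premium growth rate.
#' @param fp a \code{finance_params}.
#' @return a \code{fund_ledger} data frame (year, ltce, premium_income,
#'   current_balance, accumulated_balance) with summary attributes
#'   first_deficit_year, first_negative_accumulated_year,
#'   terminal_accumulated.
#' @export
run_ledger <- function(severe_counts, cp, lambda, fp = finance_params()) {
  years <- as.integer(names(severe_counts))
  if (!identical(years, as.integer(names(cp))))
    stop("year ranges of beneficiaries and contributors differ")
  exp_t <- ltce(unname(severe_counts), years, fp)
  inc_t <- premium_income(unname(cp), years, lambda, fp)
  cur <- inc_t - exp_t
  acc <- numeric(length(years))
  prev <- 0
  for (i in seq_along(years)) {
    prev <- prev * (1 + fp$interest) + cur[i]
    acc[i] <- prev
  }
  first_deficit <- years[which(cur < 0)[1L]]
  first_neg_acc <- years[which(acc < 0)[1L]]
  structure(data.frame(year = years, ltce = exp_t,
                       premium_income = inc_t, current_balance = cur,
                       accumulated_balance = acc),
            class = c("fund_ledger", "data.frame"),
            lambda = lambda,
            first_deficit_year = first_deficit,
            first_negative_accumulated_year = first_neg_acc,
            terminal_accumulated = acc[length(acc)])
}

#' @export
print.fund_ledger <- function(x, ...) {
  cat(sprintf(
    "LTCI fund ledger %d-%d (lambda = %.2f%%)\n  first current deficit: %s; first negative accumulated: %s\n  terminal accumulated balance: %.2f billion CNY\n",
    min(x$year), max(x$year), 100 * attr(x, "lambda"),
    as.character(attr(x, "first_deficit_year")),
    as.character(attr(x, "first_negative_accumulated_year")),
    attr(x, "terminal_accumulated") / 1e9))
  invisible(x)
}

#' @export
summary.fund_ledger <- function(object, ...) {
  list(lambda = attr(object, "lambda"),
       first_deficit_year = attr(object, "first_deficit_year"),
       first_negative_accumulated_year =
         attr(object, "first_negative_accumulated_year"),
       terminal_accumulated = attr(object, "terminal_accumulated"))
}

#' Minimal sustainable premium growth rate
#'
#' Scans a lambda grid (default 0 to 10\% in steps of 0.05 percentage
#' points) for the smallest growth rate whose ledger keeps the
#' accumulated balance non-negative through the last simulated year. The
#' result is verified by re-running the ledger at lambda* (must pass) and
#' at lambda* minus one step (must fail, unless lambda* is the grid
#' origin).
#'
#' @param severe_counts,cp,fp as in \code{\link{run_ledger}}.
#' @param grid candidate lambda values (default seq(0, 0.10, 0.0005)).
#' @return a list: lambda_star (NA if no grid value is sustainable),
#'   ledger at lambda_star, and the verification flags.
#' @export
min_sustainable_growth <- function(severe_counts, cp,
                                   fp = finance_params(),
                                   grid = seq(0, 0.10, by = 5e-4)) {
  if (!length(grid)) stop("empty grid")
  grid <- sort(grid)
  ok <- function(l) {
    led <- run_ledger(severe_counts, cp, l, fp)
    all(led$accumulated_balance >= 0)
  }
  idx <- which(vapply(grid, ok, logical(1)))[1L]
  if (is.na(idx))
    return(list(lambda_star = NA_real_, ledger = NULL,
                verified = FALSE, below_fails = NA))
  lam <- grid[idx]
  below_fails <- if (idx == 1L) NA else !ok(grid[idx - 1L])
  list(lambda_star = lam,
       ledger = run_ledger(severe_counts, cp, lam, fp),
       verified = ok(lam), below_fails = below_fails)
}

#' Write a fund ledger to CSV
#'
#' @param ledger a \code{fund_ledger}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}
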
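#' Graduate a census population to single ages
#'
#' Uniform split of abridged census counts into single years of age
#' (infant and 1--4 groups kept as drawn; the open group stays pooled at
#' its start age).
#'
#' @param census data frame (sex, year, age_group_start, population).
#' @param year census year to use.
#' @return data frame sex, age (0..100), count.
#' @export
census_base_population <- function(census, year) {
  rows <- list()
  for (s in c("male", "female")) {
    sub <- census[census$sex == s & census$year == year, ]
    sub <- sub[order(sub$age_group_start), ]
    cnt <- rep(0, 101)
    for (i in seq_len(nrow(sub))) {
      a <- sub$age_group_start[i]
      w <- if (i < nrow(sub)) sub$age_group_start[i + 1L] - a else 1
      idx <- a:(min(a + w - 1, 100)) + 1L
      cnt[idx] <- cnt[idx] + sub$population[i] / length(idx)
    }
    rows[[s]] <- data.frame(sex = s, age = 0:100, count = cnt)
  }
  do.call(rbind, rows)
}

#' Run the full simulation pipeline on synthetic inputs
#'
#' Chains every stage: synthetic censuses and child mortality ->
#' three-parameter log-quadratic annual life tables -> Lee-Carter-with-
#' rotation mortality projection (mean and 95\% life-expectancy bounds)
#' -> cohort-component population projection per life-expectancy
#' scenario -> disability prevalence and demand scenarios -> fund
#' ledgers and the minimal sustainable premium growth rate per
#' disability scenario.
#'
#' @param cfg a \code{\link{synth_config}} (its seed drives every random
#'   stage).
#' @param end last projected year (default 2080).
#' @param n_sims Lee-Carter trajectories (default 1000).
#' @param lambda_grid premium growth grid for the sustainability search.
#' @param lambdas_report fixed growth rates at which ledgers are also
#'   reported (default 2.25\%, 4.20\%, 5.25\%, 6.25\%).
#' @param fp finance parameters.
#' @param out_dir if not NULL, stage outputs are written there as
#'   CSV/JSON.
#' @return a list with every stage's object (see names).
#' @export
run_pipeline <- function(cfg, end = 2080, n_sims = 1000,
                         lambda_grid = seq(0, 0.10, by = 5e-4),
                         lambdas_report = c(0.0225, 0.042, 0.0525,
                                            0.0625),
                         fp = finance_params(), out_dir = NULL) {
  cen <- generate_censuses(cfg)
  u5 <- generate_u5mr(cfg)
  adl <- generate_adl_survey(cfg)

  dcmd <- dcmd_estimate(cen$censuses, u5)

  projs <- list()
  for (s in c("male", "female")) {
    lc <- fit_lc(dcmd_log_mx(dcmd, s), age = dcmd$tables[[s]][[1L]]$age,
                 sex = s)
    projs[[s]] <- lc_project(lc, horizon_end = end, n_sims = n_sims,
                             seed = cfg$seed + match(s, c("male",
                                                          "female")))
  }

  base_year <- max(cfg$census_years)
  base_pop <- census_base_population(cen$censuses, base_year)
  fert <- fertility_path(
    tfr = cfg$tfr_2020 * default_tfr_multipliers(base_year:end))
  cyn <- length(cfg$census_years)
  mid_tab <- lapply(c(male = "male", female = "female"), function(s) {
    y <- round((cfg$census_years[cyn - 1L] + cfg$census_years[cyn]) / 2)
    truncate_open_age(graduate_to_single_age(
      dcmd$tables[[s]][[as.character(y)]]), 100)
  })
  mig <- census_survival_migration(
    cen$censuses[cen$censuses$year == cfg$census_years[cyn - 1L], ],
    cen$censuses[cen$censuses$year == base_year, ],
    mid_tab$male, mid_tab$female,
    base_year = base_year, equilibrium_year = 2045)

  base_tab <- lapply(c(male = "male", female = "female"), function(s)
    truncate_open_age(graduate_to_single_age(
      dcmd$tables[[s]][[as.character(base_year)]]), 100))

  pops <- list()
  for (sc in c("mean", "lo95", "hi95")) {
    tabs <- lapply(c(male = "male", female = "female"), function(s) {
      tt <- projection_lifetables(projs[[s]], sc, open_age = 100)
      c(stats::setNames(list(base_tab[[s]]), base_year), tt)
    })
    pops[[sc]] <- project_population(base_pop, base_year,
                                     tabs$male, tabs$female, fert, mig,
                                     end = end)
  }

  prev <- adl_prevalence(adl$records)
  demand <- list()
  for (sc in c("mean", "lo95", "hi95"))
    for (ds in c("low", "medium", "high"))
      demand[[sc]][[ds]] <- ltc_demand(pops[[sc]], prev,
                                       disability_scenario(ds),
                                       years = 2023:end)

  ledgers <- list(); lambda_star <- list()
  for (sc in c("mean", "lo95", "hi95")) {
    cp <- contributor_series(pops[[sc]], fp)
    cp <- cp[names(cp) >= "2023"]
    for (ds in c("low", "medium", "high")) {
      sv <- severe_persons(demand[[sc]][[ds]])
      if (sc == "mean")
        lambda_star[[ds]] <- min_sustainable_growth(sv, cp, fp,
                                                    grid = lambda_grid)
      for (l in lambdas_report)
        ledgers[[sc]][[ds]][[sprintf("%.4f", l)]] <-
          run_ledger(sv, cp, l, fp)
    }
  }

  res <- list(config = cfg, censuses = cen, u5mr = u5, adl = adl,
              dcmd = dcmd, projections = projs, populations = pops,
              prevalence = prev, demand = demand, ledgers = ledgers,
              lambda_star = lambda_star, finance = fp)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_e0_csv(res$projections, file.path(dir, "e0_projection.csv"))
  utils::write.csv(res$dcmd$params, file.path(dir, "dcmd_params.csv"),
                   row.names = FALSE)
  dem <- do.call(rbind, lapply(names(res$demand), function(sc)
    do.call(rbind, lapply(res$demand[[sc]], function(d)
      cbind(e0_scenario = sc,
            d[, c("year", "scenario", "severity", "thousands")])))))
  utils::write.csv(dem, file.path(dir, "ltc_demand.csv"),
                   row.names = FALSE)
  led <- res$ledgers$mean$medium
  for (nm in names(led))
    write_ledger_csv(led[[nm]],
                     file.path(dir, sprintf("ledger_medium_%s.csv", nm)))
  summ <- list(
    lambda_star = lapply(res$lambda_star, function(x) x$lambda_star),
    first_negative_accumulated_year = lapply(
      res$ledgers$mean, function(ds) lapply(ds, function(l)
        attr(l, "first_negative_accumulated_year"))))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
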
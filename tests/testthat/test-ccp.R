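immortal_table <- function(sex = "male") {
  lifetable(rep(1e-12, 101), age = 0:100, sex = sex)
}

frozen_tables <- function() {
  g <- truncate_open_age(
    graduate_to_single_age(fx_censuses()$truth$tables[["male 2020"]]),
    100)
  gf <- truncate_open_age(
    graduate_to_single_age(fx_censuses()$truth$tables[["female 2020"]]),
    100)
  list(male = g, female = gf)
}

test_that("a deathless, closed, childless population just shifts", {
  pop <- ltcisim:::pop_to_matrix(
    data.frame(sex = rep(c("male", "female"), each = 101),
               age = rep(0:100, 2), count = rep(1000, 202)))
  im <- immortal_table("male"); imf <- immortal_table("female")
  fert <- fertility_path(tfr = c("2020" = 0))
  out <- step_population(pop, im, imf, 0, fert)
  expect_equal(unname(out[2:100, ]), unname(pop[1:99, ]),
               tolerance = 1e-6)
  expect_equal(unname(out[1, ]), c(0, 0))
  # open group absorbs ages 99 and 100+
  expect_equal(unname(out[101, ]), unname(pop[100, ] + pop[101, ]),
               tolerance = 1e-4)
})

test_that("population change equals implied cohort deaths (conservation)", {
  tabs <- frozen_tables()
  pop <- ltcisim:::pop_to_matrix(
    data.frame(sex = rep(c("male", "female"), each = 101),
               age = rep(0:100, 2),
               count = round(stats::dlnorm(rep(0:100, 2) + 1, 3.5, 0.7) *
                               1e6) + 50))
  fert <- fertility_path(tfr = c("2020" = 0))
  out <- step_population(pop, tabs$male, tabs$female, 0, fert)
  # scalar oracle: deaths = sum over cohorts of pop * (1 - ratio)
  for (s in c("male", "female")) {
    lt <- tabs[[s]]
    sr <- vapply(0:100, function(x) survival_ratio(lt, x), numeric(1))
    deaths <- sum(pop[, s] * (1 - sr))
    expect_equal(sum(pop[, s]) - sum(out[, s]), deaths,
                 tolerance = 1e-8 * sum(pop[, s]))
    # no cohort grows without migration
    expect_true(all(out[2:101, s] <= pop[1:100, s] + pop[101, s] + 1e-9))
  }
})

test_that("births scale linearly with fertility and split by sex ratio", {
  tabs <- frozen_tables()
  pop <- ltcisim:::pop_to_matrix(
    data.frame(sex = rep(c("male", "female"), each = 101),
               age = rep(0:100, 2), count = rep(1000, 202)))
  fert <- fertility_path(tfr = c("2020" = 1))
  o1 <- step_population(pop, tabs$male, tabs$female, 1.0, fert)
  o2 <- step_population(pop, tabs$male, tabs$female, 2.0, fert)
  expect_equal(unname(o2[1, ]), unname(2 * o1[1, ]), tolerance = 1e-12)
  expect_equal(o1[1, "male"] / o1[1, "female"],
               1.05 * tabs$male$Lx[1] / tabs$male$lx[1] /
                 (tabs$female$Lx[1] / tabs$female$lx[1]),
               tolerance = 1e-9)
})

test_that("census survival method recovers injected migration", {
  tabs <- frozen_tables()
  lt <- tabs$male
  age5 <- age_grid_abridged(100)
  # build census1 from a smooth pyramid, survive it 10 years for census2
  pop1 <- round(2e5 * exp(-0.02 * age5)) + 100
  cen1 <- rbind(
    data.frame(sex = "male", age_group_start = age5, population = pop1),
    data.frame(sex = "female", age_group_start = age5,
               population = pop1))
  surv10 <- function(ltab, a) {
    num <- sum(ltab$Lx[match((a + 10):(a + 14), ltab$age)])
    den <- sum(ltab$Lx[match(a:(a + 4), ltab$age)])
    num / den
  }
  survive_census <- function(cen, ltab) {
    out <- cen
    for (a in seq(0, 85, 5)) {
      src <- if (a == 0) sum(cen$population[cen$age_group_start %in%
                                              c(0, 1)])
             else cen$population[match(a, cen$age_group_start)]
      out$population[match(a + 10, out$age_group_start)] <-
        round(src * surv10(ltab, a))
    }
    out
  }
  cen2 <- rbind(survive_census(cen1[cen1$sex == "male", ], tabs$male),
                survive_census(cen1[cen1$sex == "female", ],
                               tabs$female))
  ms0 <- census_survival_migration(cen1, cen2, tabs$male, tabs$female)
  expect_lt(max(abs(ms0$base$net_migrants_per_year)), 60)  # ~0 + rounding
  # inject +1000 into the male cohort aged 30-34 at census1 (40-44 at 2)
  cen2b <- cen2
  i <- cen2b$sex == "male" & cen2b$age_group_start == 40
  cen2b$population[i] <- cen2b$population[i] + 1000
  ms1 <- census_survival_migration(cen1, cen2b, tabs$male, tabs$female)
  coh <- ms1$base$sex == "male" & ms1$base$age %in% 35:39
  expect_equal(sum(ms1$base$net_migrants_per_year[coh] -
                     ms0$base$net_migrants_per_year[coh]), 100,
               tolerance = 1e-6)
  # broader recovery: uniform +200/yr injected over working-age cohorts
  cen2c <- cen2
  for (a in seq(20, 50, 5)) {
    j <- cen2c$sex == "male" & cen2c$age_group_start == a + 10
    cen2c$population[j] <- cen2c$population[j] + 2000
  }
  ms2 <- census_survival_migration(cen1, cen2c, tabs$male, tabs$female)
  tot <- sum(ms2$base$net_migrants_per_year[ms2$base$sex == "male" &
                                              ms2$base$age %in% 25:64])
  expect_lt(abs(tot - 7 * 200) / (7 * 200), 0.10)
})

test_that("taper declines linearly to equilibrium", {
  ms <- migration_schedule(
    data.frame(sex = "male", age = 0:100, net_migrants_per_year = 1),
    base_year = 2020, equilibrium_year = 2045)
  expect_identical(migration_taper(ms, 2020), 1)
  expect_identical(migration_taper(ms, 2045), 0)
  expect_identical(migration_taper(ms, 2060), 0)
  expect_equal(migration_taper(ms, 2030), 0.6)
  expect_true(all(diff(migration_taper(ms, 2020:2050)) <= 0))
})

test_that("projection composes steps, anchors the base year, and matches
           a matrix-power oracle without fertility or migration", {
  tabs <- frozen_tables()
  base <- data.frame(sex = rep(c("male", "female"), each = 101),
                     age = rep(0:100, 2),
                     count = round(stats::dlnorm(rep(0:100, 2) + 1, 3.5,
                                                 0.7) * 1e6) + 50)
  fert <- fertility_path(
    tfr = stats::setNames(rep(0, 61), 2020:2080))
  tm <- stats::setNames(rep(list(tabs$male), 61), 2020:2080)
  tf <- stats::setNames(rep(list(tabs$female), 61), 2020:2080)
  proj <- project_population(base, 2020, tm, tf, fert, mig = NULL,
                             end = 2080)
  # anchoring
  expect_equal(sum(proj$counts[61:101, , 1]),
               sum(base$count[base$age >= 60]))
  # one-step equivalence
  p0 <- ltcisim:::pop_to_matrix(base)
  p1 <- step_population(p0, tabs$male, tabs$female, 0, fert)
  expect_equal(unname(proj$counts[, , 2]), unname(unclass(p1)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # matrix-power oracle: apply the survival operator 60 times by hand
  for (s in c("male", "female")) {
    sr <- vapply(0:100, function(x) survival_ratio(tabs[[s]], x),
                 numeric(1))
    v <- p0[, s]
    for (i in 1:60) {
      w <- numeric(101)
      w[2:101] <- v[1:100] * sr[1:100]
      w[101] <- w[101] + v[101] * sr[101]
      v <- w
    }
    expect_equal(unname(proj$counts[, s, 61]), v, tolerance = 1e-8)
  }
})

test_that("higher life expectancy dominates the old-age population", {
  res <- fx_pipeline()
  o_hi <- population_older(res$populations$hi95)
  o_lo <- population_older(res$populations$lo95)
  expect_true(all(o_hi >= o_lo - 1e-6))
})
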
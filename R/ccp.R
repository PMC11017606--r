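#' Fertility path
#'
#' A total fertility rate (TFR) trajectory plus a fixed age-specific
#' fertility shape over ages 15--49 (summing to 1) and a sex ratio at
#' birth. The default shape is a late-peaking schedule (mode near age 29)
#' typical of contemporary low-fertility East Asian populations.
#'
#' @param tfr named numeric vector of TFR by year.
#' @param shape non-negative weights over ages 15--49 summing to 1;
#'   default a discretised normal peaking at 29.
#' @param srb sex ratio at birth, males per female (default 1.05).
#' @return a \code{fertility_path} list with ages, shape, tfr, srb.
#' @export
fertility_path <- function(tfr, shape = NULL, srb = 1.05) {
  ages <- 15:49
  if (is.null(shape)) {
    shape <- stats::dnorm(ages, mean = 29, sd = 5.5)
    shape <- shape / sum(shape)
  }
  stopifnot(length(shape) == length(ages), all(shape >= 0),
            abs(sum(shape) - 1) < 1e-8, all(tfr >= 0), srb > 0)
  structure(list(ages = ages, shape = shape, tfr = tfr, srb = srb),
            class = "fertility_path")
}

#' Default relative TFR change path
#'
#' A smooth multiplier path standing in for a published country-level
#' fertility recovery scenario: 1 at the base year, rising along a
#' saturating exponential so that TFR recovers slowly toward roughly 1.4
#' by 2080 from a 1.04 start.
#'
#' @param years projection years.
#' @param base_year year at which the multiplier is 1 (default 2020).
#' @param final_multiplier multiplier approached by 2080 (default 1.346,
#'   i.e. 1.04 -> ~1.40).
#' @return named numeric vector of multipliers.
#' @export
default_tfr_multipliers <- function(years, base_year = 2020,
                                    final_multiplier = 1.346) {
  h <- pmax(years - base_year, 0)
  m <- 1 + (final_multiplier - 1) * (1 - exp(-h / 25)) / (1 - exp(-60 / 25))
  names(m) <- years
  m
}

#' Migration schedule with linear taper to equilibrium
#'
#' Base net-migration counts by single age and sex, scaled each year by a
#' taper: 1 at the base year, declining linearly to 0 at the equilibrium
#' year and 0 afterwards.
#'
#' @param base data frame with columns sex, age, net_migrants_per_year.
#' @param base_year taper start (default 2020).
#' @param equilibrium_year year from which net migration is 0
#'   (default 2045).
#' @return a \code{migration_schedule} list.
#' @export
migration_schedule <- function(base, base_year = 2020,
                               equilibrium_year = 2045) {
  stopifnot(all(c("sex", "age", "net_migrants_per_year") %in% names(base)))
  structure(list(base = base, base_year = base_year,
                 equilibrium_year = equilibrium_year),
            class = "migration_schedule")
}

#' @rdname migration_schedule
#' @param ms a \code{migration_schedule}.
#' @param year calendar year.
#' @return taper value in [0, 1].
#' @export
migration_taper <- function(ms, year) {
  pmin(pmax((ms$equilibrium_year - year) /
              (ms$equilibrium_year - ms$base_year), 0), 1)
}

pop_to_matrix <- function(pop, open_age = 100) {
  ages <- 0:open_age
  out <- matrix(0, length(ages), 2, dimnames = list(ages,
                                                    c("male", "female")))
  for (s in c("male", "female")) {
    sub <- pop[pop$sex == s, ]
    out[match(sub$age, ages), s] <- sub$count
  }
  out
}

matrix_to_pop <- function(mat, year) {
  data.frame(year = year,
             sex = rep(colnames(mat), each = nrow(mat)),
             age = rep(as.integer(rownames(mat)), 2),
             count = c(mat[, 1L], mat[, 2L]))
}

mig_to_matrix <- function(ms, open_age = 100) {
  pop_to_matrix(data.frame(sex = ms$base$sex, age = ms$base$age,
                           count = ms$base$net_migrants_per_year),
                open_age)
}

#' Advance a population one year
#'
#' One step of cohort-component projection: each cohort is aged forward
#' with its survival ratio L(x+1)/L(x) (open-age groups pooled with the
#' T-ratio convention), births are generated from age-specific fertility
#' applied to women aged 15--49, split by the sex ratio at birth, and
#' survived to age 0 with the birth-cohort factor L(0)/l(0); tapered
#' age-specific net migration is added at the end of the interval. Counts
#' are floored at zero (a negative count is recorded as a diagnostic
#' attribute).
#'
#' @param pop matrix of counts, ages 0..open in rows, columns male/female.
#' @param lt_male,lt_female single-age \code{lifetable}s for the year.
#' @param tfr total fertility rate for the year.
#' @param fert a \code{fertility_path} (shape, ages, srb used).
#' @param mig matrix of net migrants (same shape as \code{pop}) already
#'   multiplied by the year's taper, or NULL for none.
#' @return population matrix at t + 1, with attribute
#'   \code{negatives_floored}.
#' @export
step_population <- function(pop, lt_male, lt_female, tfr, fert,
                            mig = NULL) {
  ages <- as.integer(rownames(pop))
  open <- max(ages)
  k <- length(ages)
  out <- matrix(0, k, 2, dimnames = dimnames(pop))
  for (s in c("male", "female")) {
    lt <- if (s == "male") lt_male else lt_female
    if (max(lt$age) != open) stop("grid mismatch")
    sr <- survival_ratio(lt, ages)
    out[2:k, s] <- pop[1:(k - 1L), s] * sr[1:(k - 1L)]
    out[k, s] <- out[k, s] + pop[k, s] * sr[k]
  }
  # births
  women <- pop[match(fert$ages, ages), "female"]
  births <- tfr * sum(fert$shape * women)
  b_male <- births * fert$srb / (1 + fert$srb)
  b_female <- births - b_male
  out[1L, "male"] <- b_male * lt_male$Lx[1L] / lt_male$lx[1L]
  out[1L, "female"] <- b_female * lt_female$Lx[1L] / lt_female$lx[1L]
  if (!is.null(mig)) out <- out + mig
  neg <- sum(out < 0)
  out[out < 0] <- 0
  attr(out, "negatives_floored") <- neg
  out
}

#' Cohort-component population projection
#'
#' Projects a base-year population forward year by year under a set of
#' annual single-age life tables (one list per sex, e.g. from
#' \code{\link{projection_lifetables}}), a fertility path, and a tapering
#' migration schedule.
#'
#' @param base_pop data frame (sex, age, count) for the base year.
#' @param base_year base calendar year (default 2020).
#' @param tables_male,tables_female named lists of single-age
#'   \code{lifetable}s, names = years \code{base_year ... end-1} (a year
#'   t table drives the t -> t+1 step; the last available table is reused
#'   if a year is missing).
#' @param fert a \code{fertility_path} covering the projection years.
#' @param mig a \code{migration_schedule} or NULL.
#' @param end last projected year (default 2080).
#' @return an object of class \code{population_projection}: array
#'   age x sex x year plus metadata.
#' @export
project_population <- function(base_pop, base_year = 2020, tables_male,
                               tables_female, fert, mig = NULL,
                               end = 2080) {
  pop <- pop_to_matrix(base_pop)
  years <- base_year:end
  arr <- array(NA_real_, dim = c(nrow(pop), 2, length(years)),
               dimnames = list(rownames(pop), c("male", "female"), years))
  arr[, , 1L] <- pop
  mig_base <- if (is.null(mig)) NULL else mig_to_matrix(mig)
  floored <- 0L
  for (i in seq_along(years)[-1L]) {
    yr <- years[i - 1L]                  # the step t -> t+1 uses year-t rates
    pick <- function(tabs) {
      j <- match(as.character(yr), names(tabs))
      if (is.na(j)) tabs[[length(tabs)]] else tabs[[j]]
    }
    tfr_y <- fert$tfr[as.character(yr)]
    if (is.na(tfr_y)) tfr_y <- fert$tfr[length(fert$tfr)]
    m <- if (is.null(mig_base)) NULL else
      mig_base * migration_taper(mig, yr)
    pop <- step_population(pop, pick(tables_male), pick(tables_female),
                           tfr_y, fert, m)
    floored <- floored + attr(pop, "negatives_floored")
    arr[, , i] <- pop
  }
  structure(list(counts = arr, years = years, base_year = base_year,
                 negatives_floored = floored),
            class = "population_projection")
}

#' @export
print.population_projection <- function(x, ...) {
  tot <- apply(x$counts, 3, sum)
  o60 <- apply(x$counts[as.integer(dimnames(x$counts)[[1]]) >= 60, , ,
                        drop = FALSE], 3, sum)
  last <- length(x$years)
  cat(sprintf(
    "Population projection %d-%d\n  total: %.0f -> %.0f; 60+: %.0f -> %.0f (peak %.0f in %d)\n",
    x$years[1L], x$years[last], tot[1L], tot[last], o60[1L], o60[last],
    max(o60), x$years[which.max(o60)]))
  invisible(x)
}

#' Population aged at or above a threshold, by year
#'
#' @param proj a \code{population_projection}.
#' @param min_age lower age bound (default 60).
#' @return named numeric vector of counts by year.
#' @export
population_older <- function(proj, min_age = 60) {
  a <- as.integer(dimnames(proj$counts)[[1]])
  apply(proj$counts[a >= min_age, , , drop = FALSE], 3, sum)
}

#' Estimate a base migration schedule by census survival
#'
#' Census survival ratio method: each five-year cohort observed at the
#' first census is survived ten years forward with the intercensal life
#' tables; the difference between the observed second-census cohort and
#' its expected survivors is the decade's net migration, spread uniformly
#' over the ten years and over single ages around the cohort's
#' mid-decade age. Cohorts born between the censuses and cohorts ending
#' in the open age group are left at zero.
#'
#' @param census1,census2 data frames (sex, age_group_start, population)
#'   ten years apart, 5-year groups with infant/child split at the start.
#' @param table_male,table_female single-age \code{lifetable}s
#'   representing intercensal mortality.
#' @param base_year taper base year for the resulting schedule.
#' @param equilibrium_year taper end year.
#' @return a \code{migration_schedule} of annual net migrants by single
#'   age and sex.
#' @export
census_survival_migration <- function(census1, census2, table_male,
                                      table_female, base_year = 2020,
                                      equilibrium_year = 2045) {
  rows <- list()
  for (s in c("male", "female")) {
    lt <- if (s == "male") table_male else table_female
    c1 <- census1[census1$sex == s, ]
    c2 <- census2[census2$sex == s, ]
    ann <- rep(0, 101)
    for (a in seq(0, 85, by = 5)) {
      p1 <- if (a == 0) {
        sum(c1$population[c1$age_group_start %in% c(0, 1)])
      } else c1$population[match(a, c1$age_group_start)]
      p2 <- c2$population[match(a + 10, c2$age_group_start)]
      if (is.na(p1) || is.na(p2)) stop("missing cohort in census")
      num <- sum(lt$Lx[match((a + 10):(a + 14), lt$age)])
      den <- sum(lt$Lx[match(a:(a + 4), lt$age)])
      resid <- (p2 - p1 * num / den) / 10   # per year of the decade
      ann[(a + 5):(a + 9) + 1L] <- ann[(a + 5):(a + 9) + 1L] + resid / 5
    }
    rows[[s]] <- data.frame(sex = s, age = 0:100,
                            net_migrants_per_year = ann)
  }
  migration_schedule(do.call(rbind, rows), base_year, equilibrium_year)
}
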
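#' Configuration of the synthetic input generator
#'
#' Defines the study conditions the generator emulates: four census
#' snapshots ten years apart whose life expectancy rises (men roughly 68
#' to 80 years between 1990 and 2020, women 72 to 85), child mortality
#' falling by an order of magnitude over the period and lower for girls,
#' an in-migration-shaped population pyramid, and a disability survey
#' whose severity-specific prevalence rises steeply with age and is
#' higher for women.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param census_years four census years (default 1990, 2000, 2010,
#'   2020).
#' @param scale total population at the last census (default 64 million,
#'   a large-coastal-province magnitude).
#' @param scale_path relative total population at each census.
#' @param e0_male,e0_female life expectancy of the generating schedules
#'   at each census year.
#' @param q5_male,q5_female child mortality of the generating schedules
#'   at each census year.
#' @param growth_rate stable-population growth rate shaping each census
#'   pyramid (young-heavy early, near-stationary late).
#' @param bump_age_2020 centre age, at the last census, of the
#'   baby-boom bulge in the pyramid (default 45, so the bulge reaches 60+
#'   during the 2030s-2050s and the old-age population later peaks and
#'   declines).
#' @param bump_sd,bump_base width of the bulge and the relative size of
#'   the low-fertility base cohorts.
#' @param u5mr_noise lognormal s.d. of the annual child-mortality series
#'   around its smooth trend (default 0.01).
#' @param tfr_2020 base-year total fertility rate (default 1.04).
#' @param adl_n disability survey size (default 50000, enough to keep
#'   binomial noise below the scenario effects).
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(seed,
                         census_years = c(1990, 2000, 2010, 2020),
                         scale = 64e6,
                         scale_path = c(0.70, 0.82, 0.93, 1.00),
                         e0_male = c(68, 72, 76, 80.4),
                         e0_female = c(72, 76.5, 81, 84.7),
                         q5_male = c(0.040, 0.021, 0.010, 0.005),
                         q5_female = c(0.034, 0.017, 0.008, 0.004),
                         growth_rate = c(0.020, 0.014, 0.008, 0.004),
                         bump_age_2020 = 45, bump_sd = 18,
                         bump_base = 0.35,
                         u5mr_noise = 0.01,
                         tfr_2020 = 1.04,
                         adl_n = 50000) {
  if (missing(seed)) stop("seed is required")
  stopifnot(length(census_years) == 4, scale > 0,
            length(e0_male) == 4, length(q5_male) == 4)
  structure(list(seed = as.integer(seed), census_years = census_years,
                 scale = scale, scale_path = scale_path,
                 e0 = list(male = e0_male, female = e0_female),
                 q5 = list(male = q5_male, female = q5_female),
                 growth_rate = growth_rate,
                 bump_age_2020 = bump_age_2020, bump_sd = bump_sd,
                 bump_base = bump_base, u5mr_noise = u5mr_noise,
                 tfr_2020 = tfr_2020, adl_n = adl_n),
            class = "synth_config")
}

group_midpoints <- function(age) {
  n <- diff(age)
  c(age[-length(age)] + n / 2, age[length(age)] + 3)
}

# Gompertz-Makeham adult component plus an exponentially decaying child
# component; the two scales are solved to hit (5q0, e0) targets.
synth_mx_components <- function(age, sex) {
  mid <- group_midpoints(age)
  g <- if (sex == "male") 0.115 else 0.122
  # adult (Makeham) part ramped out below ~age 12 so the child scale
  # alone controls 5q0; the level factor acts on old ages with a tapered
  # exponent (full improvement to 65, 35% of it at 110), reproducing the
  # slower old-age decline seen in low-mortality populations
  ramp <- stats::plogis((mid - 12) / 2.5)
  wexp <- 1 - 0.65 * pmin(pmax((mid - 65) / 45, 0), 1)
  list(child = exp(-0.95 * mid),
       adult = (5e-5 + 3e-5 * exp(g * (mid - 30))) * ramp,
       wexp = wexp)
}

# evaluate a family member: child scale sc, adult level sa
synth_mx_eval <- function(comp, sc, sa) {
  sc * comp$child + comp$adult * sa^comp$wexp
}

#' Generating death-rate schedule hitting child-mortality and
#' life-expectancy targets
#'
#' Builds a Gompertz-Makeham-with-childhood-component schedule on an
#' abridged grid whose implied 5q0 and e0 equal the requested targets
#' (child and adult scale factors solved alternately to convergence).
#'
#' @param q5_target child mortality 5q0.
#' @param e0_target life expectancy at birth.
#' @param sex sex.
#' @param age abridged grid (default open at 100).
#' @return mx vector on \code{age}.
#' @export
synth_mx_schedule <- function(q5_target, e0_target, sex,
                              age = age_grid_abridged(100)) {
  comp <- synth_mx_components(age, sex)
  sc <- q5_target * 2; sa <- 1
  for (it in 1:4) {
    sc <- stats::uniroot(function(s) {
      lt <- lifetable(synth_mx_eval(comp, s, sa), age, sex = sex)
      interval_prob(lt, 0, 5) - q5_target
    }, c(1e-6, 50), tol = 1e-12)$root
    sa <- stats::uniroot(function(s) {
      lt <- lifetable(synth_mx_eval(comp, sc, s), age, sex = sex)
      lt$ex[1L] - e0_target
    }, c(1e-3, 80), tol = 1e-12)$root
  }
  synth_mx_eval(comp, sc, sa)
}

#' Generate synthetic censuses with known mortality
#'
#' Four age-sex census snapshots: each pyramid follows the stable-
#' population shape L(x) exp(-r x) of its generating life table (r
#' declining over the census years, so early pyramids are young-heavy),
#' scaled to the configured totals; death counts are Poisson draws around
#' population times the generating death rate. The generating truth
#' (schedules, life tables, e0, 5q0) is returned for recovery testing.
#'
#' @param cfg a \code{synth_config}.
#' @return list: \code{censuses} (data frame sex, year, age_group_start,
#'   population, deaths) and \code{truth} (per sex-year schedules,
#'   tables, e0, q5).
#' @export
generate_censuses <- function(cfg) {
  set.seed(cfg$seed)
  age <- age_grid_abridged(100)
  mid <- group_midpoints(age)
  rows <- list(); truth_tab <- list(); truth_e0 <- list()
  prev_pop <- list(); prev_lt <- list()
  for (i in seq_along(cfg$census_years)) {
    yr <- cfg$census_years[i]
    tot <- cfg$scale * cfg$scale_path[i]
    for (s in c("male", "female")) {
      mx <- synth_mx_schedule(cfg$q5[[s]][i], cfg$e0[[s]][i], s, age)
      lt <- lifetable(mx, age, sex = s, year = yr)
      # pyramid: survivorship shape, discounted by past growth, with a
      # baby-boom bulge whose cohorts age across the census years (at
      # working ages by the last census) over a low-fertility base
      bump_c <- cfg$bump_age_2020 - (max(cfg$census_years) - yr)
      bulge <- exp(-((mid - bump_c)^2) / (2 * cfg$bump_sd^2)) +
        cfg$bump_base
      w <- lt$Lx * exp(-cfg$growth_rate[i] * mid) * bulge
      pop <- pmax(round(tot / 2 * w / sum(w)), 5)  # avoid empty old-age cells
      # old-age cohorts are closed to migration: ages 70+ are the
      # survivors of the previous census's cohorts under intercensal
      # mortality (geometric mean of the two period tables)
      if (i > 1L) {
        p0 <- prev_pop[[s]]; lt0 <- prev_lt[[s]]
        coh_S <- function(a_from, a_to) {
          sqrt((lt0$Lx[match(a_to, age)] / lt0$Lx[match(a_from, age)]) *
                 (lt$Lx[match(a_to, age)] / lt$Lx[match(a_from, age)]))
        }
        for (a in seq(70, 95, 5))
          pop[match(a, age)] <-
            pmax(round(p0[match(a - 10, age)] * coh_S(a - 10, a)), 5)
        iT0 <- match(c(90, 100), age)
        S_open <- sqrt((lt0$Tx[iT0[2L]] / lt0$Tx[iT0[1L]]) *
                         (lt$Tx[iT0[2L]] / lt$Tx[iT0[1L]]))
        pop[match(100, age)] <-
          pmax(round(sum(p0[age >= 90]) * S_open), 5)
      }
      prev_pop[[s]] <- pop; prev_lt[[s]] <- lt
      deaths <- stats::rpois(length(pop), pop * mx)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, year = yr, age_group_start = age, population = pop,
        deaths = deaths)
      key <- paste(s, yr)
      truth_tab[[key]] <- lt
      truth_e0[[length(truth_e0) + 1L]] <- data.frame(
        sex = s, year = yr, e0 = lt$ex[1L],
        q5_0 = interval_prob(lt, 0, 5),
        q45_15 = interval_prob(lt, 15, 45),
        q15_60 = interval_prob(lt, 60, 15))
    }
  }
  list(censuses = do.call(rbind, rows),
       truth = list(tables = truth_tab,
                    summary = do.call(rbind, truth_e0)))
}

#' Generate an annual under-5 mortality series
#'
#' Smooth monotone (PCHIP on the log scale) interpolation of the
#' census-year child-mortality targets, with small lognormal noise, by
#' sex.
#'
#' @param cfg a \code{synth_config}.
#' @return data frame sex, year, q5_0 covering the census span.
#' @export
generate_u5mr <- function(cfg) {
  set.seed(cfg$seed + 1L)
  yrs <- min(cfg$census_years):max(cfg$census_years)
  rows <- lapply(c("male", "female"), function(s) {
    trend <- exp(pchip_interp(cfg$census_years, log(cfg$q5[[s]]), yrs))
    noise <- exp(stats::rnorm(length(yrs), 0, cfg$u5mr_noise))
    noise[yrs %in% cfg$census_years] <- 1   # anchored at census years
    data.frame(sex = s, year = yrs, q5_0 = trend * noise)
  })
  do.call(rbind, rows)
}

# severity probabilities for one per-item difficulty probability p
adl_severity_probs <- function(p) {
  c(none = stats::dbinom(0, 6, p),
    mild = stats::dbinom(1, 6, p) + stats::dbinom(2, 6, p),
    moderate = stats::dbinom(3, 6, p) + stats::dbinom(4, 6, p),
    severe = stats::pbinom(4, 6, p, lower.tail = FALSE))
}

adl_item_prob <- function(age, sex) {
  a <- pmax(age - 60, -15)
  stats::plogis(-1.2 + 0.018 * a + 0.00095 * a^2 +
                  0.15 * (sex == "female"))
}

#' Generate a synthetic disability survey
#'
#' Person-level records aged 45+, each with six activities-of-daily-
#' living difficulty flags drawn independently with a per-item
#' probability that is logistic in age with a female excess. The induced
#' severe-disability prevalence (5+ items) rises from under 2\% at ages
#' 60--64 to over 25\% at 95+. The generating severity probabilities per
#' prevalence cell (averaged over the drawn ages) are returned as truth.
#'
#' @param cfg a \code{synth_config}.
#' @param n number of records (default \code{cfg$adl_n}).
#' @return list: \code{records} (id, age, sex, six item flags) and
#'   \code{truth} (sex, age_group, severity, prob).
#' @export
generate_adl_survey <- function(cfg, n = cfg$adl_n) {
  set.seed(cfg$seed + 2L)
  ages <- 45:104
  w <- exp(-0.05 * (ages - 45))
  age <- sample(ages, n, replace = TRUE, prob = w)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  p <- adl_item_prob(age, sex)
  flags <- matrix(stats::runif(n * 6) < p, n, 6)
  colnames(flags) <- adl_items
  records <- data.frame(id = seq_len(n), age = age, sex = sex, flags)

  grp <- age_group_label(age)
  keep <- !is.na(grp)
  cells <- unique(data.frame(sex = sex[keep], age_group = grp[keep]))
  truth <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    in_cell <- keep & sex == cells$sex[i] & grp == cells$age_group[i]
    probs <- rowMeans(vapply(p[in_cell], adl_severity_probs,
                             numeric(4)))
    data.frame(sex = cells$sex[i], age_group = cells$age_group[i],
               severity = names(probs), prob = unname(probs))
  }))
  list(records = records, truth = truth)
}

#' Reference worked-example fixture for scenario scaling
#'
#' A frozen table of projected disabled-older-population counts (in
#' thousands) under the constant-prevalence (medium) scenario together
#' with the printed high/low scenario columns, used as the worked example
#' for the +/-0.8\%-per-year scenario factors with base year 2020. The
#' medium column times 1.008^(year-2020) reproduces the high column for
#' 2030 onward (and 0.992^(year-2020) the low column) to within the
#' 1-thousand rounding of the source table.
#'
#' @return data frame: year, older_population, severity, medium, high,
#'   low (thousands).
#' @export
table1_fixture <- function() {
  yrs <- c(2023, 2030, 2040, 2050, 2060, 2070, 2080)
  older <- c(14625, 19266, 24738, 29089, 30728, 29300, 27417)
  sev <- data.frame(year = yrs, older_population = older,
                    severity = "severe",
                    medium = c(285, 386, 592, 810, 941, 1000, 1027),
                    high = c(295, 418, 694, 1029, 1295, 1489, 1657),
                    low = c(276, 356, 504, 637, 683, 669, 634))
  mod <- data.frame(year = yrs, older_population = older,
                    severity = "moderate",
                    medium = c(288, 383, 571, 753, 848, 869, 858),
                    high = c(297, 414, 669, 956, 1166, 1294, 1384),
                    low = c(279, 353, 486, 592, 615, 582, 530))
  mild <- data.frame(year = yrs, older_population = older,
                     severity = "mild",
                     medium = c(1393, 1845, 2618, 3229, 3544, 3503, 3389),
                     high = c(1438, 1998, 3071, 4101, 4874, 5218, 5466),
                     low = c(1349, 1703, 2230, 2538, 2570, 2344, 2093))
  rbind(sev, mod, mild)
}

#' Write all pipeline input fixtures to a directory
#'
#' Emits the CSV/YAML files consumed by the pipeline stages: censuses,
#' annual child mortality, the disability survey, the log-quadratic
#' coefficient schedule, and finance/fertility configuration.
#'
#' @param dir output directory (created if needed).
#' @param cfg a \code{synth_config}.
#' @return named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cen <- generate_censuses(cfg)
  u5 <- generate_u5mr(cfg)
  adl <- generate_adl_survey(cfg)
  paths <- c(
    censuses = file.path(dir, "censuses.csv"),
    u5mr = file.path(dir, "u5mr.csv"),
    adl_survey = file.path(dir, "adl_survey.csv"),
    logquad_coefs = file.path(dir, "logquad_coefs.csv"),
    finance = file.path(dir, "finance.yaml"),
    fertility = file.path(dir, "fertility.yaml"))
  utils::write.csv(cen$censuses, paths["censuses"], row.names = FALSE)
  utils::write.csv(u5, paths["u5mr"], row.names = FALSE)
  utils::write.csv(adl$records, paths["adl_survey"], row.names = FALSE)
  file.copy(system.file("extdata", "logquad_coefs_synthetic.csv",
                        package = "ltcisim", mustWork = TRUE),
            paths["logquad_coefs"], overwrite = TRUE)
  fp <- finance_params()
  yaml::write_yaml(list(
    unit_costs_monthly = as.list(fp$unit_costs_monthly),
    shares = as.list(fp$shares),
    cost_inflation = fp$cost_inflation, premium_t0 = fp$premium_t0,
    premium_base_year = fp$premium_base_year, interest = fp$interest,
    cost_base_year = fp$cost_base_year,
    participation_rate = fp$participation_rate), paths["finance"])
  yaml::write_yaml(list(tfr_2020 = cfg$tfr_2020,
                        final_multiplier = 1.346,
                        equilibrium_migration_year = 2045,
                        srb = 1.05), paths["fertility"])
  invisible(paths)
}

#' Read finance parameters from a YAML configuration
#'
#' @param path YAML file as written by \code{\link{make_fixtures}}.
#' @return a \code{finance_params}.
#' @export
read_finance_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  finance_params(unit_costs_monthly = unlist(y$unit_costs_monthly),
                 shares = unlist(y$shares),
                 cost_inflation = y$cost_inflation,
                 premium_t0 = y$premium_t0,
                 premium_base_year = y$premium_base_year,
                 interest = y$interest, cost_base_year = y$cost_base_year,
                 participation_rate = y$participation_rate)
}
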
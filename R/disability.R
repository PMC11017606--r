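adl_items <- c("bathing", "dressing", "eating", "transferring",
               "toileting", "continence")

prev_age_groups <- function() {
  data.frame(start = c(seq(60, 95, 5), 100),
             end = c(seq(64, 99, 5), Inf),
             label = c(paste(seq(60, 95, 5), seq(64, 99, 5), sep = "-"),
                       "100+"))
}

age_group_label <- function(age) {
  g <- prev_age_groups()
  i <- findInterval(age, g$start)
  i[age < 60] <- NA_integer_
  g$label[i]
}

#' Classify disability severity from ADL difficulty counts
#'
#' Counts the six activities of daily living (bathing, dressing, eating,
#' transferring, toileting, continence) with reported difficulty:
#' 0 items is no disability, 1--2 mild, 3--4 moderate, and 5 or more
#' severe.
#'
#' @param flags logical/0-1 matrix or data frame with the six ADL item
#'   columns, one row per person (a single vector of 6 is also accepted).
#' @return factor with levels none, mild, moderate, severe.
#' @export
classify_adl <- function(flags) {
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L)
  flags <- as.matrix(flags)
  if (ncol(flags) != 6L) stop("expected 6 ADL items")
  d <- rowSums(flags > 0)
  cut(d, breaks = c(-0.5, 0.5, 2.5, 4.5, 6.5),
      labels = c("none", "mild", "moderate", "severe"))
}

#' Age-sex-severity disability prevalence from survey records
#'
#' Tabulates classified severity by sex and 5-year age group from 60--64
#' to 100+: each cell rate is the number of respondents at that severity
#' divided by the cell sample size. Respondents under 60 are ignored.
#'
#' @param records data frame with columns age, sex and the six ADL item
#'   columns (see \code{\link{classify_adl}}).
#' @param require_complete error when any age-sex cell up to 100+ has no
#'   respondents (default TRUE, since downstream demand calculations
#'   need every cell); FALSE tabulates only the cells present.
#' @return a \code{prevalence_table} data frame (sex, age_group,
#'   severity, rate, n).
#' @export
adl_prevalence <- function(records, require_complete = TRUE) {
  stopifnot(all(c("age", "sex", adl_items) %in% names(records)))
  rec <- records[records$age >= 60, ]
  sev <- classify_adl(rec[, adl_items])
  grp <- age_group_label(rec$age)
  cells <- expand.grid(sex = c("male", "female"),
                       age_group = prev_age_groups()$label,
                       stringsAsFactors = FALSE)
  empty <- character(0)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    in_cell <- rec$sex == cells$sex[i] & grp == cells$age_group[i]
    n <- sum(in_cell)
    if (n == 0L) {
      empty <- c(empty, paste(cells$sex[i], cells$age_group[i]))
      next
    }
    out[[i]] <- data.frame(
      sex = cells$sex[i], age_group = cells$age_group[i],
      severity = c("mild", "moderate", "severe"),
      rate = as.vector(table(sev[in_cell])[c("mild", "moderate",
                                             "severe")]) / n,
      n = n)
  }
  if (length(empty) && require_complete)
    stop("empty prevalence cells: ", paste(empty, collapse = ", "))
  structure(do.call(rbind, out),
            class = c("prevalence_table", "data.frame"))
}

#' Disability-change scenario
#'
#' Annual proportional change applied to every age-sex-severity
#' prevalence cell from the base year: -0.8\% per year (low, disability
#' compression), 0 (medium, constant rates), +0.8\% per year (high,
#' disability expansion).
#'
#' @param name "low", "medium" or "high".
#' @param base_year scenario base year (default 2020).
#' @return a \code{disability_scenario} list with the annual rate r.
#' @export
disability_scenario <- function(name = c("medium", "low", "high"),
                                base_year = 2020) {
  name <- match.arg(name)
  r <- c(low = -0.008, medium = 0, high = 0.008)[[name]]
  structure(list(name = name, r = r, base_year = base_year),
            class = "disability_scenario")
}

#' Scale a prevalence table to a target year under a scenario
#'
#' Multiplies every cell by (1 + r)^(year - base_year), capping rates
#' at 1.
#'
#' @param table a \code{prevalence_table}.
#' @param scenario a \code{disability_scenario}.
#' @param year target calendar year (>= base year).
#' @return the scaled \code{prevalence_table}.
#' @export
scale_prevalence <- function(table, scenario, year) {
  if (year < scenario$base_year) stop("year before scenario base year")
  f <- (1 + scenario$r)^(year - scenario$base_year)
  table$rate <- pmin(table$rate * f, 1)
  table
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Disabled older population by year, severity and scenario
#'
#' Multiplies the projected age-sex population 60+ by scenario-scaled
#' prevalence rates and sums over ages: the count of older people at each
#' disability severity, reported in thousands (rounded half away from
#' zero; unrounded values kept alongside), together with the total
#' population 60+.
#'
#' @param proj a \code{population_projection} covering ages 60+.
#' @param table a \code{prevalence_table} (base-year rates).
#' @param scenario a \code{disability_scenario}.
#' @param years years to report (default 2023:2080).
#' @return a \code{disabled_counts} data frame: year, scenario, severity,
#'   thousands, persons, older_population.
#' @export
ltc_demand <- function(proj, table, scenario, years = 2023:2080) {
  ages <- as.integer(dimnames(proj$counts)[[1]])
  grp <- age_group_label(ages)
  keep <- !is.na(grp)
  out <- list()
  for (y in years) {
    j <- match(y, proj$years)
    if (is.na(j)) stop("projection does not cover year ", y)
    tab <- scale_prevalence(table, scenario, y)
    older <- sum(proj$counts[keep, , j])
    for (sv in c("mild", "moderate", "severe")) {
      persons <- 0
      for (s in c("male", "female")) {
        rate <- tab$rate[tab$sex == s & tab$severity == sv]
        names(rate) <- tab$age_group[tab$sex == s & tab$severity == sv]
        persons <- persons +
          sum(proj$counts[keep, s, j] * rate[grp[keep]])
      }
      out[[length(out) + 1L]] <- data.frame(
        year = y, scenario = scenario$name, severity = sv,
        thousands = round_half_away(persons / 1000), persons = persons,
        older_population = older)
    }
  }
  structure(do.call(rbind, out),
            class = c("disabled_counts", "data.frame"))
}

#' @export
print.disabled_counts <- function(x, ...) {
  sev <- x[x$severity == "severe", ]
  cat(sprintf(
    "Disabled older population (%s scenario), %d-%d\n  severe: %d -> %d thousand\n",
    x$scenario[1L], min(x$year), max(x$year),
    sev$thousands[1L], sev$thousands[nrow(sev)]))
  invisible(x)
}

#' Severe-disability counts in persons, by year
#'
#' @param counts a \code{disabled_counts}.
#' @return named numeric vector (persons) by year.
#' @export
severe_persons <- function(counts) {
  sev <- counts[counts$severity == "severe", ]
  stats::setNames(sev$persons, sev$year)
}
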
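#' Life table directly from census deaths and population
#'
#' Central death rates are deaths/population by age group; cells with
#' zero recorded deaths get a continuity floor of half a death so rates
#' stay positive.
#'
#' @param census data frame with columns sex, year, age_group_start,
#'   population, deaths.
#' @param sex,year which slice to use.
#' @return a \code{lifetable} on the census grid.
#' @export
census_lifetable <- function(census, sex, year) {
  sub <- census[census$sex == sex & census$year == year, ]
  if (nrow(sub) == 0) stop("no census rows for ", sex, " ", year)
  sub <- sub[order(sub$age_group_start), ]
  mx <- pmax(sub$deaths, 0.5) / sub$population
  lifetable(mx, sub$age_group_start, sex = sex, year = year)
}

#' Estimate annual life tables with the three-parameter log-quadratic model
#'
#' Reconstructs annual life tables between censuses from three summary
#' parameters per year: child mortality 5q0 (given annually), adult
#' mortality 45q15 and old-age mortality 15q60 (anchored at knot years
#' and interpolated with monotone cubics). At census years, 45q15 comes
#' from the census life table directly and the 15q60 anchor is the
#' average of the census life-table value and the two-parameter model's
#' implied value; at intercensal midpoints the 15q60 anchor averages the
#' model-implied value with an empirical value from cohort survival of
#' the old-age census blocks. Each year the adjustment factor k is solved
#' so the model reproduces 45q15, and the old-age intercepts are shifted
#' so the table reproduces the 15q60 anchor.
#'
#' @param censuses data frame of all census-year counts (sex, year,
#'   age_group_start, population, deaths).
#' @param u5mr data frame (sex, year, q5_0) covering every estimation
#'   year.
#' @param coefs a \code{logquad_coefs} table (default the bundled
#'   synthetic schedule).
#' @param years years to estimate; default the census span.
#' @return an object of class \code{dcmd_fit}: per-sex lists of annual
#'   \code{lifetable}s, a parameter data frame (q5_0, q45_15, q15_60, k,
#'   old_age_shift, e0 per sex-year), and the census life tables.
#' @export
dcmd_estimate <- function(censuses, u5mr, coefs = read_logquad_coefs(),
                          years = NULL) {
  cys <- sort(unique(censuses$year))
  if (length(cys) < 2) stop("need at least two censuses")
  if (is.null(years)) years <- min(cys):max(cys)
  tables <- list()
  census_tables <- list()
  params <- list()
  for (s in c("male", "female")) {
    q5s <- u5mr[u5mr$sex == s, ]
    q5 <- stats::setNames(q5s$q5_0, q5s$year)
    if (!all(as.character(years) %in% names(q5)))
      stop("u5mr does not cover all estimation years for ", s)

    clt <- lapply(cys, function(cy) census_lifetable(censuses, s, cy))
    names(clt) <- cys
    census_tables[[s]] <- clt
    q45_c <- vapply(clt, interval_prob, numeric(1), from_age = 15,
                    span = 45)
    q60_emp_c <- vapply(clt, interval_prob, numeric(1), from_age = 60,
                        span = 15)

    # two-parameter model implied 15q60 at a knot (q5, 45q15 known)
    implied60 <- function(q5y, q45y) {
      k <- solve_k(coefs, q5y, q45y, sex = s)
      interval_prob(loglq_lifetable(coefs, q5y, k, sex = s), 60, 15)
    }
    q60_blend_c <- vapply(seq_along(cys), function(i)
      blend_old_age(implied60(q5[as.character(cys[i])], q45_c[i]),
                    q60_emp_c[i]), numeric(1))

    mids <- (cys[-length(cys)] + cys[-1L]) / 2
    q45_mid <- interpolate_targets(cys, q45_c, mids)
    q60_blend_mid <- vapply(seq_along(mids), function(i) {
      emp <- intercensal_old_age_q(
        censuses[censuses$sex == s & censuses$year == cys[i], ],
        censuses[censuses$sex == s & censuses$year == cys[i + 1L], ])
      q5_mid <- q5[as.character(round(mids[i]))]
      if (is.na(q5_mid)) q5_mid <- mean(q5[as.character(cys[i:(i + 1)])])
      blend_old_age(implied60(q5_mid, q45_mid[i]), emp)
    }, numeric(1))

    knots60 <- c(cys, mids)
    ord <- order(knots60)
    q45_y <- interpolate_targets(cys, q45_c, years)
    q60_y <- interpolate_targets(knots60[ord],
                                 c(q60_blend_c, q60_blend_mid)[ord],
                                 years)

    tabs <- vector("list", length(years))
    for (j in seq_along(years)) {
      y <- years[j]
      q5y <- q5[[as.character(y)]]
      k <- solve_k(coefs, q5y, q45_y[j], sex = s)
      fit <- adjust_old_age(coefs, q5y, k, q60_y[j], sex = s)
      lt <- loglq_lifetable(coefs, q5y, k, sex = s,
                            old_age_shift = fit$old_age_shift, year = y)
      tabs[[j]] <- lt
      params[[length(params) + 1L]] <- data.frame(
        sex = s, year = y, q5_0 = q5y, q45_15 = q45_y[j],
        q15_60 = q60_y[j], k = k, old_age_shift = fit$old_age_shift,
        e0 = lt$ex[1L])
    }
    names(tabs) <- years
    tables[[s]] <- tabs
  }
  structure(list(tables = tables, params = do.call(rbind, params),
                 census_tables = census_tables, years = years,
                 census_years = cys, coefs = coefs),
            class = "dcmd_fit")
}

#' @export
print.dcmd_fit <- function(x, ...) {
  rng <- range(x$years)
  for (s in c("male", "female")) {
    p <- x$params[x$params$sex == s, ]
    cat(sprintf("DCMD annual life tables, %s %d-%d: e0 %.2f -> %.2f\n",
                s, rng[1L], rng[2L], p$e0[1L], p$e0[nrow(p)]))
  }
  invisible(x)
}

#' Estimated life expectancy series
#'
#' @param fit a \code{dcmd_fit}.
#' @return data frame sex, year, e0.
#' @export
dcmd_e0 <- function(fit) {
  fit$params[, c("sex", "year", "e0")]
}

#' Log death-rate matrix from an estimated series of life tables
#'
#' @param fit a \code{dcmd_fit}.
#' @param sex which sex.
#' @return matrix of log mx, ages in rows (named), years in columns.
#' @export
dcmd_log_mx <- function(fit, sex) {
  tabs <- fit$tables[[sex]]
  M <- vapply(tabs, function(lt) log(lt$mx), numeric(nrow(tabs[[1L]])))
  rownames(M) <- tabs[[1L]]$age
  colnames(M) <- names(tabs)
  M
}
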
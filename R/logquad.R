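#' Read a log-quadratic coefficient schedule
#'
#' Coefficient files have columns \code{sex, age_group_start, a, b, c, v}:
#' for each sex and age group x, log m(x) is modelled as
#' a(x) + b(x) log(5q0) + c(x) [log(5q0)]^2 + v(x) k, where 5q0 is child
#' mortality and k the adult-mortality adjustment factor. The package
#' ships a synthetic schedule in this format (see
#' \code{\link{fit_logquad_coefs}}); published schedules in the same
#' layout can be substituted.
#'
#' @param path CSV path; default the bundled synthetic schedule.
#' @return a \code{logquad_coefs} data frame.
#' @export
read_logquad_coefs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "logquad_coefs_synthetic.csv",
                        package = "ltcisim", mustWork = TRUE)
  df <- utils::read.csv(path)
  need <- c("sex", "age_group_start", "a", "b", "c", "v")
  if (!all(need %in% names(df))) stop("missing coefficient columns")
  stopifnot(all(is.finite(df$a)), all(is.finite(df$b)),
            all(is.finite(df$c)), all(is.finite(df$v)))
  structure(df[order(df$sex, df$age_group_start), need],
            class = c("logquad_coefs", "data.frame"))
}

coefs_for_sex <- function(coefs, sex) {
  out <- coefs[coefs$sex == sex, , drop = FALSE]
  if (nrow(out) == 0) stop("no coefficients for sex ", sex)
  out
}

#' Fit log-quadratic coefficients from a library of mortality schedules
#'
#' Given a family of age-specific death-rate schedules spanning a range of
#' mortality levels, regresses log m(x) on log(5q0) and its square for
#' each age group (giving a, b, c) and takes the leading left singular
#' vector of the residual matrix as the k-loading v(x), scaled so the
#' residual scores have unit variance. This mirrors the construction of
#' published log-quadratic model life-table systems and is used to build
#' the bundled synthetic schedule.
#'
#' @param mx_list list of mx vectors on \code{age}.
#' @param age abridged age-group lower bounds.
#' @param sex sex label for the output rows.
#' @return a \code{logquad_coefs} data frame for one sex.
#' @export
fit_logquad_coefs <- function(mx_list, age, sex) {
  M <- log(do.call(cbind, mx_list))           # age x schedule
  q5 <- vapply(mx_list, function(m)
    interval_prob(lifetable(m, age, sex = sex), 0, 5), numeric(1))
  X <- cbind(1, log(q5), log(q5)^2)
  B <- t(solve(crossprod(X), crossprod(X, t(M))))  # age x 3
  R <- M - B %*% t(X)
  sv <- svd(R)
  v <- sv$u[, 1L] * sv$d[1L]
  # orient so positive k raises adult mortality, scale to unit k-variance
  adult <- age >= 15 & age < 60
  if (sum(v[adult]) < 0) v <- -v
  scores <- crossprod(R, v / sum(v^2))
  v <- v * stats::sd(scores)
  structure(data.frame(sex = sex, age_group_start = age,
                       a = B[, 1L], b = B[, 2L], c = B[, 3L], v = v),
            class = c("logquad_coefs", "data.frame"))
}

#' Death-rate schedule from the log-quadratic model
#'
#' Evaluates m(x) = exp(a'(x) + b(x) log q + c(x) (log q)^2 + v(x) k) with
#' q = 5q0, where a'(x) = a(x) + old_age_shift for ages at or above 60 and
#' a(x) below (the old-age intercept adjustment), on the coefficient
#' schedule's own age grid.
#'
#' @param coefs a \code{logquad_coefs} table (one sex's rows are selected
#'   via \code{sex}).
#' @param q5_0 child mortality, in (0, 1).
#' @param k adult-mortality adjustment factor (0 gives the two-parameter
#'   model).
#' @param sex which sex's coefficients to use.
#' @param old_age_shift intercept increment applied at ages >= 60
#'   (default 0).
#' @return a list with \code{mx}, \code{age}, \code{sex}.
#' @export
loglq_schedule <- function(coefs, q5_0, k = 0,
                           sex = c("male", "female"), old_age_shift = 0) {
  sex <- match.arg(sex)
  if (!is.finite(q5_0) || q5_0 <= 0 || q5_0 >= 1)
    stop("q5_0 must be in (0,1)")
  cf <- coefs_for_sex(coefs, sex)
  lq <- log(q5_0)
  a <- cf$a + ifelse(cf$age_group_start >= 60, old_age_shift, 0)
  mx <- exp(a + cf$b * lq + cf$c * lq^2 + cf$v * k)
  list(mx = mx, age = cf$age_group_start, sex = sex)
}

#' Life table implied by a log-quadratic fit
#'
#' @param coefs coefficient table.
#' @param q5_0,k,sex,old_age_shift model parameters, as in
#'   \code{\link{loglq_schedule}}.
#' @param year year label.
#' @return a \code{lifetable}.
#' @export
loglq_lifetable <- function(coefs, q5_0, k = 0, sex = c("male", "female"),
                            old_age_shift = 0, year = NA_integer_) {
  s <- loglq_schedule(coefs, q5_0, k, sex, old_age_shift)
  lifetable(s$mx, s$age, sex = s$sex, year = year)
}

#' Solve the adult-mortality adjustment factor k
#'
#' Finds k such that the life table implied by (5q0, k) reproduces a
#' target adult mortality 45q15, by bisection on k in [-10, 10] to an
#' absolute tolerance of 1e-8 on the probability.
#'
#' @param coefs coefficient table.
#' @param q5_0 child mortality.
#' @param q45_15_target target adult mortality, in (0, 1).
#' @param sex sex.
#' @return the solved k (scalar).
#' @export
solve_k <- function(coefs, q5_0, q45_15_target, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (q45_15_target <= 0 || q45_15_target >= 1)
    stop("target must be in (0,1)")
  f <- function(k) {
    val <- tryCatch(
      interval_prob(loglq_lifetable(coefs, q5_0, k, sex), 15, 45),
      error = function(e) NA_real_)
    # survivorship collapsing below age 15 means 45q15 is effectively 1
    if (!is.finite(val)) val <- 1
    val - q45_15_target
  }
  lo <- -10; hi <- 10
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop(sprintf(
      "target 45q15 = %.6f not attainable for k in [-10,10]: range [%.6f, %.6f]",
      q45_15_target, q45_15_target + flo, q45_15_target + fhi))
  mid <- (lo + hi) / 2
  for (it in seq_len(80L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-9 || (hi - lo) < 1e-13) break
    if (fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  mid
}

#' Old-age intercept adjustment
#'
#' Computes the increment added to the model intercepts at ages 60 and
#' above so the table reproduces a target old-age mortality 15q60. The
#' closed-form step is log(log(1 - target) / log(1 - implied)) -- the log
#' of the ratio of cumulative hazards over ages 60--75 -- which is exact
#' under piecewise-exponential survival; by default the step is iterated
#' to convergence so the rebuilt table matches the target to 1e-9.
#'
#' @param coefs coefficient table.
#' @param q5_0,k,sex model parameters already fitted.
#' @param q15_60_target target old-age mortality, in (0, 1).
#' @param refine iterate the closed-form update to convergence (default
#'   TRUE); FALSE applies the single closed-form step.
#' @return a \code{logquad_fit} list: q5_0, k, old_age_shift, sex.
#' @export
adjust_old_age <- function(coefs, q5_0, k, q15_60_target,
                           sex = c("male", "female"), refine = TRUE) {
  sex <- match.arg(sex)
  if (q15_60_target <= 0 || q15_60_target >= 1)
    stop("target must be in (0,1)")
  shift <- 0
  for (it in seq_len(if (refine) 50L else 1L)) {
    implied <- interval_prob(
      loglq_lifetable(coefs, q5_0, k, sex, old_age_shift = shift), 60, 15)
    if (implied <= 0 || implied >= 1) stop("degenerate implied 15q60")
    step <- log(log(1 - q15_60_target) / log(1 - implied))
    shift <- shift + step
    if (abs(step) < 1e-12) break
  }
  structure(list(q5_0 = q5_0, k = k, old_age_shift = shift, sex = sex),
            class = "logquad_fit")
}

#' @export
print.logquad_fit <- function(x, ...) {
  cat(sprintf(
    "Log-quadratic fit (%s%s): 5q0 = %.5f, k = %.4f, old-age shift = %.4f\n",
    x$sex, if (is.null(x$year)) "" else paste0(", ", x$year),
    x$q5_0, x$k, x$old_age_shift))
  invisible(x)
}

#' Blend model-based and empirical old-age mortality
#'
#' Arithmetic mean of the two 15q60 estimates (model-implied and
#' empirical), the equal-weight average used to anchor the old-age
#' parameter.
#'
#' @param model_q15_60,empirical_q15_60 probabilities in (0, 1).
#' @return blended probability.
#' @export
blend_old_age <- function(model_q15_60, empirical_q15_60) {
  stopifnot(model_q15_60 > 0, model_q15_60 < 1,
            empirical_q15_60 > 0, empirical_q15_60 < 1)
  (model_q15_60 + empirical_q15_60) / 2
}

#' Intercensal old-age mortality from cohort survival
#'
#' Follows the cohorts aged 60--74 at the first census to ages 70--84 at
#' the second census ten years later, and converts the observed
#' aggregate block survival S to a period 15q60 centred at the
#' intercensal midpoint with a survival model: a Gompertz hazard (level
#' and slope) is fitted to the three cohort-group survival ratios, and
#' the fitted hazard integrated over ages 60--75 gives 15q60. This
#' respects the steep age gradient of old-age mortality, which a
#' constant-hazard conversion badly overstates.
#'
#' @param census1,census2 data frames with columns
#'   \code{age_group_start, population} for one sex, ten years apart
#'   (5-year groups).
#' @return implied 15q60 at the midpoint year.
#' @export
intercensal_old_age_q <- function(census1, census2) {
  from <- c(60, 65, 70)
  p1 <- census1$population[match(from, census1$age_group_start)]
  p2 <- census2$population[match(from + 10, census2$age_group_start)]
  if (anyNA(p1) || anyNA(p2)) stop("old-age counts missing from census")
  if (any(p1 <= 0) || any(p2 < 0)) stop("degenerate cohort survival")
  Sa <- pmin(p2 / p1, 1)
  if (all(Sa >= 1)) return(0)
  # Gompertz level f and slope g fitted to the three group survivals;
  # within-group ages weighted uniformly at half-year midpoints
  block <- function(f, g, a) {
    x <- a + 0:4 + 0.5
    mean(exp(-f * (exp(g * (x + 10)) - exp(g * x)) / g))
  }
  obj <- function(par) {
    mod <- vapply(from, function(a) block(exp(par[1L]), par[2L], a),
                  numeric(1))
    sum((log(Sa) - log(pmax(mod, 1e-12)))^2)
  }
  o <- stats::optim(c(log(1e-5), 0.11), obj, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  f <- exp(o$par[1L]); g <- o$par[2L]
  1 - exp(-f * (exp(g * 75) - exp(g * 60)) / g)
}

#' Interpolate mortality targets to annual values
#'
#' Monotone cubic (PCHIP) interpolation of a parameter series through its
#' knot years: passes through the knots exactly and never overshoots the
#' local knot range, so interpolated probabilities stay within the range
#' spanned by neighbouring knots.
#'
#' @param knot_years years at which values are anchored.
#' @param values values at the knots.
#' @param years years at which to evaluate.
#' @return numeric vector of annual values.
#' @export
interpolate_targets <- function(knot_years, values, years) {
  pchip_interp(knot_years, values, years)
}
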
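#' @keywords internal
"_PACKAGE"

#' Abridged age grid
#'
#' Standard abridged grid: infant group [0,1), child group [1,5), then
#' five-year groups up to an open-ended interval.
#'
#' @param open_age start of the open interval (default 100).
#' @return integer vector of group lower bounds.
#' @export
age_grid_abridged <- function(open_age = 100) {
  stopifnot(open_age >= 10, open_age %% 5 == 0)
  c(0L, 1L, seq(5L, open_age, by = 5L))
}

# group widths for a vector of lower bounds ending in an open interval
age_widths <- function(age) {
  n <- diff(age)
  c(n, Inf)
}

#' Mean person-years lived by those dying in the infant interval
#'
#' Andreev--Kingkade style a0 as a piecewise-linear function of the infant
#' death rate, by sex. Used because a0 is the only separation factor that
#' materially moves life expectancy; all other closed intervals use the
#' midpoint convention.
#'
#' @param m0 infant central death rate.
#' @param sex "male" or "female".
#' @return a0 in years.
#' @export
ax_infant <- function(m0, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") {
    ifelse(m0 < 0.02300, 0.14929 - 1.99545 * m0,
      ifelse(m0 < 0.08307, 0.02832 + 3.26021 * m0, 0.29915))
  } else {
    ifelse(m0 < 0.01724, 0.14903 - 2.05527 * m0,
      ifelse(m0 < 0.06891, 0.04667 + 3.88089 * m0, 0.31411))
  }
}

#' Build a life table from central death rates
#'
#' Converts a schedule of central death rates m(x) on an abridged or
#' single-year grid into a full life table: probabilities of death q(x),
#' survivors l(x) from a radix of 100,000, deaths d(x), person-years L(x)
#' and T(x), and remaining life expectancy e(x). Closed intervals use
#' q = n m / (1 + (n - a) m); the open interval has q = 1 and
#' L = l / m.
#'
#' @param mx positive central death rates, one per age group.
#' @param age lower bounds of the age groups (last group open-ended);
#'   default the abridged grid implied by \code{length(mx)}.
#' @param sex "male" or "female" (drives the infant separation factor).
#' @param year calendar year label (metadata only).
#' @param ax_rule "infant_formula" (default; Andreev--Kingkade a0, midpoint
#'   elsewhere) or "midpoint" (n/2 everywhere).
#' @param radix survivors at age 0 (default 100000).
#' @return an object of class \code{lifetable}: a data frame with columns
#'   age, n, mx, ax, qx, lx, dx, Lx, Tx, ex and attributes sex and year.
#' @examples
#' lt <- lifetable(rep(0.01, 22), sex = "male", year = 2000)
#' life_expectancy(lt)
#' @export
lifetable <- function(mx, age = NULL,
                      sex = c("male", "female"), year = NA_integer_,
                      ax_rule = c("infant_formula", "midpoint"),
                      radix = 1e5) {
  sex <- match.arg(sex)
  ax_rule <- match.arg(ax_rule)
  if (any(!is.finite(mx)) || any(mx <= 0))
    stop("all mx must be positive and finite")
  k <- length(mx)
  if (is.null(age)) {
    age <- if (k == 22L) age_grid_abridged(100) else stop("supply `age`")
  }
  stopifnot(length(age) == k, !is.unsorted(age, strictly = TRUE))

  n <- age_widths(age)
  ax <- ifelse(is.finite(n), n / 2, NA_real_)
  if (ax_rule == "infant_formula" && age[1L] == 0 && n[1L] == 1)
    ax[1L] <- ax_infant(mx[1L], sex)
  ax[k] <- 1 / mx[k]

  # closed-interval qx capped just below 1 so survivorship stays positive
  qx <- ifelse(is.finite(n), pmin(n * mx / (1 + (n - ax) * mx), 1 - 1e-9), 1)
  qx[k] <- 1
  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- numeric(k)
  cl <- seq_len(k - 1L)
  Lx[cl] <- n[cl] * lx[cl + 1L] + ax[cl] * dx[cl]
  Lx[k] <- lx[k] / mx[k]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- Tx / lx

  out <- data.frame(age = age, n = n, mx = mx, ax = ax, qx = qx,
                    lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  structure(out, class = c("lifetable", "data.frame"),
            sex = sex, year = year, radix = radix)
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("Life table (%s, %s): %d age groups, open at %d+, e0 = %.2f\n",
              attr(x, "sex"), as.character(attr(x, "year")),
              nrow(x), max(x$age), x$ex[1L]))
  print.data.frame(cbind(x[, c("age", "n")],
                         round(x[, c("mx", "qx", "ax")], 5),
                         round(x[, c("lx", "Lx", "ex")], 2)),
                   row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.lifetable <- function(object, ...) {
  c(e0 = object$ex[1L],
    q5_0 = interval_prob(object, 0, 5),
    q45_15 = interval_prob(object, 15, 45),
    q15_60 = interval_prob(object, 60, 15))
}

#' Life expectancy at a given age
#'
#' @param table a \code{lifetable}.
#' @param age age at which to evaluate (default 0, i.e. at birth).
#' @return remaining life expectancy in years.
#' @export
life_expectancy <- function(table, age = 0) {
  i <- match(age, table$age)
  if (is.na(i)) stop("age not on the table grid")
  table$ex[i]
}

#' Probability of dying within an age span
#'
#' The probability that a person exact age \code{from_age} dies before
#' reaching \code{from_age + span}, i.e. 1 - l(from+span)/l(from). The
#' conventional summary parameters 5q0 (child), 45q15 (adult) and 15q60
#' (old-age mortality) are all instances of this.
#'
#' @param table a \code{lifetable}.
#' @param from_age starting exact age (must be a grid boundary).
#' @param span length of the interval in years (\code{from_age + span}
#'   must also be a grid boundary; a span of 0 gives 0).
#' @return probability in [0, 1].
#' @export
interval_prob <- function(table, from_age, span) {
  if (span == 0) return(0)
  i <- match(from_age, table$age)
  j <- match(from_age + span, table$age)
  if (is.na(i) || is.na(j)) stop("ages must lie on grid boundaries")
  1 - table$lx[j] / table$lx[i]
}

#' Graduate an abridged life table to single years of age
#'
#' Interpolates log survivorship log l(x) with a monotone cubic (PCHIP)
#' through the abridged boundaries, yielding a strictly non-increasing
#' single-age l(x); single-age q(x), d(x) and person-years follow, with the
#' open interval inheriting the abridged open-age death rate. Life
#' expectancy at birth is preserved to within about 0.1 years on smooth
#' schedules.
#'
#' @param table an abridged \code{lifetable}.
#' @return a \code{lifetable} on the single-year grid 0, 1, ..., open age.
#' @export
graduate_to_single_age <- function(table) {
  age <- table$age
  if (all(diff(age) == 1)) return(table)
  open <- max(age)
  xs <- 0:open
  llx <- pchip_interp(age, log(table$lx), xs)
  lx <- exp(llx)
  k <- length(xs)
  qx <- c(1 - lx[-1L] / lx[-k], 1)
  dx <- lx * qx
  mopen <- table$mx[nrow(table)]
  ax <- c(rep(0.5, k - 1L), 1 / mopen)
  if (age[1L] == 0) ax[1L] <- table$ax[1L]
  Lx <- c(lx[-k] - (1 - ax[-k]) * dx[-k], lx[k] / mopen)
  mx <- dx / Lx
  Tx <- rev(cumsum(rev(Lx)))
  out <- data.frame(age = xs, n = c(rep(1, k - 1L), Inf), mx = mx, ax = ax,
                    qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx,
                    ex = Tx / lx)
  structure(out, class = c("lifetable", "data.frame"),
            sex = attr(table, "sex"), year = attr(table, "year"),
            radix = attr(table, "radix"))
}

#' Lower the open age group of a life table
#'
#' Collapses all groups at or above \code{open_age} into a single open
#' interval, preserving person-years (the new open-interval L equals the
#' old T at that age), so survival quantities below the new open age are
#' unchanged.
#'
#' @param table a \code{lifetable}.
#' @param open_age new open-interval start (default 100).
#' @return a \code{lifetable} with the open group at \code{open_age}.
#' @export
truncate_open_age <- function(table, open_age = 100) {
  if (max(table$age) <= open_age) return(table)
  i <- match(open_age, table$age)
  if (is.na(i)) stop("open_age not on the grid")
  keep <- table$age < open_age
  lx_o <- table$lx[i]
  Tx_o <- table$Tx[i]
  open_row <- data.frame(age = open_age, n = Inf, mx = lx_o / Tx_o,
                         ax = Tx_o / lx_o, qx = 1, lx = lx_o, dx = lx_o,
                         Lx = Tx_o, Tx = Tx_o, ex = Tx_o / lx_o)
  out <- rbind(as.data.frame(table)[keep, ], open_row)
  rownames(out) <- NULL
  structure(out, class = c("lifetable", "data.frame"),
            sex = attr(table, "sex"), year = attr(table, "year"),
            radix = attr(table, "radix"))
}

#' Cohort survival ratio from a single-age life table
#'
#' L(x+1)/L(x), the ratio used to age a cohort from completed age x to
#' x+1 in cohort-component projection. At the open age group the ratio is
#' T(open)/T(open-1), which carries both the last closed group and the
#' open group forward together.
#'
#' @param table a single-age \code{lifetable}.
#' @param x completed age (0 to open age).
#' @return survival ratio in (0, 1].
#' @export
survival_ratio <- function(table, x) {
  age <- table$age
  if (any(diff(age) != 1)) stop("survival_ratio needs a single-age table")
  open <- max(age)
  if (any(x > open | x < 0)) stop("age off grid")
  k <- nrow(table)
  ifelse(x >= open - 1L,
         table$Tx[k] / table$Tx[k - 1L],
         table$Lx[match(x, age) + 1L] / table$Lx[match(x, age)])
}

#' Write / read life tables as CSV
#'
#' Serialization with columns sex, year, age, n, mx, qx, ax, lx, dx, Lx,
#' Tx, ex (one block per table).
#'
#' @param tables a \code{lifetable} or list of them.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_lifetables_csv <- function(tables, path) {
  if (inherits(tables, "lifetable")) tables <- list(tables)
  rows <- lapply(tables, function(lt) {
    cbind(sex = attr(lt, "sex"), year = attr(lt, "year"),
          as.data.frame(lt)[, c("age", "n", "mx", "qx", "ax",
                                "lx", "dx", "Lx", "Tx", "ex")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# fast e0 for many schedules at once: mx_mat is age-groups x schedules
e0_from_mx_mat <- function(mx_mat, age, sex) {
  mx_mat <- as.matrix(mx_mat)
  k <- nrow(mx_mat)
  n <- age_widths(age)
  ax <- matrix(rep(ifelse(is.finite(n), n / 2, NA_real_), ncol(mx_mat)),
               nrow = k)
  if (age[1L] == 0 && n[1L] == 1)
    ax[1L, ] <- ax_infant(mx_mat[1L, ], sex)
  nm <- matrix(rep(ifelse(is.finite(n), n, 0), ncol(mx_mat)), nrow = k)
  qx <- pmin(nm * mx_mat / (1 + (nm - ax) * mx_mat), 1)
  qx[k, ] <- 1
  px <- 1 - qx
  lx <- apply(rbind(1, px[-k, , drop = FALSE]), 2, cumprod)
  dx <- lx * qx
  Lx <- nm * rbind(lx[-1L, , drop = FALSE], 0) + ax * dx
  Lx[k, ] <- lx[k, ] / mx_mat[k, ]
  colSums(Lx)
}
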
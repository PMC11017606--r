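#' Fit a Lee-Carter mortality model
#'
#' Decomposes a log death-rate surface as log m(x,t) = alpha(x) +
#' beta(x) kappa(t): alpha is the row (age) mean, (beta, kappa) come from
#' the rank-1 SVD of the centred matrix, normalised so beta sums to 1 and
#' kappa sums to 0 over the fitting window. A second stage (default on)
#' re-solves each kappa(t) so the life table implied by
#' alpha + beta kappa(t) reproduces that year's life expectancy at birth,
#' which is the appropriate refit when the inputs are model-based life
#' tables rather than raw death counts. The period index is then summarised
#' by its drift (mean annual increment) and the standard deviation of the
#' increments about the drift, the random-walk-with-drift forecast basis.
#'
#' @param log_mx matrix of log death rates, ages in rows, years in
#'   columns (column names = years).
#' @param age age-group lower bounds (rows).
#' @param sex sex (used for life-table construction).
#' @param match_e0 re-solve kappa per year to match each year's e0
#'   (default TRUE).
#' @return an object of class \code{lc_fit} with elements alpha, beta,
#'   kappa, drift, sigma, age, years, sex, jumpoff_mx.
#' @export
fit_lc <- function(log_mx, age, sex = c("male", "female"),
                   match_e0 = TRUE) {
  sex <- match.arg(sex)
  log_mx <- as.matrix(log_mx)
  if (anyNA(log_mx) || any(!is.finite(log_mx))) stop("missing cells")
  if (ncol(log_mx) < 10L) stop("need at least 10 years")
  years <- as.integer(colnames(log_mx))
  if (anyNA(years)) years <- seq_len(ncol(log_mx))
  alpha <- rowMeans(log_mx)
  Z <- log_mx - alpha
  if (max(abs(Z)) < 1e-12) stop("degenerate (constant) surface")
  sv <- svd(Z)
  beta <- sv$u[, 1L]
  kappa <- sv$v[, 1L] * sv$d[1L]
  s <- sum(beta)
  if (abs(s) < 1e-12) stop("degenerate age loading")
  beta <- beta / s
  kappa <- kappa * s
  kappa <- kappa - mean(kappa)           # centre; absorbed by alpha below
  alpha <- rowMeans(log_mx - outer(beta, kappa))

  if (match_e0) {
    e0_obs <- e0_from_mx_mat(exp(log_mx), age, sex)
    kappa <- vapply(seq_along(kappa), function(j) {
      f <- function(k) e0_from_mx_mat(exp(alpha + beta * k), age, sex) -
        e0_obs[j]
      stats::uniroot(f, lower = kappa[j] - 30, upper = kappa[j] + 30,
                     extendInt = "downX", tol = 1e-9)$root
    }, numeric(1))
    # re-centre kappa, absorbing the mean into alpha so fitted rates
    # (and hence the matched e0) are unchanged
    m <- mean(kappa)
    alpha <- alpha + beta * m
    kappa <- kappa - m
  }
  Tn <- length(kappa)
  drift <- (kappa[Tn] - kappa[1L]) / (Tn - 1L)
  sigma <- stats::sd(diff(kappa) - drift)
  structure(list(alpha = alpha, beta = beta, kappa = kappa,
                 drift = drift, sigma = sigma, age = age, years = years,
                 sex = sex,
                 jumpoff_mx = exp(alpha + beta * kappa[Tn])),
            class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf(
    "Lee-Carter fit (%s), %d ages x %d years (%d-%d)\n  drift = %.4f, sigma = %.4f, jump-off e0 = %.2f\n",
    x$sex, length(x$age), length(x$years), min(x$years), max(x$years),
    x$drift, x$sigma,
    e0_from_mx_mat(x$jumpoff_mx, x$age, x$sex)))
  invisible(x)
}

#' @export
coef.lc_fit <- function(object, ...) {
  list(alpha = object$alpha, beta = object$beta, kappa = object$kappa,
       drift = object$drift, sigma = object$sigma)
}

#' Rotation parameters for long-horizon Lee-Carter projection
#'
#' In low-mortality populations the decline of death rates decelerates at
#' young ages and accelerates at old ages, so a static age loading is
#' anomalous over long horizons. The loading is rotated toward an
#' "ultimate" schedule as projected life expectancy rises from
#' \code{e0_start} to \code{e0_end}.
#'
#' @param e0_start life expectancy at which rotation begins (default 80).
#' @param e0_end life expectancy at which rotation is complete
#'   (default 102).
#' @param p smoothness power of the rotation weight, in (0, 1]
#'   (default 0.5).
#' @return a \code{rotation_params} list.
#' @export
rotation_params <- function(e0_start = 80, e0_end = 102, p = 0.5) {
  stopifnot(e0_start < e0_end, p > 0, p <= 1)
  structure(list(e0_start = e0_start, e0_end = e0_end, p = p),
            class = "rotation_params")
}

#' Ultimate age loading for rotation
#'
#' Replaces the loading below age 65 by its mean over ages 15--64 and
#' tapers ages 65 and above linearly in age from that mean toward a small
#' positive floor at the oldest age, then renormalises to sum 1. The
#' result shifts projected mortality decline from young toward old ages.
#'
#' @param beta normalised age loading (sums to 1).
#' @param age age-group lower bounds.
#' @return ultimate loading, summing to 1.
#' @export
ultimate_beta <- function(beta, age) {
  stopifnot(length(beta) == length(age))
  young <- age >= 15 & age < 65
  old <- age >= 65
  b_young <- mean(beta[young])
  u <- beta
  u[age < 65] <- b_young
  amax <- max(age)
  floor_val <- b_young * 0.05
  u[old] <- b_young + (floor_val - b_young) * (age[old] - 65) / (amax - 65)
  u / sum(u)
}

#' Rotation weight
#'
#' Weight w in [0, 1] on the ultimate loading as a smooth monotone
#' function of projected life expectancy: 0 at or below \code{e0_start},
#' 1 at or above \code{e0_end}, and
#' w = [ (1 + sin(pi (s - 1/2))) / 2 ]^p in between, with s the position
#' of e0 within the rotation window.
#'
#' @param e0 life expectancy (vectorised).
#' @param rp a \code{\link{rotation_params}} object.
#' @return weights in [0, 1].
#' @export
rotation_weight <- function(e0, rp = rotation_params()) {
  s <- (e0 - rp$e0_start) / (rp$e0_end - rp$e0_start)
  s <- pmin(pmax(s, 0), 1)
  (0.5 * (1 + sin(pi * (s - 0.5))))^rp$p
}

#' Project mortality with rotation and simulation intervals
#'
#' Forecasts the period index as a random walk with drift, simulating
#' \code{n_sims} trajectories (innovation noise plus, by default, drift
#' estimation uncertainty). The age loading applied to each year's index
#' increment is the rotated blend (1 - w) beta + w beta_ultimate,
#' renormalised, with w driven by the deterministic mean life-expectancy
#' path so trajectories remain exchangeable. Death-rate surfaces are
#' rebuilt per trajectory from the jump-off rates, and the life-expectancy
#' path is summarised by its mean and 2.5/97.5 percentiles. Scenario
#' surfaces for the lower/upper life-expectancy bounds use the per-year
#' 97.5/2.5 percentile paths of the simulated index (life expectancy is
#' monotone decreasing in the index).
#'
#' @param fit an \code{lc_fit}.
#' @param rp rotation parameters; NULL disables rotation (classic
#'   Lee-Carter).
#' @param horizon_end last projected year (default 2080).
#' @param n_sims number of simulated trajectories (default 1000; fewer
#'   than 100 is recorded as a warning flag in the result).
#' @param seed integer seed (mandatory, for reproducibility).
#' @param drift_uncertainty include drift-estimation uncertainty
#'   (default TRUE).
#' @return an object of class \code{lc_projection}: years, e0 summary
#'   (mean, lo95, hi95), mean mx surface, scenario mx surfaces
#'   (\code{mean}, \code{lo95}, \code{hi95} life-expectancy paths), the
#'   rotated loadings, and metadata.
#' @export
lc_project <- function(fit, rp = rotation_params(), horizon_end = 2080,
                       n_sims = 1000, seed, drift_uncertainty = TRUE) {
  stopifnot(inherits(fit, "lc_fit"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  low_sims <- n_sims < 100
  jump_year <- max(fit$years)
  yrs <- seq(jump_year + 1L, horizon_end)
  H <- length(yrs)
  age <- fit$age
  ub <- ultimate_beta(fit$beta, age)

  # deterministic mean path: drift only, rotation driven by its own e0
  log_m_det <- log(fit$jumpoff_mx)
  e0_det <- numeric(H)
  betas <- matrix(NA_real_, length(age), H)
  e0_prev <- e0_from_mx_mat(fit$jumpoff_mx, age, fit$sex)
  for (h in seq_len(H)) {
    w <- if (is.null(rp)) 0 else rotation_weight(e0_prev, rp)
    bt <- (1 - w) * fit$beta + w * ub
    bt <- bt / sum(bt)
    betas[, h] <- bt
    log_m_det <- log_m_det + bt * fit$drift
    e0_det[h] <- e0_from_mx_mat(exp(log_m_det), age, fit$sex)
    e0_prev <- e0_det[h]
  }

  # simulated kappa increments about the jump-off index
  drift_i <- fit$drift +
    if (drift_uncertainty) stats::rnorm(n_sims, 0, fit$sigma /
                                          sqrt(length(fit$kappa) - 1L))
    else rep(0, n_sims)
  eps <- matrix(stats::rnorm(H * n_sims, 0, fit$sigma), H, n_sims)
  dk <- sweep(eps, 2, drift_i, "+")           # H x n_sims increments
  kap_path <- apply(dk, 2, cumsum)
  if (H == 1L) kap_path <- matrix(kap_path, 1L)

  # e0 per trajectory per year
  e0_traj <- matrix(NA_real_, H, n_sims)
  log_m <- matrix(log(fit$jumpoff_mx), length(age), n_sims)
  for (h in seq_len(H)) {
    log_m <- log_m + outer(betas[, h], dk[h, ])
    e0_traj[h, ] <- e0_from_mx_mat(exp(log_m), age, fit$sex)
  }
  e0_mean <- rowMeans(e0_traj)
  e0_lo <- apply(e0_traj, 1, stats::quantile, probs = 0.025, names = FALSE)
  e0_hi <- apply(e0_traj, 1, stats::quantile, probs = 0.975, names = FALSE)

  # scenario kappa paths -> mx surfaces (hi e0 <-> low kappa)
  kq_lo_e0 <- apply(kap_path, 1, stats::quantile, probs = 0.975, names = FALSE)
  kq_hi_e0 <- apply(kap_path, 1, stats::quantile, probs = 0.025, names = FALSE)
  kq_mean <- cumsum(rep(fit$drift, H))
  surf <- function(kpath) {
    dkp <- diff(c(0, kpath))
    lm <- log(fit$jumpoff_mx)
    out <- matrix(NA_real_, length(age), H, dimnames = list(age, yrs))
    for (h in seq_len(H)) {
      lm <- lm + betas[, h] * dkp[h]
      out[, h] <- exp(lm)
    }
    out
  }
  surfaces <- list(mean = surf(kq_mean), lo95 = surf(kq_lo_e0),
                   hi95 = surf(kq_hi_e0))

  e0_tab <- data.frame(year = yrs, mean = e0_mean, lo95 = e0_lo,
                       hi95 = e0_hi, det = e0_det)
  structure(list(years = yrs, age = age, sex = fit$sex, e0 = e0_tab,
                 mx = surfaces, betas = betas, fit = fit, rp = rp,
                 n_sims = n_sims, seed = seed,
                 drift_uncertainty = drift_uncertainty,
                 low_sims_warning = low_sims),
            class = "lc_projection")
}

#' @export
predict.lc_fit <- function(object, horizon_end = 2080,
                           rp = rotation_params(), n_sims = 1000, seed,
                           ...) {
  lc_project(object, rp = rp, horizon_end = horizon_end,
             n_sims = n_sims, seed = seed, ...)
}

#' @export
print.lc_projection <- function(x, ...) {
  last <- nrow(x$e0)
  cat(sprintf(
    "Lee-Carter projection (%s) to %d, %d trajectories%s\n  e0 %d: %.2f [%.2f, %.2f]\n",
    x$sex, max(x$years), x$n_sims,
    if (x$low_sims_warning) " [warning: < 100 trajectories]" else "",
    x$e0$year[last], x$e0$mean[last], x$e0$lo95[last], x$e0$hi95[last]))
  invisible(x)
}

#' Annual single-age life tables from a projected mortality surface
#'
#' @param proj an \code{lc_projection}.
#' @param scenario "mean", "lo95" or "hi95" (life-expectancy scenario).
#' @param open_age if not NULL, collapse the tables' open interval to
#'   this age (e.g. 100 for projection against a census-style grid).
#' @return named list of single-age \code{lifetable}s, one per year.
#' @export
projection_lifetables <- function(proj, scenario = c("mean", "lo95",
                                                     "hi95"),
                                  open_age = NULL) {
  scenario <- match.arg(scenario)
  S <- proj$mx[[scenario]]
  out <- lapply(seq_along(proj$years), function(j) {
    lt <- graduate_to_single_age(
      lifetable(S[, j], proj$age, sex = proj$sex, year = proj$years[j]))
    if (!is.null(open_age)) lt <- truncate_open_age(lt, open_age)
    lt
  })
  names(out) <- proj$years
  out
}

#' Write the life-expectancy summary of a projection to CSV
#'
#' @param projs list of \code{lc_projection} (e.g. one per sex).
#' @param path output CSV (columns sex, year, mean, lo95, hi95).
#' @return path, invisibly.
#' @export
write_e0_csv <- function(projs, path) {
  rows <- lapply(projs, function(p)
    cbind(sex = p$sex, p$e0[, c("year", "mean", "lo95", "hi95")]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
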
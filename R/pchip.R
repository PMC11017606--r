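#' Monotone piecewise-cubic (PCHIP) interpolation
#'
#' Fritsch--Carlson shape-preserving cubic Hermite interpolation. The
#' interpolant passes through every knot exactly and never overshoots the
#' local knot range, which makes it the standard choice for interpolating
#' demographic rate series between sparse anchor years (probabilities stay
#' probabilities, monotone segments stay monotone).
#'
#' @param x numeric vector of knot locations, strictly increasing.
#' @param y numeric vector of knot values, same length as \code{x}.
#' @param xout numeric vector of evaluation points (inside or at the knot
#'   range; no extrapolation is performed).
#' @return numeric vector of interpolated values at \code{xout}.
#' @examples
#' pchip_interp(c(1990, 2000, 2010), c(0.05, 0.03, 0.01), 1990:2010)
#' @export
pchip_interp <- function(x, y, xout) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 knots")
  if (anyDuplicated(x)) stop("duplicate knots")
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (any(diff(x) <= 0)) stop("knots must be strictly increasing")
  if (any(xout < x[1L] - 1e-12) || any(xout > x[length(x)] + 1e-12))
    stop("xout outside knot range; extrapolation not supported")

  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  d <- pchip_slopes(h, delta)

  # locate interval for each xout
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= n] <- n - 1L
  t <- (xout - x[idx]) / h[idx]
  # cubic Hermite basis
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[idx] + h10 * h[idx] * d[idx] +
    h01 * y[idx + 1L] + h11 * h[idx] * d[idx + 1L]
}

# Fritsch-Carlson derivative estimates at the knots.
pchip_slopes <- function(h, delta) {
  n <- length(h) + 1L
  d <- numeric(n)
  if (n == 2L) {
    d[] <- delta
    return(d)
  }
  # interior: weighted harmonic mean where slopes agree in sign, else 0
  for (k in 2:(n - 1L)) {
    if (delta[k - 1L] * delta[k] > 0) {
      w1 <- 2 * h[k] + h[k - 1L]
      w2 <- h[k] + 2 * h[k - 1L]
      d[k] <- (w1 + w2) / (w1 / delta[k - 1L] + w2 / delta[k])
    } else {
      d[k] <- 0
    }
  }
  d[1L] <- pchip_end_slope(h[1L], h[2L], delta[1L], delta[2L])
  d[n] <- pchip_end_slope(h[n - 1L], h[n - 2L], delta[n - 1L], delta[n - 2L])
  d
}

# One-sided three-point end condition with monotonicity clamp.
pchip_end_slope <- function(h1, h2, del1, del2) {
  d <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
  if (sign(d) != sign(del1)) {
    d <- 0
  } else if (sign(del1) != sign(del2) && abs(d) > abs(3 * del1)) {
    d <- 3 * del1
  }
  d
}
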
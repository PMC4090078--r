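#' Uniform 1-D grids for continuous opinions
#'
#' Continuous opinions are handled as densities sampled on a uniform grid
#' with inclusive endpoints; all integrals use the trapezoid rule.  A
#' 100-point grid is enough for figure-style runs; quantitative work uses
#' 2001 points spanning at least six standard deviations beyond every
#' anchor involved.
#'
#' @param x_lo,x_hi grid endpoints, `x_lo < x_hi`.
#' @param n_points number of points, at least 2.
#' @return an object of class `opinion_grid` with elements `x_lo`, `x_hi`,
#'   `n_points`, `x` (the points) and `dx` (the spacing).
#' @export
opinion_grid <- function(x_lo, x_hi, n_points = 2001L) {
  if (!is.numeric(x_lo) || !is.numeric(x_hi) || x_lo >= x_hi)
    stop("'x_lo' must be strictly less than 'x_hi'")
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("'n_points' must be at least 2")
  x <- seq(x_lo, x_hi, length.out = n_points)
  structure(list(x_lo = x_lo, x_hi = x_hi, n_points = n_points,
                 x = x, dx = x[2L] - x[1L]),
            class = "opinion_grid")
}

#' @export
print.opinion_grid <- function(x, ...) {
  cat(sprintf("Uniform grid: [%g, %g], %d points (dx = %g)\n",
              x$x_lo, x$x_hi, x$n_points, x$dx))
  invisible(x)
}

# trapezoid integral of sampled values on a uniform grid
trapz <- function(y, dx) dx * (sum(y) - (y[1L] + y[length(y)]) / 2)

same_grid <- function(g1, g2) {
  g1$n_points == g2$n_points &&
    isTRUE(all.equal(g1$x_lo, g2$x_lo, tolerance = 1e-12)) &&
    isTRUE(all.equal(g1$x_hi, g2$x_hi, tolerance = 1e-12))
}

#' Grid-discretized opinion densities
#'
#' @param grid an [opinion_grid()].
#' @param density nonnegative density values at the grid points.
#' @param normalize if `TRUE` (default) the values are rescaled so the
#'   trapezoid integral is exactly 1; if `FALSE` the integral must already
#'   be 1 within `1e-6`.
#' @return an object of class `grid_opinion` with elements `grid` and
#'   `density`.
#' @seealso [gaussian_opinion()], [bump_opinion()], [revise_density()]
#' @export
grid_opinion <- function(grid, density, normalize = TRUE) {
  stopifnot(inherits(grid, "opinion_grid"))
  density <- as.numeric(density)
  if (length(density) != grid$n_points)
    stop("'density' must have one value per grid point")
  if (anyNA(density) || any(density < 0))
    stop("density values must be nonnegative and free of NA")
  z <- trapz(density, grid$dx)
  if (z <= 0) stop("density integrates to zero")
  if (normalize) {
    density <- density / z
  } else if (abs(z - 1) > 1e-6) {
    stop(sprintf("density integrates to %.8g, not 1 (tolerance 1e-6)", z))
  }
  structure(list(grid = grid, density = density), class = "grid_opinion")
}

#' @export
print.grid_opinion <- function(x, ...) {
  cat(sprintf("Grid opinion on [%g, %g] (%d points); mode near x = %g\n",
              x$grid$x_lo, x$grid$x_hi, x$grid$n_points,
              x$grid$x[which.max(x$density)]))
  invisible(x)
}

#' Gaussian opinion parameters
#'
#' The anchor `mu` is the most probable value (the centre of the latitude
#' of acceptance); `sigma` quantifies the opinion's uncertainty.
#'
#' @param mu anchor (mean).
#' @param sigma dispersion, strictly positive.
#' @return an object of class `gaussian_params`.
#' @export
gaussian_params <- function(mu, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu))
    stop("'mu' must be a finite scalar")
  structure(list(mu = mu, sigma = sigma), class = "gaussian_params")
}

#' Gaussian opinion on a grid
#'
#' @param params a [gaussian_params()] object.
#' @param grid an [opinion_grid()].  A warning is issued if the grid does
#'   not span at least `mu +/- 5 sigma`, since truncation then distorts the
#'   quadrature normalization.
#' @return a [grid_opinion()].
#' @examples
#' g <- opinion_grid(-10, 10, 2001)
#' p <- gaussian_opinion(gaussian_params(0, 1), g)
#' @export
gaussian_opinion <- function(params, grid) {
  stopifnot(inherits(params, "gaussian_params"), inherits(grid, "opinion_grid"))
  if (grid$x_lo > params$mu - 5 * params$sigma ||
      grid$x_hi < params$mu + 5 * params$sigma)
    warning("grid does not span mu +/- 5 sigma; normalization may be crude")
  grid_opinion(grid, stats::dnorm(grid$x, params$mu, params$sigma))
}

#' Bump-function opinion on a grid
#'
#' A smooth opinion with strictly bounded support: the density is
#' proportional to `exp(-b / (1 - x^2))` on `(-1, 1)` and exactly zero at
#' and beyond `|x| = 1`, yet infinitely differentiable everywhere.  Large
#' `b` gives a single Gaussian-like peak; small `b` approaches a uniform
#' opinion on the support.  The normalization constant is computed
#' numerically for each `b`.
#'
#' @param b sharpness parameter, strictly positive.
#' @param grid an [opinion_grid()] covering `[-1, 1]`.
#' @return a [grid_opinion()].
#' @examples
#' g <- opinion_grid(-1, 1, 401)
#' flat  <- bump_opinion(0.01, g)
#' peaky <- bump_opinion(5, g)
#' @export
bump_opinion <- function(b, grid) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0)
    stop("'b' must be a positive scalar")
  stopifnot(inherits(grid, "opinion_grid"))
  if (grid$x_lo > -1 || grid$x_hi < 1)
    stop("grid must cover the bump support [-1, 1]")
  d <- numeric(grid$n_points)
  inside <- abs(grid$x) < 1
  d[inside] <- exp(-b / (1 - grid$x[inside]^2))
  grid_opinion(grid, d)
}

#' Opinion revision for densities
#'
#' Applies the discrete revision rule pointwise to two densities on a
#' common grid and renormalizes by quadrature.  This agrees with the
#' discrete rule applied to bin masses up to terms of the order of the grid
#' spacing.
#'
#' @param p,q [grid_opinion()] objects on the same grid.
#' @param params a [revision_params()] object.
#' @return the revised [grid_opinion()].
#' @examples
#' g <- opinion_grid(-10, 10, 1001)
#' p <- gaussian_opinion(gaussian_params(0, 1), g)
#' q <- gaussian_opinion(gaussian_params(2, 1), g)
#' pt <- revise_density(p, q, revision_params(0.5))
#' @export
revise_density <- function(p, q, params) {
  stopifnot(inherits(p, "grid_opinion"), inherits(q, "grid_opinion"),
            inherits(params, "revision_params"))
  if (!same_grid(p$grid, q$grid))
    stop("'p' and 'q' live on different grids")
  eps <- params$epsilon
  if (eps == 0 && params$variant != "project_then_average") {
    if (all(p$density > 0)) return(q)
    stop("degenerate revision: at epsilon = 0 the rule is discontinuous ",
         "when the prior density has zeros")
  }
  w <- revise_kernel(p$density, q$density, eps, params$variant)
  if (all(w == 0))
    stop("degenerate revision: the revised density vanishes everywhere")
  grid_opinion(p$grid, w)
}

#' Social-judgment latitudes of a Gaussian opinion
#'
#' Partitions the opinion axis into the latitude of acceptance
#' (`|x - mu| <= 2 sigma`), the latitude of non-commitment
#' (`2 sigma < |x - mu| <= 3 sigma`, two intervals) and the latitude of
#' rejection (`|x - mu| > 3 sigma`, two half-lines), following the
#' two-and-three-sigma rule.  For a Gaussian opinion the three zones carry
#' 95.4%, 4.3% and 0.3% of the probability.
#'
#' @param params a [gaussian_params()] object.
#' @return an object of class `latitudes` with elements `acceptance`
#'   (interval), `non_commitment` (list of two intervals) and `rejection`
#'   (list of two half-lines), plus the defining `mu` and `sigma`.
#' @examples
#' latitudes(gaussian_params(0, 1))$acceptance   # c(-2, 2)
#' @export
latitudes <- function(params) {
  stopifnot(inherits(params, "gaussian_params"))
  mu <- params$mu; s <- params$sigma
  structure(list(
    acceptance = c(mu - 2 * s, mu + 2 * s),
    non_commitment = list(c(mu - 3 * s, mu - 2 * s),
                          c(mu + 2 * s, mu + 3 * s)),
    rejection = list(c(-Inf, mu - 3 * s), c(mu + 3 * s, Inf)),
    mu = mu, sigma = s), class = "latitudes")
}

#' @export
print.latitudes <- function(x, ...) {
  cat(sprintf("Latitudes of a Gaussian opinion (mu = %g, sigma = %g)\n",
              x$mu, x$sigma))
  cat(sprintf("  acceptance     : [%g, %g]\n",
              x$acceptance[1], x$acceptance[2]))
  cat(sprintf("  non-commitment : [%g, %g] and [%g, %g]\n",
              x$non_commitment[[1]][1], x$non_commitment[[1]][2],
              x$non_commitment[[2]][1], x$non_commitment[[2]][2]))
  cat(sprintf("  rejection      : beyond |x - %g| > %g\n", x$mu, 3 * x$sigma))
  invisible(x)
}

# cumulative trapezoid mass of a grid opinion up to point b (linear
# interpolation inside the cell containing b)
cum_mass_to <- function(op, b) {
  x <- op$grid$x; d <- op$density; dx <- op$grid$dx
  if (b <= x[1L]) return(0)
  n <- length(x)
  if (b >= x[n]) return(trapz(d, dx))
  i <- findInterval(b, x)           # x[i] <= b < x[i+1]
  base <- if (i > 1L) trapz(d[1:i], dx) else 0
  t <- (b - x[i]) / dx
  db <- d[i] + t * (d[i + 1L] - d[i])
  base + t * dx * (d[i] + db) / 2
}

#' Probability mass of the three latitudes
#'
#' Quadrature masses of the acceptance, non-commitment and rejection zones
#' of an arbitrary grid opinion.  The three masses partition the opinion's
#' total probability, so they sum to 1 (up to quadrature truncation of the
#' tails outside the grid, which is why the grid must cover the rejection
#' boundaries).
#'
#' @param op a [grid_opinion()].
#' @param lat a [latitudes()] object whose 3-sigma boundaries lie inside
#'   the grid.
#' @return named numeric vector `c(acceptance=, non_commitment=,
#'   rejection=)`.
#' @examples
#' g <- opinion_grid(-10, 10, 4001)
#' p <- gaussian_opinion(gaussian_params(0, 1), g)
#' latitude_masses(p, latitudes(gaussian_params(0, 1)))  # ~ .954 .043 .003
#' @export
latitude_masses <- function(op, lat) {
  stopifnot(inherits(op, "grid_opinion"), inherits(lat, "latitudes"))
  b <- c(lat$mu - 3 * lat$sigma, lat$mu - 2 * lat$sigma,
         lat$mu + 2 * lat$sigma, lat$mu + 3 * lat$sigma)
  if (b[1] < op$grid$x_lo || b[4] > op$grid$x_hi)
    stop("grid too narrow: it must cover the 3-sigma rejection boundaries")
  total <- trapz(op$density, op$grid$dx)
  f <- vapply(b, function(z) cum_mass_to(op, z), numeric(1))
  acc <- f[3] - f[2]
  nc <- (f[2] - f[1]) + (f[4] - f[3])
  rej <- total - (f[4] - f[1])
  c(acceptance = acc, non_commitment = nc, rejection = rej)
}
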
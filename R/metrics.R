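# Extract a mass-1 probability vector (discrete) or density (grid) together
# with the quadrature weight needed to integrate products of densities.
metric_values <- function(x) {
  if (inherits(x, "discrete_opinion")) {
    list(v = x$weights / x$total_mass, dx = NA_real_, grid = NULL)
  } else if (inherits(x, "grid_opinion")) {
    list(v = x$density, dx = x$grid$dx, grid = x$grid)
  } else {
    v <- as.numeric(x)
    if (anyNA(v) || any(v < 0)) stop("weights must be nonnegative")
    list(v = v / sum(v), dx = NA_real_, grid = NULL)
  }
}

metric_pair <- function(p, q) {
  a <- metric_values(p); b <- metric_values(q)
  if (xor(is.null(a$grid), is.null(b$grid)))
    stop("cannot mix discrete and grid opinions in a distance")
  if (!is.null(a$grid) && !same_grid(a$grid, b$grid))
    stop("grid opinions live on different grids")
  if (is.null(a$grid) && length(a$v) != length(b$v))
    stop("discrete opinions have different numbers of events")
  list(p = a$v, q = b$v, dx = a$dx)
}

overlap_integral <- function(pr) {
  if (is.na(pr$dx)) sum(sqrt(pr$p * pr$q)) else trapz(sqrt(pr$p * pr$q), pr$dx)
}

#' Hellinger distance between two opinions
#'
#' Overlap-based metric on the unit interval:
#' \deqn{H(p, q)^2 = 1 - \int \sqrt{p(x) q(x)}\, dx,}
#' with the integral replaced by a sum for discrete opinions.  `H = 0` iff
#' the opinions coincide and `H = 1` iff their supports are disjoint.
#' Opinions with unequal total mass are compared on their mass-1
#' rescalings.
#'
#' @param p,q two [discrete_opinion()]s, two [grid_opinion()]s on the same
#'   grid, or plain nonnegative vectors of equal length.
#' @return a scalar in `[0, 1]`.
#' @seealso [hellinger_gaussian()] for the Gaussian closed form,
#'   [total_variation()], [distance_report()]
#' @export
hellinger <- function(p, q) {
  pr <- metric_pair(p, q)
  # (1/2) * integral (sqrt p - sqrt q)^2 equals 1 - overlap for mass-1
  # inputs, but is free of the catastrophic cancellation the overlap form
  # suffers near identical opinions (which floors it at ~1e-8)
  d2 <- (sqrt(pr$p) - sqrt(pr$q))^2
  h2 <- 0.5 * if (is.na(pr$dx)) sum(d2) else trapz(d2, pr$dx)
  sqrt(min(1, h2))
}

#' Bhattacharyya overlap
#'
#' The overlap integral \eqn{\int \sqrt{pq}} itself; identically
#' `1 - hellinger(p, q)^2`.
#'
#' @inheritParams hellinger
#' @return a scalar in `[0, 1]`.
#' @export
bhattacharyya <- function(p, q) {
  pr <- metric_pair(p, q)
  min(1, max(0, overlap_integral(pr)))
}

#' Hellinger distance between two Gaussian opinions (closed form)
#'
#' For Gaussians the overlap integral is available in closed form:
#' \deqn{1 - H^2 = \sqrt{\frac{2\sigma_a\sigma_b}{\sigma_a^2+\sigma_b^2}}
#'   \exp\!\left(-\frac{(\mu_a-\mu_b)^2}{4(\sigma_a^2+\sigma_b^2)}\right).}
#'
#' @param a,b [gaussian_params()] objects.
#' @return a scalar in `[0, 1]`.
#' @examples
#' hellinger_gaussian(gaussian_params(0, 1), gaussian_params(1, 1))
#' @export
hellinger_gaussian <- function(a, b) {
  stopifnot(inherits(a, "gaussian_params"), inherits(b, "gaussian_params"))
  s2 <- a$sigma^2 + b$sigma^2
  bc <- sqrt(2 * a$sigma * b$sigma / s2) * exp(-(a$mu - b$mu)^2 / (4 * s2))
  sqrt(max(0, 1 - bc))
}

#' Total-variation distance between two opinions
#'
#' \deqn{d_{TV}(p,q) = \tfrac12 \int |p(x) - q(x)|\, dx \in [0, 1],} the
#' L1-norm distance, computed on mass-1 rescalings.  It equals the maximal
#' difference the two opinions can assign to any event, and admits the
#' usual optimal-coupling characterization.
#'
#' @inheritParams hellinger
#' @return a scalar in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  pr <- metric_pair(p, q)
  v <- abs(pr$p - pr$q)
  0.5 * if (is.na(pr$dx)) sum(v) else trapz(v, pr$dx)
}

#' f-divergence between two opinions
#'
#' \deqn{D_f(p \| q) = \sum_k q_k f(p_k / q_k)} on mass-1 rescalings, for a
#' convex `f`.  `D_f` is minimized at `p = q` with value `f(1)`.  These
#' divergences serve as Lyapunov functions of repeated persuasion: along a
#' trajectory converging to the persuader they never increase.
#'
#' Conventions: terms with `q_k = 0, p_k = 0` contribute `0`; if `p_k > 0`
#' where `q_k = 0` the divergence is `+Inf`, returned with attribute
#' `flag = "support_mismatch"` rather than raising an error.  Convexity of
#' `f` is the caller's contract; it is not checked.
#'
#' @inheritParams hellinger
#' @param f a scalar-vectorized convex function.  Ready-made choices:
#'   [f_hellinger()], [f_total_variation()], [f_kl()].
#' @return a scalar (possibly `Inf`).
#' @examples
#' p <- c(0.2, 0.8); q <- c(0.5, 0.5)
#' f_divergence(p, q, f_total_variation) == total_variation(p, q)
#' @export
f_divergence <- function(p, q, f) {
  pr <- metric_pair(p, q)
  pv <- pr$p; qv <- pr$q
  if (!is.na(pr$dx)) { pv <- pv * pr$dx; qv <- qv * pr$dx }  # cell masses
  if (any(pv > 0 & qv == 0))
    return(structure(Inf, flag = "support_mismatch"))
  pos <- qv > 0
  sum(qv[pos] * f(pv[pos] / qv[pos]))
}

#' Divergence generators
#'
#' Convex generators for [f_divergence()]:
#' * `f_hellinger(y) = (sqrt(y) - 1)^2`, giving twice the squared Hellinger
#'   distance;
#' * `f_total_variation(y) = |y - 1| / 2`, giving the total variation;
#' * `f_kl(y) = y log y` (with `0 log 0 = 0`), giving the Kullback-Leibler
#'   divergence.
#'
#' @param y numeric vector of likelihood ratios.
#' @return numeric vector.
#' @name divergence_generators
NULL

#' @rdname divergence_generators
#' @export
f_hellinger <- function(y) (sqrt(y) - 1)^2

#' @rdname divergence_generators
#' @export
f_total_variation <- function(y) abs(y - 1) / 2

#' @rdname divergence_generators
#' @export
f_kl <- function(y) ifelse(y == 0, 0, y * log(y))

#' Distance report between two opinions
#'
#' @inheritParams hellinger
#' @return an object of class `distance_report`: list with `hellinger`,
#'   `total_variation` and `bhattacharyya_overlap`, all in `[0, 1]`.
#' @export
distance_report <- function(p, q) {
  structure(list(hellinger = hellinger(p, q),
                 total_variation = total_variation(p, q),
                 bhattacharyya_overlap = bhattacharyya(p, q)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf(paste0("Hellinger: %.6f  total variation: %.6f  ",
                     "Bhattacharyya overlap: %.6f\n"),
              x$hellinger, x$total_variation, x$bhattacharyya_overlap))
  invisible(x)
}
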
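# revision params matching the regime of a bare epsilon
auto_params <- function(epsilon) {
  revision_params(epsilon,
                  variant = if (epsilon > 1) "boomerang"
                            else "average_then_project")
}

# Unnormalized log density of the revised opinion for Gaussian p and q,
# evaluable at arbitrary x (no grid).  Used for sub-grid anchor location.
gaussian_revised_logdensity <- function(x, p, q, epsilon) {
  pv <- stats::dnorm(x, p$mu, p$sigma)
  qv <- stats::dnorm(x, q$mu, q$sigma)
  pi <- epsilon * pv + (1 - epsilon) * qv
  if (epsilon <= 1) {
    epsilon * log(pv) + (1 - epsilon) * log(pi)
  } else {
    out <- (2 - epsilon) * log(pv) + (epsilon - 1) * log(abs(pi))
    out[pi == 0] <- -Inf
    out
  }
}

# All local maxima of the revised Gaussian pair, refined by optimize();
# returns data.frame(location, height_log) sorted by height descending.
gaussian_revised_anchors <- function(p, q, epsilon, n_scan = 4001L) {
  lo <- min(p$mu - 6 * p$sigma, q$mu - 6 * q$sigma)
  hi <- max(p$mu + 6 * p$sigma, q$mu + 6 * q$sigma)
  x <- seq(lo, hi, length.out = n_scan)
  y <- gaussian_revised_logdensity(x, p, q, epsilon)
  y[!is.finite(y)] <- -Inf
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[is.finite(y[i])]
  if (!length(i)) i <- which.max(y)
  dx <- x[2L] - x[1L]
  ref <- vapply(i, function(j) {
    opt <- stats::optimize(function(z)
      gaussian_revised_logdensity(z, p, q, epsilon),
      lower = max(lo, x[j] - 2 * dx), upper = min(hi, x[j] + 2 * dx),
      maximum = TRUE, tol = 1e-12)
    c(opt$maximum, opt$objective)
  }, numeric(2))
  out <- data.frame(location = ref[1, ], height_log = ref[2, ])
  out[order(out$height_log, decreasing = TRUE), , drop = FALSE]
}

#' Weighted-average prediction of the revised anchor and dispersion
#'
#' In the small-discrepancy limit the revision rule reduces to the
#' weighted-average model of opinion change: the revised anchor is a
#' weighted mean of the two anchors,
#' `x* = w_self * mu_p + w_other * mu_q`, with weights obtained by
#' expanding the revised log density around the prior anchor.  The same
#' expansion at equal anchors yields the first-order change in dispersion.
#' `w_other` grows with the persuader's confidence (small `sigma_q`),
#' shrinks with the agent's own confidence, vanishes at `epsilon = 1`, and
#' becomes *negative* in the boomerang regime (`epsilon > 1`) -- the anchor
#' then drifts away from the persuader and the equal-anchor dispersion
#' inequality reverses.
#'
#' @param p,q [gaussian_params()] for the agent and the persuader.
#' @param epsilon revision weight (any nonnegative value; `> 1` switches
#'   to the boomerang continuation).
#' @return list with `predicted_anchor`, `weight_self`, `weight_other`
#'   (summing to 1) and `predicted_dispersion_ratio` (the ratio of the
#'   revised to the prior dispersion at equal anchors; `NA` if the
#'   expansion predicts peak splitting instead of a single peak).
#' @examples
#' weighted_average_prediction(gaussian_params(0, 1),
#'                             gaussian_params(0.1, 1), 0.5)
#' @export
weighted_average_prediction <- function(p, q, epsilon) {
  stopifnot(inherits(p, "gaussian_params"), inherits(q, "gaussian_params"))
  sp <- p$sigma; sq <- q$sigma; eps <- epsilon
  if (eps <= 1) { ep <- eps; epi <- 1 - eps } else { ep <- 2 - eps; epi <- eps - 1 }
  denom0 <- eps * sq + (1 - eps) * sp     # pooled density at the anchor, xs
  if (denom0 <= 0)                        # pooled measure vanishes at anchor
    return(list(predicted_anchor = NA_real_, weight_self = NA_real_,
                weight_other = NA_real_,
                predicted_dispersion_ratio = NA_real_))
  a <- eps * sq / denom0                  # share of p in the pool at the anchor
  A <- (ep + epi * a) / sp^2
  B <- epi * (1 - a) / sq^2
  w_other <- B / (A + B)
  inv_s2 <- ep / sp^2 + epi * (a / sp^2 + (1 - a) / sq^2)
  list(predicted_anchor = p$mu + w_other * (q$mu - p$mu),
       weight_self = 1 - w_other,
       weight_other = w_other,
       predicted_dispersion_ratio =
         if (inv_s2 > 0) 1 / (sp * sqrt(inv_s2)) else NA_real_)
}

#' Local maxima (anchors) of a grid opinion
#'
#' Finds the strict interior local maxima of the density, collapses
#' plateaus to their midpoint, refines each peak by local quadratic
#' interpolation for sub-grid resolution, and keeps peaks whose height is
#' at least `min_height_frac` of the global maximum.
#'
#' @param op a [grid_opinion()].
#' @param min_height_frac minimum height, as a fraction of the tallest
#'   peak, for an anchor to be reported.
#' @return an object of class `anchor_set`: list with `anchors` (a
#'   data.frame of `location` and `height`, sorted by height descending)
#'   and `dominant` (the first row as a list).
#' @examples
#' g <- opinion_grid(-10, 10, 1001)
#' p <- gaussian_opinion(gaussian_params(1.5, 1), g)
#' find_anchors(p)$dominant$location   # ~ 1.5
#' @export
find_anchors <- function(op, min_height_frac = 0.05) {
  stopifnot(inherits(op, "grid_opinion"))
  y <- op$density; x <- op$grid$x; dx <- op$grid$dx
  n <- length(y)
  s <- sign(diff(y))
  nz <- which(s != 0)
  locs <- numeric(0); hts <- numeric(0)
  if (length(nz) >= 2L) {
    for (j in seq_len(length(nz) - 1L)) {
      if (s[nz[j]] == 1 && s[nz[j + 1L]] == -1) {
        i1 <- nz[j] + 1L          # first index of the (possibly flat) top
        i2 <- nz[j + 1L]          # last index of the top
        if (i2 > i1) {            # plateau: collapse to midpoint
          locs <- c(locs, (x[i1] + x[i2]) / 2)
          hts <- c(hts, y[i1])
        } else {
          i <- i1
          d2 <- y[i - 1L] - 2 * y[i] + y[i + 1L]
          if (d2 < 0) {           # quadratic vertex refinement
            off <- 0.5 * (y[i - 1L] - y[i + 1L]) / d2
            locs <- c(locs, x[i] + off * dx)
            hts <- c(hts, y[i] - (y[i - 1L] - y[i + 1L])^2 / (8 * d2))
          } else {
            locs <- c(locs, x[i]); hts <- c(hts, y[i])
          }
        }
      }
    }
  }
  if (!length(locs)) {            # monotone density: fall back to the mode
    i <- which.max(y)
    locs <- x[i]; hts <- y[i]
  }
  keep <- hts >= min_height_frac * max(hts)
  ord <- order(hts[keep], decreasing = TRUE)
  anchors <- data.frame(location = locs[keep][ord], height = hts[keep][ord])
  structure(list(anchors = anchors,
                 dominant = as.list(anchors[1, ])),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set: %d peak(s); dominant at x = %.4g (height %.4g)\n",
              nrow(x$anchors), x$dominant$location, x$dominant$height))
  invisible(x)
}

#' Opinion change versus discrepancy sweep
#'
#' Sweeps the anchor discrepancy `m`: the agent holds a Gaussian opinion
#' centred at 0 and is persuaded by a Gaussian centred at `m`, and for
#' each `m` the sweep records the opinion change (Hellinger and total
#' variation between prior and revised opinion) and the shift of the
#' dominant anchor.  For mid-range `epsilon` the change is an inverted-U
#' of `m` whose maximum `m_star` falls in the prior's latitude of
#' non-commitment; for small `epsilon` the anchor shift collapses abruptly
#' at a critical `m` (detected when one secant step exceeds five times the
#' preceding one).
#'
#' @param sigma_p,sigma_q dispersions of the two opinions.
#' @param epsilon revision weight.
#' @param m_grid strictly increasing grid of anchor discrepancies
#'   (at least 10 points).
#' @param n_points grid resolution for the density computations.
#' @param jump_floor minimum absolute anchor drop (in units of `sigma_p`)
#'   for the jump detector, guarding against noise-level firing.
#' @return an object of class `sweep_result`: list with `table`
#'   (data.frame of `m`, `h`, `h_tv`, `anchor_shift`), `m_star`,
#'   `anchor_jump` (logical flag) and `jump_m` (location, or `NA`).
#' @export
discrepancy_sweep <- function(sigma_p, sigma_q, epsilon, m_grid,
                              n_points = 2001L, jump_floor = 0.05) {
  m_grid <- as.numeric(m_grid)
  if (length(m_grid) < 10L || any(diff(m_grid) <= 0))
    stop("'m_grid' must be a strictly increasing grid of >= 10 points")
  params <- auto_params(epsilon)
  g <- opinion_grid(-6 * sigma_p,
                    max(m_grid) + 6 * max(sigma_p, sigma_q), n_points)
  p <- gaussian_opinion(gaussian_params(0, sigma_p), g)
  rows <- lapply(m_grid, function(m) {
    q <- gaussian_opinion(gaussian_params(m, sigma_q), g)
    pt <- revise_density(p, q, params)
    data.frame(m = m, h = hellinger(p, pt), h_tv = total_variation(p, pt),
               anchor_shift = find_anchors(pt)$dominant$location)
  })
  tab <- do.call(rbind, rows)
  dA <- diff(tab$anchor_shift)
  jump <- FALSE; jump_m <- NA_real_
  for (i in seq_along(dA)[-1L]) {
    if (abs(dA[i]) > 5 * abs(dA[i - 1L]) &&
        abs(dA[i]) > jump_floor * sigma_p) {
      jump <- TRUE; jump_m <- tab$m[i + 1L]; break
    }
  }
  structure(list(table = tab, m_star = tab$m[which.max(tab$h)],
                 m_star_tv = tab$m[which.max(tab$h_tv)],
                 anchor_jump = jump, jump_m = jump_m),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Change-discrepancy sweep: m* = %g (TV: %g); anchor jump: %s\n",
              x$m_star, x$m_star_tv,
              if (x$anchor_jump) sprintf("yes, near m = %g", x$jump_m)
              else "no"))
  invisible(x)
}

#' Monotone change-discrepancy scenario (equal anchors)
#'
#' With coinciding anchors the discrepancy between the two opinions is
#' driven by the persuader's dispersion alone, and the opinion change is a
#' monotone function of it: larger discrepancy, larger change.
#'
#' @param sigma_p the agent's dispersion.
#' @param epsilon revision weight in `(0, 1)`.
#' @param sigma_q_grid dispersions of the persuader to scan.
#' @param n_points grid resolution.
#' @return data.frame with columns `sigma_q`, `discrepancy`
#'   (Hellinger between the two opinions), `h`, `h_tv`, sorted by
#'   increasing discrepancy, with attributes `monotone_h` and
#'   `monotone_tv`.
#' @export
monotone_discrepancy_check <- function(sigma_p, epsilon, sigma_q_grid,
                                       n_points = 2001L) {
  params <- auto_params(epsilon)
  smax <- max(sigma_p, sigma_q_grid)
  g <- opinion_grid(-8 * smax, 8 * smax, n_points)
  p <- gaussian_opinion(gaussian_params(0, sigma_p), g)
  tab <- do.call(rbind, lapply(sigma_q_grid, function(sq) {
    q <- gaussian_opinion(gaussian_params(0, sq), g)
    pt <- revise_density(p, q, params)
    data.frame(sigma_q = sq,
               discrepancy = hellinger_gaussian(gaussian_params(0, sigma_p),
                                                gaussian_params(0, sq)),
               h = hellinger(p, pt), h_tv = total_variation(p, pt))
  }))
  tab <- tab[order(tab$discrepancy), ]
  attr(tab, "monotone_h") <- all(diff(tab$h) > -1e-12)
  attr(tab, "monotone_tv") <- all(diff(tab$h_tv) > -1e-12)
  tab
}

# symmetric-setup validation helpers
check_symmetric_gaussian <- function(p, q, qp) {
  if (abs((q$mu - p$mu) + (qp$mu - p$mu)) > 1e-9 ||
      abs(q$sigma - qp$sigma) > 1e-9)
    stop("order experiment requires persuaders symmetric about the agent's ",
         "anchor with equal dispersions")
}
check_symmetric_discrete <- function(p, q, qp) {
  if (max(abs(rev(p$weights) - p$weights)) > 1e-9 * p$total_mass ||
      max(abs(rev(q$weights) - qp$weights)) > 1e-9 * q$total_mass)
    stop("order experiment requires a palindromic prior and mirror-image ",
         "persuaders (q' must be the reversal of q)")
}

#' Order-of-presentation experiment
#'
#' The agent meets two persuaders holding opinions symmetric with respect
#' to his own, in both orders, with the same `epsilon` for every
#' interaction.  The verdict is `"recency"` when the final opinion is
#' closer (in Hellinger distance) to the *last* persuader, `"primacy"`
#' when closer to the first, and `"tie"` within `1e-12`.  For
#' `0 < epsilon < 1` the rule predicts recency unconditionally; primacy
#' appears only deep in the boomerang regime (see [primacy_crossover()]).
#'
#' @param p the agent's opinion: [gaussian_params()] or
#'   [discrete_opinion()].
#' @param q,q_prime the two persuading opinions, of the same kind as `p`
#'   and symmetric with respect to it (equal dispersions and mirrored
#'   anchors for Gaussians; reversal-symmetric weight vectors for discrete
#'   opinions, with a palindromic `p`).
#' @param epsilon shared revision weight.
#' @param n_points grid resolution for the Gaussian case.
#' @return an object of class `order_result`: list with `final_forward`
#'   (order `q` then `q_prime`), `final_reverse`, `d_to_first`,
#'   `d_to_last` (distances of the forward run's final opinion to `q` and
#'   `q_prime`) and `verdict`.
#' @examples
#' r <- order_experiment(discrete_opinion(c(.5, .5)),
#'                       discrete_opinion(c(1, 0)),
#'                       discrete_opinion(c(0, 1)), 0.5)
#' r$verdict   # "recency"
#' @export
order_experiment <- function(p, q, q_prime, epsilon, n_points = 2001L) {
  params <- auto_params(epsilon)
  if (inherits(p, "gaussian_params")) {
    check_symmetric_gaussian(p, q, q_prime)
    smax <- max(p$sigma, q$sigma)
    span <- max(abs(q$mu - p$mu), abs(q_prime$mu - p$mu)) + 6 * smax
    g <- opinion_grid(p$mu - span, p$mu + span, n_points)
    pg <- gaussian_opinion(p, g)
    qg <- gaussian_opinion(q, g)
    qpg <- gaussian_opinion(q_prime, g)
    fwd <- revise_density(revise_density(pg, qg, params), qpg, params)
    rvs <- revise_density(revise_density(pg, qpg, params), qg, params)
    d_first <- hellinger(fwd, qg); d_last <- hellinger(fwd, qpg)
  } else {
    p <- as_discrete_opinion(p)
    q <- as_discrete_opinion(q); q_prime <- as_discrete_opinion(q_prime)
    check_symmetric_discrete(p, q, q_prime)
    fwd <- revise_sequence(p, list(q, q_prime), params)
    rvs <- revise_sequence(p, list(q_prime, q), params)
    d_first <- hellinger(fwd, q); d_last <- hellinger(fwd, q_prime)
  }
  verdict <- if (abs(d_last - d_first) <= 1e-12) "tie"
             else if (d_last < d_first) "recency" else "primacy"
  structure(list(final_forward = fwd, final_reverse = rvs,
                 d_to_first = d_first, d_to_last = d_last,
                 verdict = verdict, epsilon = epsilon),
            class = "order_result")
}

#' @export
print.order_result <- function(x, ...) {
  cat(sprintf(paste0("Order experiment (epsilon = %g): distance to first ",
                     "%.6f, to last %.6f -> %s\n"),
              x$epsilon, x$d_to_first, x$d_to_last, x$verdict))
  invisible(x)
}

#' Locate the recency-to-primacy crossover in the boomerang regime
#'
#' On the binary ignorant-agent setup (uniform prior, two opposed certain
#' persuaders) the verdict is recency for every `epsilon` in `(0, 1)` and
#' remains recency just above 1, but flips to primacy for `epsilon`
#' sufficiently deep in the boomerang regime.  This deterministically
#' scans `epsilon` and then bisects the last sign change of
#' `d_to_last - d_to_first`.
#'
#' @param lower,upper scan range (both `> 1`).
#' @param coarse coarse scan step.
#' @param tol bisection tolerance on `epsilon`.
#' @return list with `epsilon_star` and the scan `table`.
#' @export
primacy_crossover <- function(lower = 1.05, upper = 3, coarse = 0.05,
                              tol = 1e-10) {
  p <- discrete_opinion(c(0.5, 0.5))
  q <- discrete_opinion(c(1, 0)); qp <- discrete_opinion(c(0, 1))
  gap <- function(eps)
    with(order_experiment(p, q, qp, eps), d_to_last - d_to_first)
  eps_grid <- seq(lower, upper, by = coarse)
  gvals <- vapply(eps_grid, gap, numeric(1))
  flips <- which(gvals[-length(gvals)] < 0 & gvals[-1L] >= 0)
  if (!length(flips))
    return(list(epsilon_star = NA_real_,
                table = data.frame(epsilon = eps_grid, gap = gvals)))
  i <- flips[length(flips)]
  lo <- eps_grid[i]; hi <- eps_grid[i + 1L]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) < 0) lo <- mid else hi <- mid
  }
  list(epsilon_star = (lo + hi) / 2,
       table = data.frame(epsilon = eps_grid, gap = gvals))
}

#' Cognitive-dissonance scenario
#'
#' Revises a broad Gaussian opinion by a narrow, moderately displaced and
#' sufficiently credible one, and classifies the outcome by its anchor
#' structure: `"single-peak"` (no splitting), `"dissonant"` (two peaks of
#' comparable height, the signature of believing two conflicting things at
#' once), `"dominated-new"` (the persuader-induced peak dominates) or
#' `"dominated-old"`.  Raising `epsilon` suppresses the new peak, lowering
#' it makes the new peak dominant, and narrowing the prior prevents
#' splitting -- the three classic routes for dissonance reduction.
#'
#' @param p,q [gaussian_params()] for the agent and the persuader.
#' @param epsilon revision weight.
#' @param comparability two peaks count as "comparable" when their height
#'   ratio is within this factor (default 3).
#' @param n_points grid resolution.
#' @param min_height_frac detection floor for secondary peaks, as a
#'   fraction of the dominant height.
#' @return list with `anchors` (an `anchor_set`), `classification`, and
#'   the revised opinion `revised`.
#' @examples
#' dissonance_scenario(gaussian_params(0, 2), gaussian_params(2, 0.3), 0.5)
#' @export
dissonance_scenario <- function(p, q, epsilon, comparability = 3,
                                n_points = 2001L, min_height_frac = 1e-4) {
  stopifnot(inherits(p, "gaussian_params"), inherits(q, "gaussian_params"))
  params <- auto_params(epsilon)
  smax <- max(p$sigma, q$sigma)
  g <- opinion_grid(min(p$mu, q$mu) - 6 * smax,
                    max(p$mu, q$mu) + 6 * smax, n_points)
  pt <- revise_density(gaussian_opinion(p, g), gaussian_opinion(q, g), params)
  an <- find_anchors(pt, min_height_frac = min_height_frac)
  cls <- if (nrow(an$anchors) < 2L) {
    "single-peak"
  } else {
    top <- an$anchors[1:2, ]
    ratio <- top$height[2] / top$height[1]
    if (ratio >= 1 / comparability) "dissonant"
    else if (abs(top$location[1] - q$mu) < abs(top$location[1] - p$mu))
      "dominated-new"
    else "dominated-old"
  }
  list(anchors = an, classification = cls, revised = pt)
}

#' Revision under a fully certain persuader
#'
#' The persuader concentrates all mass on a single event `l`.  Every other
#' event keeps a weight proportional to its prior, while event `l` gets
#' `p_l^eps (eps p_l + (1 - eps))^(1 - eps) / eps^(1 - eps)` (on mass-1
#' scale) -- so even an event on the tail of the agent's opinion can be
#' promoted to a local or global maximum, provided `epsilon` is not close
#' to 1.  If the agent rules the event out entirely (`p_l = 0`) the
#' opinion does not change.
#'
#' @param p the agent's [discrete_opinion()].
#' @param l index of the event the persuader is certain about.
#' @param epsilon revision weight in `(0, 1)`.
#' @return the revised [discrete_opinion()].
#' @examples
#' p <- discrete_opinion(rep(0.25, 4))
#' certain_persuader_revision(p, 2, 0.5)
#' @export
certain_persuader_revision <- function(p, l, epsilon) {
  p <- as_discrete_opinion(p)
  l <- as.integer(l)
  if (l < 1L || l > length(p$weights)) stop("'l' is out of range")
  if (epsilon <= 0 || epsilon >= 1) stop("'epsilon' must lie in (0, 1)")
  qw <- numeric(length(p$weights)); qw[l] <- p$total_mass
  revise(p, discrete_opinion(qw, total_mass = p$total_mass),
         revision_params(epsilon))
}

# curvature-based dispersion of a peak at refined location x0
peak_width <- function(op, x0) {
  x <- op$grid$x; dx <- op$grid$dx
  i <- which.min(abs(x - x0))
  i <- min(max(i, 2L), length(x) - 1L)
  ly <- log(pmax(op$density, 1e-300))
  d2 <- (ly[i - 1L] - 2 * ly[i] + ly[i + 1L]) / dx^2
  if (d2 >= 0) return(NA_real_)
  1 / sqrt(-d2)
}

#' Boomerang revision report
#'
#' Applies a single boomerang revision (`epsilon > 1`) to a Gaussian pair
#' and reports its signature features: the dominant anchor displaces
#' *away* from the persuader's anchor and its peak is enhanced and
#' narrowed; mass in the overlap region where the agent already trails the
#' persuader is suppressed; and the revised density develops a near-zero
#' local minimum at the zero crossing `x0` of the pooled signed measure.
#'
#' @param p,q [gaussian_params()] for the agent and persuader.
#' @param epsilon scalar `> 1`.
#' @param n_points grid resolution.
#' @return list with `revised`, `anchors`, `anchor_shift`, `moves_away`,
#'   `peak_enhanced` (dominant height vs the prior's mode height),
#'   `dominant_width`, `width_ratio` (vs `sigma_p`), `x0` (zero crossings
#'   of the pooled measure), `min_over_peak` (deepest local minimum between
#'   the peaks relative to the dominant height) and `peak_count`.
#' @examples
#' boomerang_revision_report(gaussian_params(0, 1),
#'                           gaussian_params(1.5, 1), 1.5)$moves_away
#' @export
boomerang_revision_report <- function(p, q, epsilon, n_points = 2001L) {
  stopifnot(inherits(p, "gaussian_params"), inherits(q, "gaussian_params"))
  if (epsilon <= 1) stop("the boomerang report requires epsilon > 1")
  params <- revision_params(epsilon, variant = "boomerang")
  smax <- max(p$sigma, q$sigma)
  g <- opinion_grid(min(p$mu, q$mu) - 8 * smax,
                    max(p$mu, q$mu) + 8 * smax, n_points)
  pg <- gaussian_opinion(p, g); qg <- gaussian_opinion(q, g)
  pt <- revise_density(pg, qg, params)
  an <- find_anchors(pt, min_height_frac = 0.01)
  shift <- an$dominant$location - p$mu
  sep <- q$mu - p$mu
  pooled <- epsilon * pg$density + (1 - epsilon) * qg$density
  cross <- which(diff(sign(pooled)) != 0)
  x0 <- if (length(cross)) g$x[cross] + g$dx *
    pooled[cross] / (pooled[cross] - pooled[cross + 1L]) else numeric(0)
  min_over_peak <- if (length(x0)) {
    vmin <- min(vapply(x0, function(z)
      pt$density[which.min(abs(g$x - z))], numeric(1)))
    vmin / an$dominant$height
  } else NA_real_
  list(revised = pt, anchors = an, anchor_shift = shift,
       moves_away = if (sep == 0) shift == 0 else sign(shift) == -sign(sep),
       peak_enhanced = an$dominant$height > max(pg$density),
       dominant_width = peak_width(pt, an$dominant$location),
       width_ratio = peak_width(pt, an$dominant$location) / p$sigma,
       x0 = x0, min_over_peak = min_over_peak,
       peak_count = nrow(an$anchors))
}
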
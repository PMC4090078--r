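#' Repeated persuasion by a fixed opinion
#'
#' Iterates the revision rule with the same persuader: `p_{t+1} =
#' revise(p_t, q, params)`.  For `0 < epsilon < 1` and a persuader with
#' strictly positive weights the persuader's opinion `q` is the unique,
#' globally stable fixed point: the Hellinger distance to `q` decays
#' monotonically, and every f-divergence to `q` is a Lyapunov function
#' (see [diagnostics()]).  Convergence slows as `epsilon` grows.
#'
#' @param p0 initial opinion ([discrete_opinion()] or [grid_opinion()]).
#' @param q persuading opinion of the same kind (and grid/total mass).
#' @param params a [revision_params()] object; `epsilon` in `(0, 1)` for
#'   the convergence guarantee.
#' @param max_steps iteration cap.
#' @param tol convergence tolerance: iteration stops once
#'   `hellinger(p_t, q) < tol`.
#' @return an object of class `persuasion_trajectory`: list with
#'   `opinions` (list, `t = 0 .. T`), `params`, `persuader`,
#'   `hellinger_to_q`, `tv_to_q`, `converged`, `iterations_to_tol`.
#' @examples
#' tr <- iterate(discrete_opinion(c(0.9, 0.1)), discrete_opinion(c(0.5, 0.5)),
#'               revision_params(0.5), tol = 1e-10)
#' tr$converged
#' @export
iterate <- function(p0, q, params, max_steps = 10000L, tol = 1e-8) {
  stopifnot(inherits(params, "revision_params"))
  grid_mode <- inherits(p0, "grid_opinion")
  step <- if (grid_mode) revise_density else revise
  opinions <- vector("list", 1L)
  opinions[[1L]] <- p0
  h <- hellinger(p0, q); tv <- total_variation(p0, q)
  converged <- h < tol
  iterations <- if (converged) 0L else NA_integer_
  p <- p0
  t <- 0L
  while (!converged && t < max_steps) {
    p <- step(p, q, params)
    t <- t + 1L
    opinions[[t + 1L]] <- p
    h <- c(h, hellinger(p, q))
    tv <- c(tv, total_variation(p, q))
    if (h[t + 1L] < tol) {
      converged <- TRUE
      iterations <- t
    }
  }
  structure(list(opinions = opinions, params = params, persuader = q,
                 hellinger_to_q = h, tv_to_q = tv,
                 converged = converged, iterations_to_tol = iterations),
            class = "persuasion_trajectory")
}

#' @export
print.persuasion_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Persuasion trajectory: %d steps, epsilon = %g (%s), ",
                     "%sconverged\n"),
              length(x$opinions) - 1L, x$params$epsilon, x$params$variant,
              if (x$converged) "" else "not "))
  cat(sprintf("final Hellinger distance to persuader: %.3g\n",
              x$hellinger_to_q[length(x$hellinger_to_q)]))
  invisible(x)
}

traj_weights <- function(op) {
  if (inherits(op, "discrete_opinion")) op$weights / op$total_mass
  else op$density * op$grid$dx        # cell masses
}

#' Convergence diagnostics for a persuasion trajectory
#'
#' Computes, along a trajectory from [iterate()]:
#' * the Lyapunov series `L_t = D_f(p_t || q)` for each supplied convex
#'   generator (non-increasing whenever `epsilon` is in `(0, 1)` and the
#'   persuader has full support, with equality only at the fixed point);
#' * Hellinger and total-variation distances between consecutive opinions
#'   (the per-step opinion change -- its largest entry need *not* be the
#'   first step, i.e. the law of diminishing returns can fail);
#' * the number of Le Chatelier violations.  The principle is stated in
#'   normalization-free form: at every step, each event the agent currently
#'   overestimates (`p_k > q_k`) must grow by a strictly smaller factor
#'   than each event he underestimates.  (Before renormalization,
#'   overestimated weights always contract and underestimated ones always
#'   expand -- the pooled-projected sum never exceeds the total mass -- but
#'   the common renormalization factor is `>= 1`, so a barely-overestimated
#'   event can transiently gain absolute mass while a grossly overestimated
#'   one sheds it; the growth-factor ordering is the invariant content.)
#'
#' @param traj a `persuasion_trajectory` with at least two opinions.
#' @param f_choices named list of convex generators, by default the
#'   Hellinger-, total-variation- and KL-inducing choices.
#' @param mono_tol tolerance absorbing floating-point noise in the
#'   monotonicity counts.
#' @return an object of class `trajectory_diagnostics`: list with
#'   `lyapunov_series` (matrix, one column per generator), `step_hellinger`,
#'   `step_tv`, `largest_change_step`, `le_chatelier_violations`,
#'   `converged`, `iterations_to_tol`.
#' @export
diagnostics <- function(traj,
                        f_choices = list(hellinger = f_hellinger,
                                         total_variation = f_total_variation,
                                         kl = f_kl),
                        mono_tol = 1e-12) {
  stopifnot(inherits(traj, "persuasion_trajectory"))
  n <- length(traj$opinions)
  if (n < 2L) stop("trajectory must contain at least two opinions")
  q <- traj$persuader
  lyap <- vapply(f_choices, function(f)
    vapply(traj$opinions, function(p) f_divergence(p, q, f), numeric(1)),
    numeric(n))
  step_h <- vapply(seq_len(n - 1L), function(t)
    hellinger(traj$opinions[[t]], traj$opinions[[t + 1L]]), numeric(1))
  step_tv <- vapply(seq_len(n - 1L), function(t)
    total_variation(traj$opinions[[t]], traj$opinions[[t + 1L]]), numeric(1))
  qv <- traj_weights(q)
  viol <- 0L
  for (t in seq_len(n - 1L)) {
    a <- traj_weights(traj$opinions[[t]])
    b <- traj_weights(traj$opinions[[t + 1L]])
    growth <- ifelse(a > 0, b / a, NA_real_)
    over <- which(a > qv + mono_tol & a > 0)
    under <- which(a < qv - mono_tol & a > 0)
    if (length(over) && length(under) &&
        max(growth[over]) >= min(growth[under]) - mono_tol)
      viol <- viol + 1L
  }
  structure(list(lyapunov_series = lyap,
                 step_hellinger = step_h, step_tv = step_tv,
                 largest_change_step = which.max(step_h),
                 le_chatelier_violations = viol,
                 converged = traj$converged,
                 iterations_to_tol = traj$iterations_to_tol),
            class = "trajectory_diagnostics")
}

#' @export
print.trajectory_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("Trajectory diagnostics: largest step change at t = %d, ",
                     "%d Le Chatelier violations\n"),
              x$largest_change_step, x$le_chatelier_violations))
  invisible(x)
}

#' Repeated persuasion in the boomerang regime
#'
#' Iterates the boomerang rule (`epsilon > 1`) with a fixed Gaussian-like
#' persuader.  Unlike the normal regime the trajectory does not approach
#' `q`; instead the opinion typically splits: a smaller peak detaches and
#' migrates towards the persuader's anchor while the dominant peak narrows
#' and drifts away, until the opinion stops changing.  Stationarity is
#' therefore measured between consecutive opinions, not against `q`.
#'
#' @param p0,q [grid_opinion()] objects on the same grid.
#' @param epsilon scalar `> 1`.
#' @param max_steps iteration cap.
#' @param tol stationarity tolerance on the consecutive-step Hellinger
#'   distance (default `1e-4`; the late-time decay is slow, so demanding
#'   much more buys nothing qualitative).
#' @param track_anchors if `TRUE`, record the anchor set of every 10th
#'   opinion (see [find_anchors()]).
#' @return a `persuasion_trajectory` with extra fields `step_hellinger`,
#'   `stationary` and (optionally) `anchor_track`.
#' @export
iterate_boomerang <- function(p0, q, epsilon, max_steps = 10000L, tol = 1e-4,
                              track_anchors = TRUE) {
  stopifnot(inherits(p0, "grid_opinion"), inherits(q, "grid_opinion"))
  params <- revision_params(epsilon, variant = "boomerang")
  opinions <- list(p0)
  step_h <- numeric(0)
  track <- list()
  p <- p0
  t <- 0L
  stationary <- FALSE
  while (t < max_steps) {
    pn <- revise_density(p, q, params)
    t <- t + 1L
    step_h[t] <- hellinger(pn, p)
    p <- pn
    opinions[[t + 1L]] <- p
    if (track_anchors && t %% 10L == 0L) {
      an <- find_anchors(p, min_height_frac = 0.02)$anchors
      track[[length(track) + 1L]] <-
        data.frame(t = t, an[order(an$location), , drop = FALSE],
                   row.names = NULL)
    }
    if (step_h[t] < tol) { stationary <- TRUE; break }
  }
  structure(list(opinions = opinions, params = params, persuader = q,
                 hellinger_to_q = vapply(opinions, hellinger, numeric(1),
                                         q = q),
                 tv_to_q = vapply(opinions, total_variation, numeric(1),
                                  q = q),
                 step_hellinger = step_h, stationary = stationary,
                 anchor_track = track,
                 converged = stationary, iterations_to_tol =
                   if (stationary) t else NA_integer_),
            class = "persuasion_trajectory")
}

#' Deterministic witness against the law of diminishing returns
#'
#' Under repeated persuasion the opinion approaches the persuader
#' monotonically, yet the *largest* per-step change need not occur at the
#' first step.  This search scans a deterministic lattice on the simplex
#' (no randomness, so the witness is reproducible bit for bit) for an
#' initial opinion whose second revision step moves it further -- in
#' Hellinger distance -- than the first.
#'
#' @param K number of events (default 3).
#' @param epsilon revision weight (default 0.5).
#' @param q persuading opinion; defaults to the uniform opinion on `K`
#'   events.
#' @param lattice_step lattice spacing on the simplex.
#' @param n_steps how many persuasion steps to examine.
#' @return list with `p0`, `q`, `epsilon`, `step_hellinger` and
#'   `largest_change_step` (`>= 2` for a witness), or `NULL` if the scan
#'   finds none.
#' @examples
#' w <- diminishing_returns_witness()
#' w$largest_change_step   # 2: the second persuasion changes the most
#' @export
diminishing_returns_witness <- function(K = 3L, epsilon = 0.5, q = NULL,
                                        lattice_step = 0.002,
                                        n_steps = 4L) {
  if (is.null(q)) q <- discrete_opinion(rep(1 / K, K))
  params <- revision_params(epsilon)
  grid1 <- seq(1 - 2 * lattice_step, lattice_step, by = -lattice_step)
  for (p1 in grid1) {
    p2max <- 1 - p1 - lattice_step
    for (p2 in seq(lattice_step, p2max, by = lattice_step)) {
      rest <- 1 - p1 - p2
      p0 <- discrete_opinion(c(p1, p2, rest, rep(0, K - 3L))[seq_len(K)],
                             total_mass = 1)
      d <- numeric(n_steps)
      p <- p0
      for (t in seq_len(n_steps)) {
        pn <- revise(p, q, params)
        d[t] <- hellinger(pn, p)
        p <- pn
      }
      if (which.max(d) >= 2L)
        return(list(p0 = p0, q = q, epsilon = epsilon,
                    step_hellinger = d, largest_change_step = which.max(d)))
    }
  }
  NULL
}
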
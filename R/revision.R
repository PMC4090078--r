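# "x to the power e" with the convention 0^e = 0 for every e, so that events
# the agent rules out (weight exactly zero) stay ruled out under revision.
pow0 <- function(x, e) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos]^e
  out
}

#' Linear opinion pooling
#'
#' Combines two opinions linearly: entry `k` of the pool is
#' `epsilon * p_k + (1 - epsilon) * q_k`.  This is the first of the two
#' sub-processes of the revision rule; on its own it satisfies neither the
#' zero-preservation nor the no-overlap axiom, which is what the projection
#' step restores.  For `epsilon > 1` the pool is a signed measure (entries
#' may be negative).
#'
#' @param p,q [discrete_opinion()] objects with equal length and total mass.
#' @param params a [revision_params()] object.
#' @return a [signed_weights()] object.
#' @examples
#' p <- discrete_opinion(c(0.5, 0.5)); q <- discrete_opinion(c(1, 0))
#' pool_opinions(p, q, revision_params(0.5))$values   # 0.75 0.25
#' @export
pool_opinions <- function(p, q, params) {
  p <- as_discrete_opinion(p); q <- as_discrete_opinion(q)
  stopifnot(inherits(params, "revision_params"))
  check_compatible(p, q)
  eps <- params$epsilon
  signed_weights(eps * p$weights + (1 - eps) * q$weights,
                 total_mass = p$total_mass, epsilon = eps)
}

# Raw projection kernel on numeric vectors; pi may be signed when eps > 1.
# eps <= 1 : w_k = p_k^eps * pi_k^(1-eps)    (conservatism at eps = 1,
#                                             full acceptance at eps = 0)
# eps > 1  : w_k = p_k^(2-eps) * |pi_k|^(eps-1), the continuation through
#            the fixed point eps = 1; entries with pi_k = 0 get weight 0
#            (no flooring), as do entries with p_k = 0.
project_kernel <- function(pi, p, eps) {
  if (eps <= 1) {
    if (eps == 0) {
      w <- ifelse(p > 0, pmax(pi, 0), 0)
    } else {
      w <- pow0(p, eps) * pow0(pi, 1 - eps)
    }
  } else {
    w <- pow0(p, 2 - eps) * abs(pi)^(eps - 1)
    w[p <= 0 | pi == 0] <- 0
  }
  w
}

#' Projection of pooled weights onto the prior opinion
#'
#' The second sub-process of the revision rule ("trimming"): components of
#' the pooled opinion that deviate from the agent's existing opinion are
#' down-weighted.  The power-law form used here is the unique projection
#' that commutes with probabilistic conditioning.  Its limits pin down the
#' strength parameter: at `epsilon = 1` the result is proportional to the
#' prior `p` (conservatism); at `epsilon = 0` it is proportional to the
#' pooled weights themselves (full acceptance) wherever `p > 0`.  For
#' `epsilon > 1` the continuation takes absolute values of the signed pool,
#' which is what generates the boomerang phenomenology.
#'
#' @param pi a [signed_weights()] object (or plain numeric vector).
#' @param p the prior [discrete_opinion()] (or plain numeric vector).
#' @param epsilon projection strength, a nonnegative scalar.
#' @return numeric vector of unnormalized, nonnegative projected weights.
#' @export
project_pooled <- function(pi, p, epsilon) {
  piv <- if (inherits(pi, "signed_weights")) pi$values else as.numeric(pi)
  pv <- if (inherits(p, "discrete_opinion")) p$weights else as.numeric(p)
  if (length(piv) != length(pv))
    stop("pooled weights and prior opinion have different lengths")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("'epsilon' must be a nonnegative scalar")
  project_kernel(piv, pv, epsilon)
}

# Core revision on raw weight vectors; returns unnormalized weights.
# Degenerate outcomes (all-zero) are signalled by the caller.
revise_kernel <- function(p, q, eps, variant) {
  switch(variant,
    average_then_project = ,
    boomerang = {
      pi <- eps * p + (1 - eps) * q
      project_kernel(pi, p, eps)
    },
    project_then_average = {
      t <- project_kernel(q, p, eps)
      if (all(t == 0)) {
        # opinions with disjoint support: persuasion has no effect
        p
      } else {
        t <- t * (sum(p) / sum(t))
        eps * p + (1 - eps) * t
      }
    },
    stop("unknown variant: ", variant))
}

#' Confirmation-biased opinion revision
#'
#' Revises opinion `p` in the light of a persuading opinion `q`.  The
#' default rule pools the two opinions linearly with weight `epsilon` on the
#' prior, projects the pool back onto the prior with strength `epsilon`, and
#' renormalizes to the common total mass:
#' \deqn{\tilde p_k \propto p_k^{\varepsilon}\,
#'       (\varepsilon p_k + (1-\varepsilon) q_k)^{1-\varepsilon}.}
#' The rule satisfies, for `0 < epsilon <= 1`:
#' * zero preservation: `p_k = 0` implies `\tilde p_k = 0`;
#' * no-overlap invariance: disjoint supports leave `p` unchanged;
#' * identical-opinion invariance: `p = q` implies `\tilde p = p`;
#' * homogeneity of degree one in a joint rescaling of `p` and `q`.
#'
#' At `epsilon = 0` exactly the agent fully accepts `q` provided all of his
#' weights are positive; if any `p_k = 0` the limit is discontinuous and the
#' call raises a degenerate-revision error rather than guessing.  The
#' `"boomerang"` variant continues the rule to `epsilon > 1`
#' (\eqn{\tilde p_k \propto p_k^{2-\varepsilon}
#' |\varepsilon p_k + (1-\varepsilon) q_k|^{\varepsilon-1}}), under which
#' overlap events the agent already deems less likely than the persuader
#' does lose further mass.
#'
#' @param p the agent's prior opinion, a [discrete_opinion()].
#' @param q the persuading opinion, same length and total mass as `p`.
#' @param params a [revision_params()] object.
#' @return the revised [discrete_opinion()], renormalized to
#'   `p$total_mass`.
#' @examples
#' p <- discrete_opinion(c(0.5, 0.5))
#' q <- discrete_opinion(c(1, 0))
#' revise(p, q, revision_params(0.5))$weights    # sqrt(3)/(1+sqrt(3)), ...
#' @export
revise <- function(p, q, params) {
  p <- as_discrete_opinion(p); q <- as_discrete_opinion(q)
  stopifnot(inherits(params, "revision_params"))
  check_compatible(p, q)
  eps <- params$epsilon
  if (eps == 0 && params$variant != "project_then_average") {
    if (all(p$weights > 0))
      return(discrete_opinion(q$weights * (p$total_mass / q$total_mass),
                              total_mass = p$total_mass))
    stop("degenerate revision: at epsilon = 0 the rule is discontinuous ",
         "when some prior weights are zero")
  }
  w <- revise_kernel(p$weights, q$weights, eps, params$variant)
  s <- sum(w)
  if (s <= 0)
    stop("degenerate revision: all pooled-projected weights are zero ",
         "(e.g. disjoint supports at epsilon = 0, or a pooled measure ",
         "vanishing everywhere)")
  discrete_opinion(w * (p$total_mass / s), total_mass = p$total_mass)
}

#' Sequential revision by an ordered list of persuaders
#'
#' Left-fold of [revise()] over a list of persuading opinions: the agent
#' meets the persuaders one at a time, in order, with the same parameters
#' for each interaction.  The order matters -- see [order_experiment()] for
#' the recency/primacy analysis.
#'
#' @param p the agent's prior opinion.
#' @param persuaders list of [discrete_opinion()] objects (possibly empty).
#' @param params a [revision_params()] object shared by all interactions.
#' @return the final [discrete_opinion()].
#' @examples
#' p <- discrete_opinion(c(0.5, 0.5))
#' revise_sequence(p, list(discrete_opinion(c(1, 0)),
#'                         discrete_opinion(c(0, 1))),
#'                 revision_params(0.5))$weights  # c(0.4727, 0.5273)
#' @export
revise_sequence <- function(p, persuaders, params) {
  p <- as_discrete_opinion(p)
  for (q in persuaders) p <- revise(p, q, params)
  p
}
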
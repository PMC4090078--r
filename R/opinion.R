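#' Discrete probabilistic opinions
#'
#' A discrete opinion assigns a nonnegative weight to each of `K >= 2`
#' mutually exclusive events.  The overall normalization (`total_mass`) is a
#' free parameter: opinions elicited in percent sum to 100, opinions on the
#' probability scale sum to 1.  All revision operators are homogeneous of
#' degree one, so the choice of normalization never affects relative weights
#' -- but two opinions can only interact when they share the same
#' normalization (see [revise()]).
#'
#' @param weights numeric vector of `K >= 2` nonnegative weights.
#' @param total_mass positive scalar the weights must sum to.  Defaults to
#'   `sum(weights)`, i.e. the vector is taken at face value.
#' @return an object of class `discrete_opinion`: a list with elements
#'   `weights` and `total_mass`.
#' @examples
#' discrete_opinion(c(0.3, 0.7))
#' discrete_opinion(c(30, 70), total_mass = 100)
#' @seealso [revise()], [grid_opinion()] for the continuous counterpart.
#' @export
discrete_opinion <- function(weights, total_mass = sum(weights)) {
  weights <- as.numeric(weights)
  if (length(weights) < 2L)
    stop("a discrete opinion needs at least two events (K >= 2)")
  if (anyNA(weights) || any(weights < 0))
    stop("opinion weights must be nonnegative and free of NA")
  if (!is.numeric(total_mass) || length(total_mass) != 1L || total_mass <= 0)
    stop("'total_mass' must be a positive scalar")
  s <- sum(weights)
  if (abs(s - total_mass) > 1e-9 * total_mass)
    stop(sprintf(
      "weights sum to %.12g but 'total_mass' is %.12g (relative tolerance 1e-9)",
      s, total_mass))
  structure(list(weights = weights, total_mass = total_mass),
            class = "discrete_opinion")
}

#' @export
print.discrete_opinion <- function(x, ...) {
  cat(sprintf("Discrete opinion over %d events (total mass %g)\n",
              length(x$weights), x$total_mass))
  print(x$weights, ...)
  invisible(x)
}

#' @rdname discrete_opinion
#' @param x object to coerce or test.
#' @export
as_discrete_opinion <- function(x) {
  if (inherits(x, "discrete_opinion")) return(x)
  discrete_opinion(as.numeric(x))
}

#' @rdname discrete_opinion
#' @export
is_discrete_opinion <- function(x) inherits(x, "discrete_opinion")

#' Revision parameters
#'
#' Bundles the projection/credibility weight `epsilon` with the rule variant.
#' `epsilon = 1` is full conservatism (the opinion never changes),
#' `epsilon = 0` is full acceptance of the persuader, and `epsilon > 1` is
#' the boomerang (backfire) regime in which the pooled opinion becomes a
#' signed measure and revision moves *away* from the persuader.
#'
#' @param epsilon nonnegative scalar.  The variants
#'   `"average_then_project"` and `"project_then_average"` require
#'   `0 <= epsilon <= 1`; `"boomerang"` requires `epsilon > 1`.
#' @param variant one of `"average_then_project"` (the default: pool
#'   linearly, then project onto the prior), `"project_then_average"`
#'   (project the persuading opinion first, then pool), or `"boomerang"`.
#' @return an object of class `revision_params`.
#' @examples
#' revision_params(0.5)
#' revision_params(1.5, variant = "boomerang")
#' @export
revision_params <- function(epsilon,
                            variant = c("average_then_project",
                                        "project_then_average",
                                        "boomerang")) {
  variant <- match.arg(variant)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0)
    stop("'epsilon' must be a nonnegative scalar")
  if (variant == "boomerang") {
    if (epsilon <= 1)
      stop("the boomerang variant requires epsilon > 1")
  } else if (epsilon > 1) {
    stop("variants 'average_then_project' and 'project_then_average' require ",
         "0 <= epsilon <= 1; use variant = 'boomerang' for epsilon > 1")
  }
  structure(list(epsilon = epsilon, variant = variant),
            class = "revision_params")
}

#' @export
print.revision_params <- function(x, ...) {
  cat(sprintf("Revision parameters: epsilon = %g, variant = %s\n",
              x$epsilon, x$variant))
  invisible(x)
}

#' Signed pooled weights
#'
#' The linear pool `epsilon * p + (1 - epsilon) * q` of two opinions.  For
#' `epsilon <= 1` all entries are nonnegative; in the boomerang regime
#' (`epsilon > 1`) entries may be negative and the vector is a signed
#' measure.  The total mass is preserved by construction.
#'
#' @param values numeric vector of pooled values.
#' @param total_mass the common total mass of the pooled opinions.
#' @param epsilon the pooling weight used (only recorded; `epsilon <= 1`
#'   triggers a nonnegativity check).
#' @return an object of class `signed_weights`.
#' @seealso [pool_opinions()]
#' @export
signed_weights <- function(values, total_mass, epsilon = NA_real_) {
  values <- as.numeric(values)
  if (abs(sum(values) - total_mass) > 1e-9 * abs(total_mass))
    stop("signed weights must sum to 'total_mass'")
  if (!is.na(epsilon) && epsilon <= 1 && any(values < 0))
    stop("negative pooled weights are only possible in the boomerang regime")
  structure(list(values = values, total_mass = total_mass, epsilon = epsilon),
            class = "signed_weights")
}

#' @export
print.signed_weights <- function(x, ...) {
  cat(sprintf("Pooled (signed) weights, total mass %g:\n", x$total_mass))
  print(x$values, ...)
  invisible(x)
}

# shared input check for binary operations on discrete opinions
check_compatible <- function(p, q) {
  if (length(p$weights) != length(q$weights))
    stop("opinions are defined over different numbers of events")
  if (abs(p$total_mass - q$total_mass) >
      1e-9 * max(p$total_mass, q$total_mass))
    stop("opinions use different total masses; rescale explicitly before ",
         "combining (a common normalization is required)")
  invisible(TRUE)
}
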
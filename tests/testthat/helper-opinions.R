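# shared generators for randomized property tests (always seeded by caller)

random_opinion <- function(K, total_mass = 1, allow_zero = FALSE) {
  w <- stats::rgamma(K, shape = 1)
  if (allow_zero && stats::runif(1) < 0.3)
    w[sample(K, sample(K - 1L, 1L))] <- 0
  if (sum(w) == 0) w[1L] <- 1
  discrete_opinion(w * (total_mass / sum(w)), total_mass = total_mass)
}

# palindromic prior plus mirror-image persuaders for order experiments
random_symmetric_setup <- function(K = NULL) {
  if (is.null(K)) K <- sample(2:6, 1L)
  w <- stats::rgamma(ceiling(K / 2), shape = 1)
  p <- if (K %% 2 == 0) c(w, rev(w))
       else c(w[-length(w)], w[length(w)], rev(w[-length(w)]))
  q <- stats::rgamma(K, shape = 1)
  list(p = discrete_opinion(p / sum(p)),
       q = discrete_opinion(q / sum(q)),
       q_prime = discrete_opinion(rev(q) / sum(q)))
}

default_params <- function(eps) revision_params(eps)

std_grid <- function(lo = -10, hi = 10, n = 2001L) opinion_grid(lo, hi, n)
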
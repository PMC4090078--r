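test_that("weighted-average prediction has the right limits and signs", {
  p <- gaussian_params(0, 1)
  # full conservatism: no weight on the persuader
  wa1 <- weighted_average_prediction(p, gaussian_params(2, 1), 1)
  expect_equal(wa1$weight_other, 0)
  expect_equal(wa1$predicted_anchor, 0)
  expect_equal(wa1$weight_self + wa1$weight_other, 1)
  # a more confident persuader (smaller sigma_q) gets more weight
  w_narrow <- weighted_average_prediction(p, gaussian_params(1, 0.5),
                                          0.5)$weight_other
  w_wide <- weighted_average_prediction(p, gaussian_params(1, 2),
                                        0.5)$weight_other
  expect_gt(w_narrow, w_wide)
  # equal anchors, narrower persuader: revised opinion becomes narrower
  expect_lt(weighted_average_prediction(p, gaussian_params(0, 0.5),
                                        0.5)$predicted_dispersion_ratio, 1)
  expect_gt(weighted_average_prediction(p, gaussian_params(0, 2),
                                        0.5)$predicted_dispersion_ratio, 1)
  # ... and the inequality reverses in the boomerang regime
  expect_gt(weighted_average_prediction(p, gaussian_params(0, 0.9),
                                        1.5)$predicted_dispersion_ratio, 1)
  # boomerang: negative persuader weight, anchor drifts away
  expect_lt(weighted_average_prediction(p, gaussian_params(1, 1),
                                        1.5)$weight_other, 0)
})

test_that("the full rule converges to the weighted-average prediction", {
  p <- gaussian_params(0, 1); eps <- 0.5
  g <- opinion_grid(-8, 8, 4001L)
  pg <- gaussian_opinion(p, g)
  shift_err <- vapply(c(0.08, 0.04, 0.02), function(m) {
    q <- gaussian_params(m, 0.6)
    pred <- weighted_average_prediction(p, q, eps)$predicted_anchor
    # sub-grid anchor via the exact revised log density
    opt <- optimize(function(x) {
      pv <- dnorm(x, 0, 1); qv <- dnorm(x, m, 0.6)
      eps * log(pv) + (1 - eps) * log(eps * pv + (1 - eps) * qv)
    }, c(-0.5, 0.5), maximum = TRUE, tol = 1e-12)
    abs(opt$maximum / pred - 1)
  }, numeric(1))
  # first-order agreement: relative error shrinks roughly linearly in m
  expect_lt(shift_err[2], shift_err[1] * 0.7)
  expect_lt(shift_err[3], shift_err[2] * 0.7)
  expect_lt(shift_err[3], 0.05)
})

test_that("anchor detection handles single peaks, mixtures and plateaus", {
  g <- opinion_grid(-10, 10, 2001L)
  p <- gaussian_opinion(gaussian_params(1.5, 1), g)
  a <- find_anchors(p)
  expect_equal(nrow(a$anchors), 1L)
  expect_equal(a$dominant$location, 1.5, tolerance = 1e-6)
  mix <- grid_opinion(g, dnorm(g$x, -3, 0.8) + 0.6 * dnorm(g$x, 3, 0.8))
  am <- find_anchors(mix)
  expect_equal(nrow(am$anchors), 2L)
  expect_equal(am$dominant$location, -3, tolerance = 1e-3)
  expect_equal(sort(am$anchors$location), c(-3, 3), tolerance = 1e-3)
  # flat-top plateau collapses to its midpoint
  y <- pmin(dnorm(g$x, 0, 2), dnorm(1, 0, 2))
  af <- find_anchors(grid_opinion(g, y))
  expect_equal(af$dominant$location, 0, tolerance = 1e-9)
})

test_that("opinion change is an inverted U of discrepancy with m* in the
           non-commitment latitude", {
  sw <- discrepancy_sweep(1, 1, 0.5, seq(0, 6, by = 0.1))
  tab <- sw$table
  expect_lt(tab$h[1], 1e-9)                      # no change at m = 0
  expect_lt(abs(tab$anchor_shift[1]), 1e-6)
  i_star <- which.max(tab$h)
  expect_gt(i_star, 1); expect_lt(i_star, nrow(tab))   # interior maximum
  expect_true(all(diff(tab$h[1:i_star]) > 0))
  expect_true(all(diff(tab$h[i_star:nrow(tab)]) < 0))
  expect_gt(sw$m_star, 2); expect_lt(sw$m_star, 3)     # 2 sigma .. 3 sigma
  # the TV maximizer sits at the acceptance boundary on this grid
  expect_gte(sw$m_star_tv, 2); expect_lt(sw$m_star_tv, 3)
})

test_that("a small-epsilon sweep triggers the abrupt anchor-jump detector", {
  fired <- FALSE
  for (eps in seq(0.05, 0.3, by = 0.05)) {
    sw <- discrepancy_sweep(1, 1, eps, seq(0, 6, by = 0.1))
    if (sw$anchor_jump) { fired <- TRUE; break }
  }
  expect_true(fired)
  # mid-range epsilon shows no such discontinuity
  expect_false(discrepancy_sweep(1, 1, 0.6, seq(0, 6, by = 0.1))$anchor_jump)
})

test_that("equal-anchor discrepancy drives a monotone change", {
  # one family at a time: a persuader more confident than the agent, or
  # less -- mixing the two sides trades confidence against discrepancy and
  # is not covered by the monotonicity claim
  narrow <- monotone_discrepancy_check(1, 0.5, c(1, 0.8, 0.6, 0.5, 0.4))
  expect_true(attr(narrow, "monotone_h"))
  expect_true(attr(narrow, "monotone_tv"))
  expect_lt(narrow$h[narrow$sigma_q == 1], 1e-9)   # sigma_q = sigma_p
  wide <- monotone_discrepancy_check(1, 0.5, c(1, 1.5, 2, 2.5, 3))
  expect_true(attr(wide, "monotone_h"))
  expect_true(attr(wide, "monotone_tv"))
  # Hellinger and TV orderings agree within each family
  expect_equal(order(narrow$h), order(narrow$h_tv))
  expect_equal(order(wide$h), order(wide$h_tv))
})

test_that("the binary order experiment shows recency and matches the oracle", {
  r <- order_experiment(discrete_opinion(c(0.5, 0.5)),
                        discrete_opinion(c(1, 0)),
                        discrete_opinion(c(0, 1)), 0.5)
  expect_equal(r$final_forward$weights,
               c(0.47273387498950473, 0.52726612501049527), tolerance = 1e-12)
  expect_identical(r$verdict, "recency")
  expect_lt(r$d_to_last, r$d_to_first)
  # the reverse order mirrors the forward one
  expect_equal(r$final_reverse$weights, rev(r$final_forward$weights),
               tolerance = 1e-12)
})

test_that("recency holds across randomized symmetric setups", {
  set.seed(1234)
  for (i in 1:200) {
    s <- random_symmetric_setup()
    r <- order_experiment(s$p, s$q, s$q_prime, runif(1, 0.05, 0.95))
    expect_identical(r$verdict, "recency")
  }
})

test_that("recency persists under alternating multi-exposure sequences", {
  set.seed(4321)
  for (i in 1:200) {
    s <- random_symmetric_setup()
    eps <- runif(1, 0.05, 0.95)
    params <- revision_params(eps)
    fwd <- revise_sequence(s$p, list(s$q, s$q_prime, s$q, s$q_prime), params)
    expect_lt(hellinger(fwd, s$q_prime), hellinger(fwd, s$q))
  }
})

test_that("Gaussian symmetric setups show recency and reject asymmetry", {
  r <- order_experiment(gaussian_params(0, 1), gaussian_params(1.5, 1),
                        gaussian_params(-1.5, 1), 0.5)
  expect_identical(r$verdict, "recency")
  expect_error(order_experiment(gaussian_params(0, 1),
                                gaussian_params(1.5, 1),
                                gaussian_params(-2, 1), 0.5), "symmetric")
  expect_error(order_experiment(discrete_opinion(c(0.3, 0.7)),
                                discrete_opinion(c(1, 0)),
                                discrete_opinion(c(0, 1)), 0.5),
               "palindromic")
})

test_that("deep in the boomerang regime the verdict flips to primacy", {
  pc <- primacy_crossover(coarse = 0.1)
  expect_false(is.na(pc$epsilon_star))
  expect_gt(pc$epsilon_star, 1); expect_lte(pc$epsilon_star, 3)
  p <- discrete_opinion(c(0.5, 0.5))
  q <- discrete_opinion(c(1, 0)); qp <- discrete_opinion(c(0, 1))
  below <- order_experiment(p, q, qp, 1.2)
  above <- order_experiment(p, q, qp, pc$epsilon_star + 0.1)
  expect_identical(below$verdict, "recency")
  expect_identical(above$verdict, "primacy")
  # archived crossover fixture matches the recomputed value
  fix <- jsonlite::read_json(system.file("extdata",
    "primacy_crossover_witness.json", package = "confbias"),
    simplifyVector = TRUE)
  expect_equal(pc$epsilon_star, fix$epsilon_star, tolerance = 1e-6)
})

test_that("dissonance emerges for a narrow credible persuader and is
           suppressed along the three reduction routes", {
  p <- gaussian_params(0, 2); q <- gaussian_params(2, 0.3)
  base <- dissonance_scenario(p, q, 0.5)
  expect_identical(base$classification, "dissonant")
  an <- base$anchors$anchors
  ratio <- an$height[2] / an$height[1]
  expect_gte(ratio, 1 / 3); expect_lte(ratio, 3)
  # (i) raising epsilon makes the persuader less credible: old single peak
  high <- dissonance_scenario(p, q, 0.95)
  expect_true(high$classification %in% c("single-peak", "dominated-old"))
  expect_lt(abs(high$anchors$dominant$location - 0), 0.5)
  # (iii) lowering epsilon: the new peak dominates
  low <- dissonance_scenario(p, q, 0.1)
  expect_true(low$classification %in% c("dominated-new", "single-peak"))
  dom_low <- if (low$classification == "single-peak")
    low$anchors$dominant$location else low$anchors$anchors$location[1]
  expect_lt(abs(dom_low - q$mu), 0.5)
  # (ii) narrowing the prior suppresses the splitting
  narrow <- dissonance_scenario(gaussian_params(0, 0.4), q, 0.5)
  expect_true(narrow$classification != "dissonant")
})

test_that("a certain persuader can promote a tail event to the maximum", {
  p <- discrete_opinion(rep(0.25, 4))
  pt <- certain_persuader_revision(p, 2, 0.5)
  expect_identical(which.max(pt$weights), 2L)
  expect_true(all(pt$weights[-2] < pt$weights[2]))
  # a ruled-out event stays ruled out, opinion unchanged
  pz <- discrete_opinion(c(0, 0.5, 0.5))
  expect_equal(certain_persuader_revision(pz, 1, 0.3)$weights, pz$weights,
               tolerance = 1e-12)
  # a small but positive tail event becomes the global maximum
  K <- 10
  ptail <- discrete_opinion(c(rep(0.99 / (K - 1), K - 1), 0.01))
  out <- certain_persuader_revision(ptail, K, 0.3)
  expect_identical(which.max(out$weights), as.integer(K))
})

test_that("the boomerang report captures the backfire signature", {
  rep <- boomerang_revision_report(gaussian_params(0, 1),
                                   gaussian_params(1.5, 1), 1.5)
  expect_true(rep$moves_away)
  expect_lt(rep$anchor_shift, 0)
  expect_true(rep$peak_enhanced)
  expect_lt(rep$width_ratio, 1)                 # dominant peak narrows
  expect_gte(rep$peak_count, 2L)
  expect_length(rep$x0, 1L)
  expect_gt(rep$x0, 0); expect_lt(rep$x0, 1.5)
  expect_lt(rep$min_over_peak, 0.05)            # near-zero local minimum
  # equal anchors, narrower persuader: revised opinion widens
  rep2 <- boomerang_revision_report(gaussian_params(0, 1),
                                    gaussian_params(0, 0.9), 1.5)
  expect_gt(rep2$width_ratio, 1)
  expect_error(boomerang_revision_report(gaussian_params(0, 1),
                                         gaussian_params(1, 1), 0.5),
               "epsilon > 1")
})

test_that("the order-difference at small (1-eps) depends only on the
           persuaders", {
  # leading-order structure: the forward/reverse difference is a function
  # of (q, q') alone; changing p moves it only at higher order in (1-eps)
  q <- discrete_opinion(c(0.7, 0.3)); qp <- discrete_opinion(c(0.3, 0.7))
  diff_for <- function(p, eps) {
    params <- revision_params(eps)
    a <- revise_sequence(p, list(q, qp), params)
    b <- revise_sequence(p, list(qp, q), params)
    a$weights - b$weights
  }
  p1 <- discrete_opinion(c(0.5, 0.5)); p2 <- discrete_opinion(c(0.4, 0.6))
  rel_dev <- vapply(c(0.1, 0.05, 0.025), function(delta) {
    d1 <- diff_for(p1, 1 - delta); d2 <- diff_for(p2, 1 - delta)
    max(abs(d1 - d2)) / max(abs(d1))
  }, numeric(1))
  expect_lt(rel_dev[2], rel_dev[1] * 0.7)
  expect_lt(rel_dev[3], rel_dev[2] * 0.7)
})
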
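---
title: "Confirmation-biased opinion revision: model, parameters, and design notes"
author: "confbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confirmation-biased opinion revision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confbias)
```

## The model

An agent holds a subjective probabilistic opinion over the states of an
uncertain quantity: a nonnegative weight vector $p = (p_1, \dots, p_K)$
with a free overall normalization $M$ (1 for probabilities, 100 for
percentages), or a density $p(x)$ in the continuous case.  A persuader
holds an opinion $q$ over the same states.  Persuasion carries no new
evidence about the world — only another opinion — which is why Bayesian
conditioning is the wrong tool here: it would change the agent's opinion
even when $p = q$, and under repetition it polarizes rather than
converges.

The revision rule composes two cognitively motivated sub-processes:

1. **Linear pooling.**  The agent forms
   $\pi_k = \varepsilon\, p_k + (1 - \varepsilon)\, q_k$, the classical
   linear opinion pool.  The weight $\varepsilon \in [0, 1]$ aggregates
   everything that makes the agent keep his own counsel: the persuader's
   perceived credibility, egocentric discounting, access to one's own
   reasons but not the other's.

2. **Projection (trimming).**  The pooled opinion is projected back onto
   the prior with the power form
   $w_k = p_k^{\varepsilon}\, \pi_k^{1-\varepsilon}$, the unique
   projection that commutes with probabilistic conditioning — so it does
   not matter whether the agent conditions first and revises second, or
   the other way round.  The output is renormalized to $M$.

Together:
$$
\tilde p_k \;\propto\; p_k^{\varepsilon}\,
\bigl(\varepsilon p_k + (1-\varepsilon) q_k\bigr)^{1-\varepsilon},
\qquad 0 < \varepsilon \le 1 .
$$

The rule satisfies, by construction: ruled-out events stay ruled out
($p_k = 0 \Rightarrow \tilde p_k = 0$, with the convention $0^e = 0$);
no persuasion without overlap (disjoint supports leave $p$ unchanged);
identical opinions are never revised; and joint rescaling of $p$ and $q$
rescales the output (homogeneity of degree one), so any common
normalization is acceptable.  At $\varepsilon = 1$ the agent is perfectly
conservative.  At $\varepsilon = 0$ he adopts $q$ outright — but only if
all his weights are positive; the limit is discontinuous when some
$p_k = 0$, and `revise()` raises a degenerate-revision error there rather
than guessing a value.

```{r worked}
p <- discrete_opinion(c(0.5, 0.5))        # fully ignorant binary opinion
q <- discrete_opinion(c(1, 0))            # a certain persuader
revise(p, q, revision_params(0.5))$weights
```

The first entry is $\sqrt3 / (1 + \sqrt3) \approx 0.634$: a certain
persuader moves an ignorant agent substantially, but not all the way.

The alternative processing order — project the persuading opinion first,
then pool (`variant = "project_then_average"`) — gives qualitatively
similar results: across randomized instances the two variants lie closer
to each other than the distance either of them moves, and they pick the
same anchor up to near-ties.  The one corner where they genuinely part
ways is a credulous agent (small $\varepsilon$) facing an almost-opposed
persuader; there the pooling-then-projection order (the default) is the
one with experimental support, so we keep it.

## Continuous opinions, latitudes

Densities are handled on uniform grids with trapezoid quadrature
(`grid_opinion`, `revise_density`).  A 100-point grid already matches the
discrete rule applied to bin masses to within $10^{-2}$ in Hellinger
distance; quantitative work in this package uses 2001 points spanning six
standard deviations beyond every anchor, for which grid-refinement
changes are below $10^{-3}$.

Two parametric families are provided.  Gaussian opinions
(`gaussian_opinion`) have anchor $\mu$ (the most probable value) and
dispersion $\sigma$ (the opinion's uncertainty).  Bump opinions
(`bump_opinion`) are proportional to $\exp\{-b/(1-x^2)\}$ on $(-1,1)$ and
exactly zero outside: infinitely smooth yet with bounded support, flat
for small sharpness $b$ and Gaussian-like for large $b$.  The bump
normalization constant is computed numerically per $b$; no closed form is
assumed.

Social-judgment latitudes are identified with the two- and three-sigma
zones of a Gaussian opinion: acceptance $|x-\mu| \le 2\sigma$,
non-commitment $2\sigma < |x-\mu| \le 3\sigma$, rejection beyond
$3\sigma$, carrying 95.4%, 4.3% and 0.3% of probability.  When two
opinions overlap only within their rejection latitudes, neither can
effectively move the other: the package's test asserts a Hellinger change
below 0.05 there, a threshold we chose ourselves since the qualitative
statement comes with no number.

## Distances

The opinion change and discrepancy are measured with the Hellinger
distance, $H^2(p,q) = 1 - \int\!\sqrt{pq}$, on mass-1 rescalings, with
total variation as a cross-check.  Numerically we evaluate
$H^2 = \tfrac12 \int (\sqrt p - \sqrt q)^2$: the two forms are
algebraically identical, but the overlap form cannot resolve distances
below $\sim 10^{-8}$ (catastrophic cancellation), which matters because
the repeated-persuasion stopping rule is $H < 10^{-8}$.  For Gaussian
pairs the closed form
$1 - H^2 = \sqrt{2\sigma_a\sigma_b/(\sigma_a^2+\sigma_b^2)}\,
\exp\{-(\mu_a-\mu_b)^2/4(\sigma_a^2+\sigma_b^2)\}$ agrees with adaptive
quadrature to better than $10^{-6}$.  The f-divergence family
$D_f(p\|q) = \sum_k q_k f(p_k/q_k)$ supplies Lyapunov functions; the
generators for Hellinger, total variation and Kullback–Leibler are
exported.  Conventions: $0\log 0 = 0$; support mismatch returns a flagged
`Inf`, not an error.

## Weighted-average limit

For small anchor discrepancy $m = \mu_q - \mu_p$ the revised anchor obeys
the weighted-average model $\tilde x^* = w_A \mu_p + w_B \mu_q$.
Expanding the revised log density around the prior anchor gives
$$
w_B = \frac{B}{A + B}, \qquad
A = \frac{\varepsilon + (1-\varepsilon)a}{\sigma_p^2}, \quad
B = \frac{(1-\varepsilon)(1-a)}{\sigma_q^2}, \quad
a = \frac{\varepsilon\sigma_q}{\varepsilon\sigma_q +
    (1-\varepsilon)\sigma_p},
$$
so the persuader's weight grows with his confidence ($\sigma_q^{-1}$) and
falls with the agent's, vanishing at $\varepsilon = 1$.  The same
expansion at equal anchors gives the first-order dispersion change: a
more confident persuader narrows the agent's opinion.
`weighted_average_prediction()` implements both, and the tests verify the
prediction against the full rule: the ratio of the true to the predicted
anchor shift tends to 1 as $m \to 0$, with the error shrinking linearly
in $m$.  In the boomerang regime (below) the expansion is taken around
the boomerang rule instead; the persuader's weight then comes out
negative (drift away) and the dispersion inequality reverses.

## Change versus discrepancy

`discrepancy_sweep()` fixes $\sigma_p, \sigma_q, \varepsilon$ and sweeps
$m$.  For mid-range $\varepsilon$ the opinion change $h(m)$ is an
inverted U with an interior maximum $m^\ast$ inside the non-commitment
latitude ($2\sigma_p < m^\ast < 3\sigma_p$) — the persuader is most
effective when moderately, not maximally, discrepant.  For small
$\varepsilon$ the dominant anchor jumps discontinuously at a critical
$m$: a subdominant peak grows with $m$ and abruptly overtakes the old
one.  The detector flags a jump when one secant step of the anchor track
exceeds five times the preceding step and a floor of $0.05\sigma_p$ (the
floor suppresses noise-level firing; both constants are package choices).
At exactly equal anchors the relationship is instead monotone: with
discrepancy driven by $\sigma_q$ alone, a larger discrepancy produces a
larger change.  That monotonicity holds within each one-sided family
(persuader uniformly more confident, or uniformly less confident, than
the agent); mixing the two sides trades confidence against discrepancy
and need not be monotone, so the tests check each side separately.

## Order of presentation

With two persuaders symmetric about the agent's anchor and a common
$\varepsilon \in (0,1)$, the final opinion is always closer — anchor and
distance — to the *last* persuader: the model predicts recency
unconditionally in this regime, and the randomized harness (palindromic
discrete priors with mirror-image persuaders, and symmetric Gaussian
setups) finds no exception in hundreds of draws, including alternating
multi-exposure sequences.  The small-$(1-\varepsilon)$ expansion explains
why: to leading order the difference between the two orders depends only
on the two persuading opinions, not on the agent's — verified numerically
by showing the dependence on $p$ enters at higher order.  Primacy appears
only deep in the boomerang regime: on the binary worked example the
verdict flips at $\varepsilon^\ast \approx 2.81$, located by
deterministic scan plus bisection and archived as a fixture.

## Cognitive dissonance

A narrow, credible, moderately displaced persuader splits a broad prior
into two comparable peaks — the agent simultaneously holds his old anchor
and the persuader-induced one.  `dissonance_scenario()` classifies the
outcome by the anchor structure; "comparable" means a height ratio within
a factor of 3, our own quantification of a qualitative phrase.  The three
classic reduction routes fall out of the parameters: raise $\varepsilon$
(discredit the source) and the new peak dies; lower it and the new peak
wins; narrow the prior and no splitting occurs.  The packaged witness
(`fig5_dissonance`: $\sigma_p = 2$, $\mu_q = 2$, $\sigma_q = 0.3$,
$\varepsilon = 0.5$) was found by a deterministic parameter scan.

## Repeated persuasion

Iterating the rule against a fixed persuader with $q_k > 0$ for all $k$
and $\varepsilon \in (0,1)$ drives the opinion to $q$, the unique fixed
point: every f-divergence to $q$ is non-increasing along the trajectory
(strictly, away from the fixed point), and the Hellinger distance to $q$
decays monotonically.  Convergence time grows with $\varepsilon$.
Monotonicity assertions use a $10^{-12}$ tolerance to absorb floating
noise.

Two refinements discovered while testing are worth recording.  First, the
Le Chatelier principle — overestimated events decay, underestimated ones
rise — holds *exactly* in normalization-free form: before renormalization
every overestimated weight contracts and every underestimated one expands
(the pooled-projected sum never exceeds the total mass, by the
geometric–arithmetic mean inequality), so at every step each
overestimated event grows by a strictly smaller factor than each
underestimated one.  The common renormalization factor is $\ge 1$,
however, so a *barely* overestimated event can transiently gain absolute
mass while a grossly overestimated one sheds it; `diagnostics()` counts
violations of the growth-factor ordering, which is the invariant content.
Second, the law of diminishing returns fails: the largest per-step change
need not be the first.  `diminishing_returns_witness()` scans a
deterministic lattice on the 3-simplex (no randomness, bit-for-bit
reproducible) and finds an initial opinion — essentially certain of one
state, facing a uniform persuader — whose second revision moves it
further than its first.

## Boomerang regime

When the persuader's credibility is so low that $\varepsilon > 1$, the
pooled opinion $\varepsilon p + (1-\varepsilon) q$ becomes a signed
measure.  The rule is continued through the conservatism point
$\varepsilon = 1$ as
$$
\tilde p_k \;\propto\; p_k^{\,2-\varepsilon}\,
\bigl|\varepsilon p_k + (1-\varepsilon) q_k\bigr|^{\varepsilon-1},
$$
with zero-crossings of the pooled measure mapped to zero weight (no
flooring) and $p_k = 0$ still forcing $\tilde p_k = 0$.  The absolute
value keeps probabilities nonnegative at the price of smoothness.  The
continuation reproduces the backfire phenomenology: the dominant anchor
moves *away* from the persuader and its peak is enhanced and narrowed;
the density develops a near-zero local minimum at the crossing point
$x_0$; in the overlap band (weight ratios below
$(\varepsilon+1)/(\varepsilon-1)$) every event the agent trails on loses
probability relative to every event he leads on — outside that band the
emergent second peak can gain mass, which is exactly how dissonance
becomes easier to trigger here.  Under repeated boomerang persuasion the
opinion splits: the smaller peak migrates into the persuader's acceptance
latitude while the dominant peak narrows and retreats, and the opinion
then stops changing.  Stationarity is measured between consecutive
opinions (the trajectory never approaches $q$); the default tolerance is
a consecutive-step Hellinger of $10^{-4}$, because the late-time decay is
a slow power law and tightening the tolerance by orders of magnitude
changes nothing qualitative while multiplying the run length enormously.

## What the synthetic inputs do and do not show

Every test input is synthetic and generated in code: random simplex
points (gamma draws), parametric Gaussian/bump densities, and
deterministic witness scans standing in for unprinted figure settings.
This exercises the operators over the full parameter ranges the model
admits, which is the right evidence for a mathematical-model package.  It
does not calibrate $\varepsilon$ to any empirical persuasion data, does
not model heterogeneous or time-varying credibility, retention-time
effects (which govern the empirical recency-to-primacy switch), long-term
memory, or multi-agent consensus; opinions are one-dimensional only.
Passing tests certify the model's internal phenomenology, not its fit to
any particular experiment.

## Numerical choices, in one place

* Input validation: weights nonnegative, sums within $10^{-9}$ relative;
  outputs renormalized exactly.  Mixing total masses is an error, never a
  silent rescale.
* Power convention $0^e = 0$; at $\varepsilon = 0$ the rule returns $q$
  only when all $p_k > 0$, else errors.
* Quadrature: trapezoid throughout; density grids 100 points for
  figure-style runs, 2001 for quantitative ones, spanning
  $\mu \pm 6\sigma$ (a warning fires below $5\sigma$ coverage).
* Anchors: grid local maxima, plateaus collapsed to midpoints, refined by
  local quadratic interpolation; Gaussian-pair anchors refined by exact
  log-density optimization.
* Convergence: Hellinger-to-persuader below $10^{-8}$ (normal regime);
  consecutive-step Hellinger below $10^{-4}$ (boomerang).
* Problem sizes in the test-suite and acceptance runs: 500 randomized
  axiom instances, 200 order-effect and 200 repeated-persuasion draws,
  100 closed-form-versus-quadrature pairs, 61-point discrepancy sweeps,
  and boomerang iteration on a 241-point grid — sizes at which every
  randomized check is stable across seeds.
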
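Package: confbias
Title: Confirmation-Biased Opinion Revision and Persuasion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how a confirmationally biased agent revises a
    subjective probabilistic opinion under persuasion.  The revision operator
    linearly pools the agent's opinion with the persuading opinion and then
    projects the pooled opinion back onto the prior via the unique power-law
    projection that commutes with probabilistic conditioning.  The package
    covers discrete opinions and Gaussian or bump densities on a grid,
    social-judgment latitudes, Hellinger and total-variation distances with
    an f-divergence family, repeated-persuasion dynamics with Lyapunov
    diagnostics, order-of-presentation (recency versus primacy) experiments,
    cognitive-dissonance scenarios, and the boomerang (backfire) regime
    obtained by continuing the rule to projection weights above one.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
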
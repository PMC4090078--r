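#' Opinion JSON input/output
#'
#' Discrete opinions use the schema
#' `{"weights": [...], "total_mass": 1.0}`.  Parametric and grid densities
#' use `{"family": "gaussian", "mu": , "sigma": }`,
#' `{"family": "bump", "b": }` or
#' `{"family": "grid", "x": [...], "density": [...]}`.
#' Numbers are written with 17 significant digits so identical inputs give
#' byte-identical outputs.
#'
#' @param path file path.
#' @return `read_opinion_json()` returns a [discrete_opinion()]; the
#'   writers return `path` invisibly.
#' @name opinion_io
NULL

#' @rdname opinion_io
#' @export
read_opinion_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(o$weights)) stop("opinion JSON must contain 'weights'")
  tm <- if (is.null(o$total_mass)) sum(o$weights) else o$total_mass
  discrete_opinion(as.numeric(o$weights), total_mass = tm)
}

#' @rdname opinion_io
#' @param op a [discrete_opinion()].
#' @export
write_opinion_json <- function(op, path) {
  op <- as_discrete_opinion(op)
  jsonlite::write_json(list(weights = op$weights,
                            total_mass = op$total_mass),
                       path, auto_unbox = TRUE, digits = 17)
  invisible(path)
}

#' @rdname opinion_io
#' @param spec density spec list (as parsed from density JSON).
#' @param grid an [opinion_grid()] used to realize parametric families.
#' @export
density_from_spec <- function(spec, grid) {
  switch(spec$family,
    gaussian = gaussian_opinion(gaussian_params(spec$mu, spec$sigma), grid),
    bump = bump_opinion(spec$b, grid),
    grid = {
      x <- as.numeric(spec$x)
      g <- opinion_grid(x[1L], x[length(x)], length(x))
      grid_opinion(g, as.numeric(spec$density))
    },
    stop("unknown density family: ", spec$family))
}

#' @rdname opinion_io
#' @export
read_density_json <- function(path, grid = NULL) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(grid) && !identical(spec$family, "grid"))
    grid <- opinion_grid(-10, 10, 2001L)
  density_from_spec(spec, grid)
}

#' @rdname opinion_io
#' @export
write_density_csv <- function(op, path) {
  stopifnot(inherits(op, "grid_opinion"))
  utils::write.csv(data.frame(x = op$grid$x, density = op$density),
                   path, row.names = FALSE)
  invisible(path)
}

scenario_catalogue_names <- c(
  "eq_binary_order", "fig1_shift", "fig1_reinforce", "fig2_bump",
  "fig4_order", "fig5_dissonance", "fig6_boomerang",
  "fig9_boomerang_iterate")

#' Deterministic scenario fixtures
#'
#' Named, versioned parameter sets for the package's canonical scenarios.
#' Every scenario is fully deterministic (no random state), so repeated
#' runs give byte-identical numeric output.
#'
#' * `eq_binary_order` -- the analytic binary example: an ignorant agent
#'   (uniform binary opinion) meets two opposed certain persuaders with
#'   `epsilon = 1/2`.
#' * `fig1_shift` -- Gaussian pair with overlapping acceptance zones; the
#'   agent's opinion moves towards the persuader.
#' * `fig1_reinforce` -- equal anchors, narrower persuader; the agent's
#'   mode is reinforced.
#' * `fig2_bump` -- bump-density pair (finite support).
#' * `fig4_order` -- symmetric Gaussian order-of-presentation setup.
#' * `fig5_dissonance` -- narrow credible persuader splitting a broad
#'   prior into two comparable peaks.
#' * `fig6_boomerang` -- single boomerang revision, `epsilon = 1.5`.
#' * `fig9_boomerang_iterate` -- repeated boomerang persuasion to a
#'   stationary bimodal opinion, `epsilon = 1.2`.
#'
#' @param name scenario name; an unknown name raises an error listing the
#'   catalogue.
#' @return an object of class `scenario_spec` (a list of inputs ready for
#'   [run_scenario()]).
#' @export
make_scenario <- function(name) {
  sc <- switch(name,
    eq_binary_order = list(
      kind = "discrete_sequence",
      p = list(weights = c(0.5, 0.5), total_mass = 1),
      persuaders = list(list(weights = c(1, 0), total_mass = 1),
                        list(weights = c(0, 1), total_mass = 1)),
      epsilon = 0.5, variant = "average_then_project"),
    fig1_shift = list(
      kind = "density_revise",
      p = list(family = "gaussian", mu = 0, sigma = 1),
      q = list(family = "gaussian", mu = 1.5, sigma = 1),
      epsilon = 0.5, grid = list(x_lo = -6, x_hi = 7.5, n_points = 100L)),
    fig1_reinforce = list(
      kind = "density_revise",
      p = list(family = "gaussian", mu = 0, sigma = 1),
      q = list(family = "gaussian", mu = 0, sigma = 0.5),
      epsilon = 0.5, grid = list(x_lo = -6, x_hi = 6, n_points = 100L)),
    fig2_bump = list(
      kind = "density_revise",
      p = list(family = "bump", b = 1),
      q = list(family = "bump", b = 5),
      epsilon = 0.5, grid = list(x_lo = -1, x_hi = 1, n_points = 201L)),
    fig4_order = list(
      kind = "gaussian_order",
      p = list(mu = 0, sigma = 1),
      q = list(mu = 1.5, sigma = 1),
      q_prime = list(mu = -1.5, sigma = 1),
      epsilon = 0.5),
    fig5_dissonance = list(
      kind = "dissonance",
      p = list(mu = 0, sigma = 2),
      q = list(mu = 2, sigma = 0.3),
      epsilon = 0.5),
    fig6_boomerang = list(
      kind = "boomerang_report",
      p = list(mu = 0, sigma = 1),
      q = list(mu = 1.5, sigma = 1),
      epsilon = 1.5),
    fig9_boomerang_iterate = list(
      kind = "boomerang_iterate",
      p = list(family = "gaussian", mu = 0, sigma = 1),
      q = list(family = "gaussian", mu = 1.5, sigma = 1),
      epsilon = 1.2, steps = 8000L,
      grid = list(x_lo = -7, x_hi = 7.5, n_points = 241L)),
    stop("unknown scenario '", name, "'; available: ",
         paste(scenario_catalogue_names, collapse = ", "))
  )
  structure(c(list(name = name), sc), class = "scenario_spec")
}

#' @rdname make_scenario
#' @export
scenario_catalogue <- function() scenario_catalogue_names

#' Run a scenario and optionally write its artifacts
#'
#' Executes the operation a scenario describes and, when `out_dir` is
#' given, writes a JSON summary (17 significant digits) plus CSV
#' trajectories/densities.  Identical scenario specifications produce
#' byte-identical outputs.
#'
#' @param scenario a `scenario_spec` from [make_scenario()], or a scenario
#'   name.
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return the computed result (class depends on the scenario kind),
#'   invisibly when writing.
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  sc <- scenario
  res <- switch(sc$kind,
    discrete_sequence = {
      p <- discrete_opinion(sc$p$weights, sc$p$total_mass)
      persuaders <- lapply(sc$persuaders, function(o)
        discrete_opinion(o$weights, o$total_mass))
      params <- revision_params(sc$epsilon, sc$variant)
      steps <- vector("list", length(persuaders) + 1L)
      steps[[1L]] <- p
      for (i in seq_along(persuaders))
        steps[[i + 1L]] <- revise(steps[[i]], persuaders[[i]], params)
      list(steps = steps, final = steps[[length(steps)]])
    },
    density_revise = {
      g <- opinion_grid(sc$grid$x_lo, sc$grid$x_hi, sc$grid$n_points)
      p <- density_from_spec(sc$p, g)
      q <- density_from_spec(sc$q, g)
      pt <- revise_density(p, q, auto_params(sc$epsilon))
      list(p = p, q = q, revised = pt,
           anchors = find_anchors(pt, min_height_frac = 0.01))
    },
    gaussian_order = order_experiment(
      gaussian_params(sc$p$mu, sc$p$sigma),
      gaussian_params(sc$q$mu, sc$q$sigma),
      gaussian_params(sc$q_prime$mu, sc$q_prime$sigma), sc$epsilon),
    dissonance = dissonance_scenario(
      gaussian_params(sc$p$mu, sc$p$sigma),
      gaussian_params(sc$q$mu, sc$q$sigma), sc$epsilon),
    boomerang_report = boomerang_revision_report(
      gaussian_params(sc$p$mu, sc$p$sigma),
      gaussian_params(sc$q$mu, sc$q$sigma), sc$epsilon),
    boomerang_iterate = {
      g <- opinion_grid(sc$grid$x_lo, sc$grid$x_hi, sc$grid$n_points)
      iterate_boomerang(density_from_spec(sc$p, g),
                        density_from_spec(sc$q, g),
                        sc$epsilon, max_steps = sc$steps)
    },
    stop("unknown scenario kind: ", sc$kind))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scenario_artifacts(sc, res, out_dir)
    return(invisible(res))
  }
  res
}

write_scenario_artifacts <- function(sc, res, out_dir) {
  summary_path <- file.path(out_dir, paste0(sc$name, "_summary.json"))
  summ <- switch(sc$kind,
    discrete_sequence = list(
      scenario = sc$name, epsilon = sc$epsilon,
      final_weights = res$final$weights,
      total_mass = res$final$total_mass),
    density_revise = list(
      scenario = sc$name, epsilon = sc$epsilon,
      anchors = res$anchors$anchors,
      hellinger_change = hellinger(res$p, res$revised)),
    gaussian_order = list(
      scenario = sc$name, epsilon = sc$epsilon,
      d_to_first = res$d_to_first, d_to_last = res$d_to_last,
      verdict = res$verdict),
    dissonance = list(
      scenario = sc$name, epsilon = sc$epsilon,
      classification = res$classification,
      anchors = res$anchors$anchors),
    boomerang_report = list(
      scenario = sc$name, epsilon = sc$epsilon,
      anchor_shift = res$anchor_shift, moves_away = res$moves_away,
      peak_enhanced = res$peak_enhanced, width_ratio = res$width_ratio,
      peak_count = res$peak_count),
    boomerang_iterate = list(
      scenario = sc$name, epsilon = sc$params$epsilon,
      stationary = res$stationary,
      steps = length(res$opinions) - 1L,
      final_peaks =
        find_anchors(res$opinions[[length(res$opinions)]],
                     min_height_frac = 0.02)$anchors))
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = 17,
                       dataframe = "columns")
  if (sc$kind == "density_revise")
    write_density_csv(res$revised, file.path(out_dir,
                                             paste0(sc$name, "_revised.csv")))
  if (sc$kind == "discrete_sequence")
    write_opinion_json(res$final, file.path(out_dir,
                                            paste0(sc$name, "_final.json")))
  if (sc$kind == "boomerang_iterate")
    write_density_csv(res$opinions[[length(res$opinions)]],
                      file.path(out_dir, paste0(sc$name, "_final.csv")))
  invisible(summary_path)
}

#' Run a revision request given as JSON
#'
#' Request schema:
#' `{"p": {"weights": [...], "total_mass": 1.0},
#'   "q": {"weights": [...], "total_mass": 1.0},
#'   "epsilon": 0.5, "variant": "average_then_project"}`.
#'
#' @param path path to the request JSON.
#' @param out optional output path for the revised opinion JSON.
#' @return the revised [discrete_opinion()].
#' @export
run_revision_request <- function(path, out = NULL) {
  req <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("p", "q", "epsilon")) if (is.null(req[[key]]))
    stop("revision request must contain '", key, "'")
  variant <- if (is.null(req$variant)) {
    if (req$epsilon > 1) "boomerang" else "average_then_project"
  } else req$variant
  p <- discrete_opinion(as.numeric(req$p$weights),
                        total_mass = req$p$total_mass)
  q <- discrete_opinion(as.numeric(req$q$weights),
                        total_mass = req$q$total_mass)
  res <- revise(p, q, revision_params(req$epsilon, variant))
  if (!is.null(out)) write_opinion_json(res, out)
  res
}
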
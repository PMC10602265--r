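# Parameter search: an evolutionary strategy (rank selection, Gaussian
# mutation, multiplicative 1/5-success step-size adaptation) maximising the
# KS-based fitness, plus exhaustive grid search and a parameter-recovery
# harness.

#' Search space for free model parameters
#'
#' @param names Parameter names (any of `sigma_s`, `theta`, `s`, `r`,
#'   `sigma_i`, `xi`, or the names of a custom objective).
#' @param lower,upper Finite bounds, `lower < upper`, on a linear scale.
#' @return `data.frame` with columns `name`, `lower`, `upper`.
#' @export
search_space <- function(names, lower, upper) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  data.frame(name = as.character(names), lower = as.numeric(lower),
             upper = as.numeric(upper), stringsAsFactors = FALSE)
}

#' Evolutionary-optimisation configuration
#'
#' Defaults follow the published protocol: an initial population of 64, an
#' ongoing population of 32, and 50 generations. The mutation step size is a
#' fraction of each parameter's range, adapted multiplicatively each
#' generation (increased when more than `success_target` of offspring beat
#' their parent, decreased otherwise).
#'
#' @param n_initial Initial population size (default 64).
#' @param n_pop Ongoing population size (default 32).
#' @param n_generations Number of generations (default 50).
#' @param seed Integer seed.
#' @param step_init,step_min,step_max Initial/minimal/maximal mutation sd as
#'   a fraction of each parameter's range.
#' @param success_target Target success rate of the 1/5-success rule.
#' @param step_up,step_down Multiplicative step adjustments.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(n_initial = 64L, n_pop = 32L, n_generations = 50L,
                             seed = 1L, step_init = 0.2, step_min = 0.02,
                             step_max = 0.5, success_target = 0.2,
                             step_up = 1.5, step_down = 0.85) {
  stopifnot(n_initial >= 2, n_pop >= 2, n_generations >= 1)
  structure(list(n_initial = as.integer(n_initial), n_pop = as.integer(n_pop),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed), step_init = step_init,
                 step_min = step_min, step_max = step_max,
                 success_target = success_target, step_up = step_up,
                 step_down = step_down),
            class = "evolution_config")
}

#' Evolutionary parameter optimisation
#'
#' Maximises `objective` over the box `space`. Generation 1 evaluates
#' `n_initial` uniform random points and keeps the best `n_pop`. Each later
#' generation draws `n_pop` offspring from rank-weighted parents (linear rank
#' weights among survivors), mutates every parameter with Gaussian noise of
#' sd `step * range` clipped to the bounds, evaluates them, and keeps the
#' best `n_pop` of parents and offspring (elitist). The step size follows a
#' 1/5-success rule. The total number of objective calls is
#' `n_initial + n_pop * (n_generations - 1)`. A failing objective scores
#' `-Inf` (with a warning) instead of aborting the run. Deterministic given
#' the config seed.
#'
#' @param objective `function(params)` taking a named list and returning a
#'   numeric fitness (larger is better); may also return a list whose first
#'   element is the fitness.
#' @param space A [search_space()].
#' @param config An [evolution_config()].
#' @return List with `best` (named parameter vector), `best_fitness`,
#'   `population` (final survivors with fitness), `evaluations` (every
#'   evaluated individual: generation, parameters, fitness), and
#'   `best_by_generation`.
#' @export
evolve <- function(objective, space, config = evolution_config()) {
  set.seed(config$seed)
  d <- nrow(space)
  rng <- space$upper - space$lower
  eval_one <- function(p) {
    val <- tryCatch(objective(as.list(stats::setNames(p, space$name))),
                    error = function(e) {
                      warning("objective failed: ", conditionMessage(e),
                              call. = FALSE)
                      -Inf
                    })
    if (is.list(val)) val <- val[[1]]
    as.numeric(val)
  }
  # generation 1
  P <- matrix(stats::runif(config$n_initial * d), ncol = d)
  P <- sweep(sweep(P, 2, rng, `*`), 2, space$lower, `+`)
  fit <- apply(P, 1, eval_one)
  evals <- data.frame(generation = 1L, P, fitness = fit)
  names(evals)[1 + seq_len(d)] <- space$name
  keep <- order(fit, decreasing = TRUE)[seq_len(min(config$n_pop, nrow(P)))]
  pop <- P[keep, , drop = FALSE]; pop_fit <- fit[keep]
  step <- config$step_init
  best_gen <- numeric(config$n_generations)
  best_gen[1] <- max(pop_fit)
  if (config$n_generations > 1) for (g in 2:config$n_generations) {
    n <- nrow(pop)
    w <- (n - rank(-pop_fit, ties.method = "first") + 1)   # linear rank weights
    parents <- sample.int(n, config$n_pop, replace = TRUE, prob = w)
    off <- matrix(NA_real_, config$n_pop, d)
    for (k in seq_len(config$n_pop)) {
      child <- pop[parents[k], ] + stats::rnorm(d, 0, step * rng)
      off[k, ] <- pmin(pmax(child, space$lower), space$upper)
    }
    off_fit <- apply(off, 1, eval_one)
    block <- data.frame(generation = g, off, fitness = off_fit)
    names(block)[1 + seq_len(d)] <- space$name
    evals <- rbind(evals, block)
    success <- mean(off_fit > pop_fit[parents])
    step <- if (is.finite(success) && success > config$success_target)
      min(step * config$step_up, config$step_max)
    else max(step * config$step_down, config$step_min)
    all_p <- rbind(pop, off); all_f <- c(pop_fit, off_fit)
    keep <- order(all_f, decreasing = TRUE)[seq_len(config$n_pop)]
    pop <- all_p[keep, , drop = FALSE]; pop_fit <- all_f[keep]
    best_gen[g] <- max(pop_fit)
  }
  best_i <- which.max(pop_fit)
  population <- data.frame(pop, fitness = pop_fit)
  names(population)[seq_len(d)] <- space$name
  list(best = stats::setNames(pop[best_i, ], space$name),
       best_fitness = pop_fit[best_i], population = population,
       evaluations = evals, best_by_generation = best_gen)
}

#' Exhaustive grid search
#'
#' Evaluates `objective` on every row of `grid` and returns the grid with a
#' `fitness` column plus any auxiliary scalar statistics the objective
#' returns (list elements after the first).
#'
#' @param objective As in [evolve()].
#' @param grid `data.frame`, one parameter per column, one evaluation per row.
#' @return `grid` with results appended.
#' @export
grid_search <- function(objective, grid) {
  res <- lapply(seq_len(nrow(grid)), function(i) {
    val <- objective(as.list(grid[i, , drop = FALSE]))
    if (!is.list(val)) val <- list(fitness = val)
    if (is.null(names(val)) || names(val)[1] == "") names(val)[1] <- "fitness"
    val
  })
  aux <- unique(unlist(lapply(res, names)))
  for (nm in aux)
    grid[[nm]] <- vapply(res, function(r) as.numeric(r[[nm]] %||% NA_real_),
                         numeric(1))
  grid
}

#' Sweep factors for one-at-a-time parameter exploration
#'
#' The multiplicative factors used to perturb one parameter around its
#' default while holding the others fixed.
#'
#' @return Numeric vector `c(0.5, 0.75, 0.9, 1.1, 1.25, 2)`.
#' @export
sweep_factors <- function() c(0.5, 0.75, 0.9, 1.1, 1.25, 2)

#' Fitness objective for fitting a model variant to reference data
#'
#' Builds a deterministic objective: for a candidate parameter set it
#' simulates `n_runs` scanpaths per scene with a fixed per-(scene, run) seed
#' schedule (common random numbers across candidates, which reduces selection
#' noise), filters the pooled events, and returns the KS-based fitness
#' against the (already filtered) reference. Scene feature maps and mask
#' indices are precomputed once and shared across evaluations.
#'
#' @param bundles A `scene_bundle` or list of them.
#' @param variant Model variant name (see [model_spec()]).
#' @param ref_table Reference event table (filtered internally).
#' @param fixed Named list of parameter overrides held fixed.
#' @param n_runs Scanpaths per scene per evaluation (default 6).
#' @param base_seed Seed of the fixed simulation-seed schedule.
#' @return `function(params)` mapping a named list of free parameters to a
#'   fitness scalar with `d_SA`/`d_FD` attributes.
#' @export
fitness_objective <- function(bundles, variant, ref_table, fixed = list(),
                              n_runs = 6L, base_seed = 99L) {
  if (inherits(bundles, "scene_bundle")) bundles <- list(bundles)
  ref <- filter_events(ref_table)
  base_spec <- do.call(model_spec, c(list(variant = variant), fixed))
  pcs <- lapply(bundles, scene_precompute, spec = base_spec)
  function(params) {
    spec <- do.call(model_spec, c(list(variant = variant), fixed, params))
    out <- list(); k <- 0L
    for (i in seq_along(bundles)) for (j in seq_len(n_runs)) {
      k <- k + 1L
      out[[k]] <- simulate_scanpath(bundles[[i]], spec,
                                    seed = derive_seed(base_seed, i * 1009L + j),
                                    run_id = j, precomp = pcs[[i]],
                                    keep_trace = FALSE)$events
    }
    fitness(filter_events(do.call(rbind, out)), ref)
  }
}

#' Parameter recovery against self-generated reference data
#'
#' Generates reference scanpaths from a model with known parameters
#' ([model_as_reference()]), fits the free parameters named in `space` with
#' [evolve()] against the KS fitness, and reports the relative error of each
#' recovered parameter.
#'
#' @param bundles A `scene_bundle` or list of them.
#' @param true_spec The generating [model_spec()] (ground truth).
#' @param space A [search_space()] over the free parameters; all other
#'   parameters are fixed at their ground-truth values.
#' @param config An [evolution_config()].
#' @param n_runs Runs per scene for both reference and candidate simulations.
#' @param ref_seed,sim_seed Seeds of the reference and of the objective's
#'   simulation schedule (kept distinct).
#' @return List with `truth`, `best`, `relative_error`, `best_fitness`, and
#'   the full [evolve()] result.
#' @export
recover_parameters <- function(bundles, true_spec, space,
                               config = evolution_config(), n_runs = 6L,
                               ref_seed = 7L, sim_seed = 99L) {
  ref <- model_as_reference(bundles, true_spec, n_runs = n_runs, seed = ref_seed)
  fixed <- true_spec[intersect(c("sigma_s", "theta", "s", "r", "sigma_i", "xi",
                                 "sigma_d"), names(true_spec))]
  fixed <- fixed[!vapply(fixed, is.null, logical(1))]
  fixed <- fixed[setdiff(names(fixed), space$name)]
  obj <- fitness_objective(bundles, true_spec$variant, ref, fixed = fixed,
                           n_runs = n_runs, base_seed = sim_seed)
  res <- evolve(obj, space, config)
  truth <- unlist(true_spec[space$name])
  rel <- abs(res$best - truth) / abs(truth)
  list(truth = truth, best = res$best, relative_error = rel,
       best_fitness = res$best_fitness, evolution = res)
}
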
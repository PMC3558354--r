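#' Genetic-algorithm configuration
#'
#' Defaults follow the reference optimization design: a population of 80
#' schedules evaluated on a cohort of 8 virtual mice for 150 generations.
#' Variation operates on the compressed vector of admissible genes only
#' (length 114 on the default grid), so every individual in every
#' generation satisfies the admissibility constraint by construction.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations to evolve.
#' @param cohort_size Virtual mice per fitness evaluation.
#' @param crossover_rate Probability that a selected parent pair undergoes
#'   uniform crossover (otherwise the children are copies).
#' @param mutation_rate Per-admissible-gene flip probability; `NULL` means
#'   `1 / (number of admissible slots)`, i.e. one expected flip per genome.
#' @param tournament_size Individuals sampled (with replacement) per
#'   tournament.
#' @param elite_count Best individuals copied unchanged into the next
#'   generation; `>= 1` makes the best fitness monotone non-decreasing.
#' @param master_seed Seed of the evolution RNG stream.  Fitness randomness
#'   comes exclusively from the cohort seeds, so the whole run is
#'   reproducible from `(master_seed, cfg, grid)` for any backend.
#' @return An object of class `vax_ga_config`.
#' @export
ga_config <- function(population_size = 80L, generations = 150L,
                      cohort_size = 8L, crossover_rate = 0.7,
                      mutation_rate = NULL, tournament_size = 2L,
                      elite_count = 1L, master_seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              cohort_size = as.integer(cohort_size),
              crossover_rate = crossover_rate,
              mutation_rate = mutation_rate,
              tournament_size = as.integer(tournament_size),
              elite_count = as.integer(elite_count),
              master_seed = as.integer(master_seed))
  if (cfg$population_size < 2) stop("population_size must be >= 2")
  if (cfg$elite_count >= cfg$population_size)
    stop("elite_count must be smaller than population_size")
  if (cfg$elite_count < 0) stop("elite_count must be >= 0")
  if (cfg$crossover_rate < 0 || cfg$crossover_rate > 1)
    stop("crossover_rate must be in [0, 1]")
  if (!is.null(cfg$mutation_rate) &&
      (cfg$mutation_rate < 0 || cfg$mutation_rate > 1))
    stop("mutation_rate must be in [0, 1]")
  if (cfg$tournament_size < 1) stop("tournament_size must be >= 1")
  if (cfg$generations < 0) stop("generations must be >= 0")
  class(cfg) <- "vax_ga_config"
  cfg
}

effective_mutation_rate <- function(cfg, grid) {
  if (!is.null(cfg$mutation_rate)) return(cfg$mutation_rate)
  k <- sum(grid$admissible)
  if (k == 0) 0 else 1 / k
}

#' Random initial population
#'
#' Each admissible gene is drawn independently as Bernoulli(1/2);
#' inadmissible slots are zero.  Uses the current R RNG stream (seeded by
#' [run_ga()] from `master_seed`).
#'
#' @param cfg A [ga_config()].
#' @param grid A [time_grid()].
#' @return List of `population_size` valid `vax_schedule`s.
#' @export
init_population <- function(cfg, grid) {
  k <- sum(grid$admissible)
  lapply(seq_len(cfg$population_size), function(i)
    schedule_from_genes(grid, stats::rbinom(k, 1L, 0.5)))
}

#' Tournament selection
#'
#' Samples `tournament_size` individuals uniformly with replacement and
#' returns the best under [compare_fitness()].
#'
#' @param population List of schedules.
#' @param fitnesses Aligned list of `vax_fitness` values.
#' @param tournament_size Number of contestants.
#' @return The selected `vax_schedule`.
#' @export
tournament_select <- function(population, fitnesses, tournament_size = 2L) {
  if (length(population) == 0) stop("cannot select from an empty population")
  idx <- sample.int(length(population), tournament_size, replace = TRUE)
  best <- idx[1]
  for (i in idx[-1]) {
    if (compare_fitness(fitnesses[[i]], fitnesses[[best]]) > 0) best <- i
  }
  population[[best]]
}

#' Uniform crossover on admissible genes
#'
#' With probability `crossover_rate`, each admissible gene of the first
#' child is taken from parent `a` or `b` with equal probability and the
#' second child takes the complementary choice; otherwise the children are
#' exact copies of the parents.  Children are always valid schedules.
#'
#' @param a,b Parent `vax_schedule`s on the same grid.
#' @param crossover_rate Probability of performing crossover.
#' @return List of two `vax_schedule`s.
#' @export
crossover <- function(a, b, crossover_rate = 0.7) {
  if (!identical(a$grid$admissible, b$grid$admissible) ||
      a$grid$N != b$grid$N)
    stop("crossover parents must share the same grid")
  ga <- genes_from_schedule(a)
  gb <- genes_from_schedule(b)
  if (stats::runif(1) < crossover_rate) {
    take_a <- stats::runif(length(ga)) < 0.5
    c1 <- ifelse(take_a, ga, gb)
    c2 <- ifelse(take_a, gb, ga)
  } else {
    c1 <- ga
    c2 <- gb
  }
  list(schedule_from_genes(a$grid, c1), schedule_from_genes(a$grid, c2))
}

#' Per-gene flip mutation
#'
#' Flips each admissible gene independently with probability
#' `mutation_rate`; inadmissible slots are untouched.
#'
#' @param s A `vax_schedule`.
#' @param mutation_rate Per-gene flip probability.
#' @return A valid mutated `vax_schedule`.
#' @export
mutate <- function(s, mutation_rate) {
  g <- genes_from_schedule(s)
  if (length(g) && mutation_rate > 0) {
    flip <- stats::runif(length(g)) < mutation_rate
    g[flip] <- 1L - g[flip]
  }
  schedule_from_genes(s$grid, g)
}

#' Produce the next generation
#'
#' Copies the `elite_count` best individuals unchanged, then fills the
#' remaining slots by tournament selection, crossover and mutation.
#'
#' @param population List of schedules.
#' @param fitnesses Aligned `vax_fitness` list.
#' @param cfg A [ga_config()].
#' @param grid The shared [time_grid()].
#' @return New population of the same size.
#' @export
evolve_generation <- function(population, fitnesses, cfg, grid) {
  mrate <- effective_mutation_rate(cfg, grid)
  ord <- order_fitness(fitnesses)
  nxt <- population[ord[seq_len(cfg$elite_count)]]
  while (length(nxt) < cfg$population_size) {
    p1 <- tournament_select(population, fitnesses, cfg$tournament_size)
    p2 <- tournament_select(population, fitnesses, cfg$tournament_size)
    kids <- crossover(p1, p2, cfg$crossover_rate)
    for (k in kids) {
      if (length(nxt) < cfg$population_size)
        nxt[[length(nxt) + 1L]] <- mutate(k, mrate)
    }
  }
  nxt
}

#' Build a simulator-backed fitness evaluator
#'
#' Returns an evaluator closure mapping a population (list of schedules)
#' to a list of `vax_fitness` values, computed by running every mouse of a
#' fixed cohort for every individual through [evaluate_population()] on the
#' given backend.  The cohort seeds are fixed for the whole optimization
#' run, so the evaluator is a pure function of the schedule.
#'
#' @param params A [sim_params()].
#' @param seeds Distinct cohort seeds (the same mice for every individual
#'   and every generation).
#' @param backend An evaluation backend, see [serial_backend()].
#' @param weights A [fitness_weights()] vector.
#' @return Function `(population) -> list of vax_fitness`.
#' @export
simulator_evaluator <- function(params, seeds, backend = serial_backend(),
                                weights = fitness_weights()) {
  force(params); force(seeds); force(backend); force(weights)
  function(population)
    evaluate_population(population, params, seeds, backend, weights)
}

#' Run the genetic algorithm
#'
#' Evolves schedules for `cfg$generations` generations: evaluate the
#' population with `evaluator`, record the best, then select/cross/mutate
#' under elitism.  All evolution randomness comes from one stream seeded
#' with `cfg$master_seed`; fitness evaluation must be deterministic (the
#' simulator evaluator re-seeds per mouse), so the history is bit-identical
#' for any backend or worker count.
#'
#' @param cfg A [ga_config()].
#' @param grid A [time_grid()].
#' @param evaluator Function `(population) -> list of vax_fitness`, e.g.
#'   from [simulator_evaluator()].
#' @return An object of class `vax_ga_history`: a list with `history` (data
#'   frame with one row per evaluated generation: `generation`,
#'   `best_scalar`, `mean_scalar`, `best_survivors`,
#'   `best_n_administrations`, `elapsed_s`), `best_schedule`,
#'   `best_fitness`.
#' @export
run_ga <- function(cfg, grid, evaluator) {
  stopifnot(inherits(cfg, "vax_ga_config"), inherits(grid, "vax_grid"))
  withr::local_seed(cfg$master_seed)
  population <- init_population(cfg, grid)
  rows <- vector("list", cfg$generations + 1L)
  best_schedule <- NULL
  best_fitness <- NULL
  for (gen in 0:cfg$generations) {
    t0 <- proc.time()[["elapsed"]]
    fits <- evaluator(population)
    ib <- which_best(fits)
    if (is.null(best_fitness) ||
        compare_fitness(fits[[ib]], best_fitness) > 0) {
      best_fitness <- fits[[ib]]
      best_schedule <- population[[ib]]
    }
    rows[[gen + 1L]] <- data.frame(
      generation = gen,
      best_scalar = best_fitness$scalar,
      mean_scalar = mean(vapply(fits, `[[`, numeric(1), "scalar")),
      best_survivors = best_fitness$survivors,
      best_n_administrations = best_fitness$n_admin,
      elapsed_s = proc.time()[["elapsed"]] - t0)
    if (gen < cfg$generations)
      population <- evolve_generation(population, fits, cfg, grid)
  }
  out <- list(history = do.call(rbind, rows),
              best_schedule = best_schedule,
              best_fitness = best_fitness,
              config = cfg)
  class(out) <- "vax_ga_history"
  out
}

#' @export
print.vax_ga_history <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<vax_ga_history> %d generations; best scalar %.4f (%s/%d protected, %d doses)\n",
    nrow(h) - 1L, x$best_fitness$scalar, x$best_fitness$survivors,
    x$best_fitness$cohort_size, x$best_fitness$n_admin))
  invisible(x)
}

#' Write a GA history CSV
#'
#' Columns: `generation`, `best_scalar`, `mean_scalar`, `best_survivors`,
#' `best_n_administrations` (per-generation timing is deliberately
#' excluded so that identical runs produce byte-identical files).
#'
#' @param ga_history A [run_ga()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ga_history <- function(ga_history, path) {
  h <- ga_history$history
  utils::write.csv(
    h[, c("generation", "best_scalar", "mean_scalar", "best_survivors",
          "best_n_administrations")],
    path, row.names = FALSE)
  invisible(path)
}
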
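test_that("initial populations are valid, sized, and seed-deterministic", {
  g <- toy_grid(20)
  cfg <- ga_config(population_size = 12L, master_seed = 3L)
  pop1 <- withr::with_seed(3L, init_population(cfg, g))
  pop2 <- withr::with_seed(3L, init_population(cfg, g))
  expect_length(pop1, 12L)
  expect_identical(pop1, pop2)
  for (s in pop1) expect_equal(nrow(validate_schedule(s)), 0L)

  g0 <- time_grid(20, 24, integer(0))
  pop0 <- withr::with_seed(1L, init_population(cfg, g0))
  expect_true(all(vapply(pop0, function(s) sum(s$x), integer(1)) == 0L))
})

test_that("tournament selection returns the best of its sample", {
  g <- time_grid(28, 24, c(0L, 3L))
  p <- toy_params(palpable_threshold = 200)
  mk <- function(n_doses) {
    x <- integer(g$N)
    if (n_doses > 0) x[which(g$admissible)[seq_len(n_doses)]] <- 1L
    new_schedule(g, x)
  }
  pop <- lapply(c(5L, 3L, 0L, 7L), mk)
  outcomes <- replicate(2, fake_result(TRUE, 0), simplify = FALSE)
  fits <- lapply(pop, function(s) fitness_from_results(outcomes, s, p))
  # fitness strictly decreases with dose count here: best is the 0-dose one

  expect_identical(withr::with_seed(1, tournament_select(pop[2], fits[2])),
                   pop[[2]])

  # tournament spanning the population always returns the global best
  for (seed in 1:10) {
    sel <- withr::with_seed(seed,
      tournament_select(pop, fits, tournament_size = 64L))
    expect_identical(sel, pop[[3]])
  }
  expect_error(tournament_select(list(), list()), "empty")
})

test_that("crossover is constraint-preserving and complementary", {
  g <- time_grid(28, 24, c(0L, 3L)) # 8 admissible genes
  adm <- which(g$admissible)
  a <- new_schedule(g, { x <- integer(g$N); x[adm] <- 1L; x })
  b <- new_schedule(g, integer(g$N))

  # identical parents -> identical children, crossover or not
  kids <- withr::with_seed(1, crossover(a, a, crossover_rate = 1))
  expect_identical(kids[[1]]$x, a$x)
  expect_identical(kids[[2]]$x, a$x)

  # rate 0 -> exact copies
  kids <- withr::with_seed(1, crossover(a, b, crossover_rate = 0))
  expect_identical(kids[[1]]$x, a$x)
  expect_identical(kids[[2]]$x, b$x)

  # complementary parents: each gene comes from exactly one parent and the
  # two children take opposite choices
  for (seed in 1:10) {
    kids <- withr::with_seed(seed, crossover(a, b, crossover_rate = 1))
    g1 <- kids[[1]]$x[adm]; g2 <- kids[[2]]$x[adm]
    expect_true(all(g1 + g2 == 1L))
    expect_equal(nrow(validate_schedule(kids[[1]])), 0L)
  }
  g2 <- time_grid(21, 24, c(0L, 3L))
  expect_error(crossover(a, new_schedule(g2, integer(g2$N))), "grid")
})

test_that("mutation flips at the configured rate", {
  g <- time_grid(50, 24, 0:6) # 50 admissible genes
  s <- new_schedule(g, integer(g$N))

  expect_identical(withr::with_seed(1, mutate(s, 0))$x, s$x)
  expect_identical(withr::with_seed(1, mutate(s, 1))$x,
                   as.integer(g$admissible))

  # rate 1/L: total flips over trials ~ Binomial(trials * L, 1/L)
  trials <- 2000L
  flips <- withr::with_seed(7, {
    sum(vapply(seq_len(trials), function(i) sum(mutate(s, 1 / 50)$x),
               numeric(1)))
  })
  expected <- trials
  se <- sqrt(trials * 50 * (1 / 50) * (49 / 50))
  expect_lt(abs(flips - expected), 3 * se)
})

test_that("generations preserve size, validity and the elite", {
  g <- toy_grid(20)
  cfg <- ga_config(population_size = 10L, tournament_size = 2L,
                   crossover_rate = 0.7, elite_count = 1L)
  target <- withr::with_seed(5, rbinom(log2_search_space(g), 1L, 0.5))
  evalr <- target_evaluator(g, target)
  pop <- withr::with_seed(2, init_population(cfg, g))
  fits <- evalr(pop)
  best <- pop[[which.max(vapply(fits, `[[`, numeric(1), "scalar"))]]

  nxt <- withr::with_seed(3, evolve_generation(pop, fits, cfg, g))
  expect_length(nxt, 10L)
  for (s in nxt) expect_equal(nrow(validate_schedule(s)), 0L)
  expect_true(any(vapply(nxt, function(s) identical(s$x, best$x),
                         logical(1))))

  # selection-only evolution returns a multiset drawn from the parents
  cfg0 <- ga_config(population_size = 10L, crossover_rate = 0,
                    mutation_rate = 0, elite_count = 1L)
  nxt0 <- withr::with_seed(4, evolve_generation(pop, fits, cfg0, g))
  parents <- vapply(pop, function(s) paste(s$x, collapse = ""), character(1))
  expect_true(all(vapply(nxt0, function(s) paste(s$x, collapse = ""),
                         character(1)) %in% parents))

  # forced selection pressure: tournaments covering the population plus
  # no variation -> every non-elite slot is the best parent
  cfgT <- ga_config(population_size = 10L, crossover_rate = 0,
                    mutation_rate = 0, tournament_size = 64L,
                    elite_count = 1L)
  nxtT <- withr::with_seed(5, evolve_generation(pop, fits, cfgT, g))
  for (s in nxtT) expect_identical(s$x, best$x)
})

test_that("the GA finds the optimum of a matching-target surrogate", {
  g <- time_grid(50, 24, 0:6) # 50-gene space
  target <- withr::with_seed(99, rbinom(50, 1L, 0.5))
  evalr <- target_evaluator(g, target)
  hits <- 0L
  for (seed in 1:10) {
    cfg <- ga_config(population_size = 40L, generations = 100L,
                     master_seed = seed)
    h <- run_ga(cfg, g, evalr)
    expect_true(all(diff(h$history$best_scalar) >= 0)) # elitism
    if (h$best_fitness$scalar == 50) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("run_ga histories are reproducible and degenerate cases work", {
  g <- toy_grid(20)
  target <- withr::with_seed(1, rbinom(log2_search_space(g), 1L, 0.5))
  evalr <- target_evaluator(g, target)

  cfg0 <- ga_config(population_size = 6L, generations = 0L, master_seed = 2L)
  h0 <- run_ga(cfg0, g, evalr)
  expect_equal(nrow(h0$history), 1L)

  cfg <- ga_config(population_size = 8L, generations = 12L, master_seed = 2L)
  h1 <- run_ga(cfg, g, evalr)
  h2 <- run_ga(cfg, g, evalr)
  expect_identical(h1$history[names(h1$history) != "elapsed_s"],
                   h2$history[names(h2$history) != "elapsed_s"])
  expect_identical(h1$best_schedule, h2$best_schedule)
  expect_equal(nrow(h1$history), 13L)
})
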
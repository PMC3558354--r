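# Shared toy fixtures: a small lattice and a short horizon keep individual
# simulator runs in the millisecond range.

toy_grid <- function(T_days = 20) {
  time_grid(T_days, 24, c(0L, 3L), start_weekday = 4L)
}

toy_params <- function(...) {
  args <- list(lattice_side = 16L, horizon_steps = 60L,
               palpable_threshold = 200,
               baseline = c(B = 30L, Th = 30L, Tc = 30L, NK = 10L, DC = 20L),
               vaccine_dose = 10L)
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# a fake per-mouse outcome, for arithmetic checks of the fitness layer
fake_result <- function(survived, peak_burden, seed = 0L) {
  list(seed = seed, survived = survived, peak_burden = peak_burden)
}

# surrogate evaluator: fitness = number of admissible genes matching a
# hidden target bitstring (a OneMax-style landscape with known optimum)
target_evaluator <- function(grid, target) {
  force(grid); force(target)
  function(population) {
    lapply(population, function(s) {
      g <- s$x[grid$admissible]
      matches <- sum(g == target)
      f <- list(survivors = as.numeric(matches), cohort_size = 1L,
                burden_penalty = 0, dose_penalty = 0,
                n_admin = as.numeric(sum(s$x)),
                scalar = as.numeric(matches),
                weights = fitness_weights(),
                genome = paste(g, collapse = ""))
      class(f) <- "vax_fitness"
      f
    })
  }
}
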
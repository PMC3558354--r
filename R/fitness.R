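#' Fitness weights
#'
#' The cohort fitness is the scalar
#' `w1 * survivors - w2 * burden_penalty - w3 * dose_penalty`.
#' With the default weights (10, 1, 1) protection lexicographically
#' dominates: since both penalties lie in \[0, 1\], `w1 > w2 + w3`
#' guarantees that any schedule protecting more mice outranks any schedule
#' protecting fewer, whatever their penalties.
#'
#' @param w1 Weight of the survivor count.
#' @param w2 Weight of the mean (capped) peak tumor burden.
#' @param w3 Weight of the administration-count penalty.
#' @return Named numeric vector of validated weights.
#' @export
fitness_weights <- function(w1 = 10, w2 = 1, w3 = 1) {
  if (any(c(w1, w2, w3) < 0)) stop("fitness weights must be non-negative")
  if (w1 <= w2 + w3)
    stop("survivor dominance requires w1 > w2 + w3")
  c(w1 = w1, w2 = w2, w3 = w3)
}

#' Aggregate cohort outcomes into a fitness value
#'
#' Computes, from per-mouse results: `survivors` (mice never reaching the
#' palpable threshold), `burden_penalty` (mean over mice of
#' `min(peak_burden / threshold, 1)`), `dose_penalty` (administration count
#' divided by the number of admissible slots) and the combined scalar.
#'
#' @param results List of [run_mouse()] results (anything with `survived`
#'   and `peak_burden` fields).
#' @param schedule The evaluated `vax_schedule`.
#' @param params The [sim_params()] used (supplies the threshold).
#' @param weights A [fitness_weights()] vector.
#' @return An object of class `vax_fitness` with fields `survivors`,
#'   `cohort_size`, `burden_penalty`, `dose_penalty`, `scalar`, `n_admin`
#'   and `genome` (the admissible-slot bitstring, used as a deterministic
#'   tie-break).
#' @export
fitness_from_results <- function(results, schedule, params,
                                 weights = fitness_weights()) {
  stopifnot(inherits(schedule, "vax_schedule"))
  n_adm <- sum(schedule$grid$admissible)
  n <- count_administrations(schedule)
  survivors <- sum(vapply(results, function(r) isTRUE(r$survived), logical(1)))
  burden <- if (length(results) == 0) 0 else
    mean(vapply(results, function(r)
      min(r$peak_burden / params$palpable_threshold, 1), numeric(1)))
  dose <- if (n_adm == 0) 0 else n / n_adm
  f <- list(survivors = as.numeric(survivors),
            cohort_size = length(results),
            burden_penalty = burden,
            dose_penalty = dose,
            n_admin = as.numeric(n),
            scalar = unname(weights["w1"] * survivors -
                              weights["w2"] * burden -
                              weights["w3"] * dose),
            weights = weights,
            genome = paste(genes_from_schedule(schedule), collapse = ""))
  class(f) <- "vax_fitness"
  f
}

#' Evaluate a schedule on a cohort of virtual mice
#'
#' Runs [run_cohort()] and aggregates the outcomes with
#' [fitness_from_results()].  Pure function of `(schedule, params, seeds,
#' weights)`.
#'
#' @inheritParams run_cohort
#' @param weights A [fitness_weights()] vector.
#' @return A `vax_fitness` value.
#' @export
evaluate_schedule <- function(schedule, params, seeds,
                              weights = fitness_weights()) {
  results <- run_cohort(params, schedule, seeds)
  fitness_from_results(results, schedule, params, weights)
}

#' @export
print.vax_fitness <- function(x, ...) {
  cat(sprintf(
    "<vax_fitness> scalar %.4f: %d/%d protected, burden %.3f, %d doses\n",
    x$scalar, x$survivors, x$cohort_size, x$burden_penalty, x$n_admin))
  invisible(x)
}

#' Total order on fitness values
#'
#' Orders by the combined scalar; exact ties are broken by more survivors,
#' then lower dose penalty, then lower burden penalty, then
#' lexicographically smaller genome, so the order (and hence the whole
#' genetic algorithm) is fully deterministic.
#'
#' @param a,b `vax_fitness` values with identical weights and cohort sizes.
#' @return `-1`, `0` or `1` as `a` is worse than, equivalent to, or better
#'   than `b`.
#' @export
compare_fitness <- function(a, b) {
  stopifnot(inherits(a, "vax_fitness"), inherits(b, "vax_fitness"))
  if (a$cohort_size != b$cohort_size)
    stop("cannot compare fitness values from different cohort sizes")
  if (!isTRUE(all.equal(a$weights, b$weights)))
    stop("cannot compare fitness values computed with different weights")
  key <- function(f) c(f$scalar, f$survivors, -f$dose_penalty,
                       -f$burden_penalty)
  ka <- key(a); kb <- key(b)
  for (i in seq_along(ka)) {
    if (ka[i] > kb[i]) return(1L)
    if (ka[i] < kb[i]) return(-1L)
  }
  # deterministic final tie-break on the genome bitstring
  if (a$genome < b$genome) return(1L)
  if (a$genome > b$genome) return(-1L)
  0L
}

# index of the best fitness in a list (ties resolved by compare_fitness)
which_best <- function(fitnesses) {
  best <- 1L
  for (i in seq_along(fitnesses)[-1]) {
    if (compare_fitness(fitnesses[[i]], fitnesses[[best]]) > 0) best <- i
  }
  best
}

# decreasing order of a fitness list under compare_fitness
order_fitness <- function(fitnesses) {
  idx <- seq_along(fitnesses)
  keys <- lapply(fitnesses, function(f)
    list(-f$scalar, -f$survivors, f$dose_penalty, f$burden_penalty, f$genome))
  idx[order(vapply(keys, `[[`, numeric(1), 1),
            vapply(keys, `[[`, numeric(1), 2),
            vapply(keys, `[[`, numeric(1), 3),
            vapply(keys, `[[`, numeric(1), 4),
            vapply(keys, `[[`, character(1), 5))]
}

#' Per-individual fitness report
#'
#' @param fitnesses List of `vax_fitness` values for one generation.
#' @return Data frame with columns `individual_id`, `survivors`,
#'   `burden_penalty`, `dose_penalty`, `scalar`, `n_administrations`.
#' @export
fitness_report <- function(fitnesses) {
  data.frame(
    individual_id = seq_along(fitnesses),
    survivors = vapply(fitnesses, `[[`, numeric(1), "survivors"),
    burden_penalty = vapply(fitnesses, `[[`, numeric(1), "burden_penalty"),
    dose_penalty = vapply(fitnesses, `[[`, numeric(1), "dose_penalty"),
    scalar = vapply(fitnesses, `[[`, numeric(1), "scalar"),
    n_administrations = vapply(fitnesses, `[[`, numeric(1), "n_admin")
  )
}
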
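#' Per-generation task list
#'
#' One task per (individual, mouse) pair, row-major by individual then
#' mouse: with a population of 80 and a cohort of 8 mice a generation
#' comprises 640 simulator runs.
#'
#' @param population_size Number of individuals `P`.
#' @param seeds Cohort seeds (one mouse each).
#' @return Data frame with columns `task_id`, `individual`, `mouse`,
#'   `seed`.
#' @export
build_tasks <- function(population_size, seeds) {
  stopifnot(population_size >= 1, length(seeds) >= 1)
  m <- length(seeds)
  data.frame(
    task_id = seq_len(population_size * m),
    individual = rep(seq_len(population_size), each = m),
    mouse = rep(seq_len(m), times = population_size),
    seed = rep(as.integer(seeds), times = population_size)
  )
}

#' Static block partition of tasks over workers
#'
#' Assigns every task to exactly one worker so that chunk sizes differ by
#' at most one (workers beyond the task count stay idle).
#'
#' @param n_tasks Number of tasks.
#' @param workers Number of workers `c >= 1`.
#' @return Integer vector of length `n_tasks`: the worker (1-based) of each
#'   task.
#' @export
partition_tasks <- function(n_tasks, workers) {
  stopifnot(workers >= 1)
  if (n_tasks == 0) return(integer(0))
  base <- n_tasks %/% workers
  extra <- n_tasks %% workers
  sizes <- rep(base, workers) + c(rep(1L, extra), rep(0L, workers - extra))
  rep(seq_len(workers), times = sizes)
}

#' Evaluation backends
#'
#' A backend executes the per-generation task list and returns the
#' per-task mouse results to the master, which aggregates them into
#' fitness values.  Because every task re-seeds its own RNG stream from
#' its mouse seed, all backends return bit-identical results for every
#' worker count:
#'
#' * `serial_backend()` — the reference implementation (plain `lapply`).
#' * `multicore_backend(workers)` — fork-based parallel evaluation via
#'   [parallel::mclapply()]; emulates the master/worker cycle
#'   (broadcast population, workers run their static chunk, master
#'   gathers).
#' * `scripted_backend(workers, gather_order)` — serial execution that
#'   returns the gathered results in a permuted completion order; used to
#'   verify that the master's aggregation is order-independent.
#'
#' @param workers Worker count.
#' @param gather_order `"reverse"`, `"shuffle"`, or an explicit permutation
#'   of the task indices.
#' @return A backend object (class `vax_backend`).
#' @export
serial_backend <- function() {
  structure(list(type = "serial", workers = 1L), class = "vax_backend")
}

#' @rdname serial_backend
#' @export
multicore_backend <- function(workers = 2L) {
  stopifnot(workers >= 1)
  structure(list(type = "multicore", workers = as.integer(workers)),
            class = "vax_backend")
}

#' @rdname serial_backend
#' @export
scripted_backend <- function(workers = 1L, gather_order = "reverse") {
  structure(list(type = "scripted", workers = as.integer(workers),
                 gather_order = gather_order),
            class = "vax_backend")
}

# Execute tasks on a backend; returns a list of (task_id, value) pairs in
# backend-dependent completion order.
backend_run <- function(backend, tasks, run_one) {
  n <- nrow(tasks)
  eval_range <- function(idx) {
    lapply(idx, function(i) list(task_id = tasks$task_id[i],
                                 value = run_one(i)))
  }
  if (backend$type == "serial") {
    return(eval_range(seq_len(n)))
  }
  if (backend$type == "multicore") {
    assign_to <- partition_tasks(n, backend$workers)
    chunks <- split(seq_len(n), assign_to)
    gathered <- parallel::mclapply(chunks, eval_range,
                                   mc.cores = backend$workers,
                                   mc.set.seed = FALSE)
    err <- vapply(gathered, function(g) inherits(g, "try-error"), logical(1))
    if (any(err))
      stop("worker failure during population evaluation")
    return(do.call(c, unname(gathered)))
  }
  if (backend$type == "scripted") {
    out <- eval_range(seq_len(n))
    ord <- backend$gather_order
    if (identical(ord, "reverse")) {
      out <- rev(out)
    } else if (identical(ord, "shuffle")) {
      out <- out[withr::with_seed(0L, sample.int(n))]
    } else {
      out <- out[ord]
    }
    return(out)
  }
  stop("unknown backend type: ", backend$type)
}

#' Evaluate a population of schedules on a cohort
#'
#' The master-worker evaluation cycle: build the `P x M` task list,
#' partition it over the backend's workers, run every (individual, mouse)
#' simulation, gather the per-task results, and aggregate them per
#' individual into fitness values.  The per-task seeding discipline makes
#' the output bit-identical across backends, worker counts and gather
#' orders.
#'
#' @param population List of `vax_schedule`s.
#' @param params A [sim_params()].
#' @param seeds Distinct cohort seeds.
#' @param backend A backend from [serial_backend()] and friends.
#' @param weights A [fitness_weights()] vector.
#' @return List of `vax_fitness`, aligned with `population`.
#' @export
evaluate_population <- function(population, params, seeds,
                                backend = serial_backend(),
                                weights = fitness_weights()) {
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop("cohort seeds must be distinct")
  tasks <- build_tasks(length(population), seeds)
  run_one <- function(i) {
    run_mouse(params, population[[tasks$individual[i]]], tasks$seed[i])
  }
  gathered <- backend_run(backend, tasks, run_one)
  # master: reorder by task id, then aggregate per individual
  values <- vector("list", nrow(tasks))
  for (g in gathered) values[[g$task_id]] <- g$value
  if (any(vapply(values, is.null, logical(1))))
    stop("backend dropped task(s): ",
         paste(which(vapply(values, is.null, logical(1))), collapse = ", "))
  m <- length(seeds)
  lapply(seq_along(population), function(j) {
    results <- values[tasks$individual == j]
    fitness_from_results(results, population[[j]], params, weights)
  })
}

#' Analytic cost model of one master-worker generation
#'
#' The per-generation wall time decomposes into the serial master work
#' (evolution of the population), the synchronization overhead, and the
#' parallel fitness phase, whose span under static block partitioning is
#' `ceil(P * M / c)` simulator runs:
#'
#' `T_g(c) = T_master(P) + T_sync(c) + ceil(P * M / c) * T_fit`
#'
#' With enough workers (`c >= P * M`) the fitness span is a single run and
#' `T_g` plateaus at `T_master(P) + T_sync(c) + T_fit`: the serial master
#' work bounds the achievable speedup, and the plateau grows with the
#' population size.  Absolute wall-clock values are hardware-dependent;
#' the model reproduces the structure (linear regime, plateau, master-time
#' growth), not published minutes.
#'
#' @param T_fit Seconds per simulator run.
#' @param master_alpha Serial master seconds per individual
#'   (`T_master(P) = master_alpha * P`, an operation-count proxy).
#' @param sync_const,sync_log Synchronization overhead
#'   `T_sync(c) = sync_const + sync_log * log2(c)` in seconds.
#' @return An object of class `vax_cost_model`.
#' @export
cost_model_params <- function(T_fit = 30, master_alpha = 0.5,
                              sync_const = 1, sync_log = 0.25) {
  stopifnot(T_fit >= 0, master_alpha >= 0, sync_const >= 0, sync_log >= 0)
  structure(list(T_fit = T_fit, master_alpha = master_alpha,
                 sync_const = sync_const, sync_log = sync_log),
            class = "vax_cost_model")
}

#' @rdname cost_model_params
#' @param cm A `vax_cost_model`.
#' @param P Population size.
#' @param M Cohort size.
#' @param workers Worker count `c >= 1` (vectorized).
#' @return `predict_generation_time()`: predicted `T_g` in seconds.
#' @export
predict_generation_time <- function(cm, P, M, workers) {
  stopifnot(inherits(cm, "vax_cost_model"), all(workers >= 1))
  T_master <- cm$master_alpha * P
  T_sync <- cm$sync_const + cm$sync_log * log2(workers)
  T_master + T_sync + ceiling(P * M / workers) * cm$T_fit
}

#' Total serial runtime of a full optimization
#'
#' A single-CPU run needs one simulator execution per mouse, individual
#' and generation: `M * P * G * T_fit` seconds.  With the reference
#' constants (8 mice, 80 individuals, 150 generations, 30 s per run) that
#' is 2,880,000 s, i.e. about a month of compute.
#'
#' @param M Cohort size.
#' @param P Population size.
#' @param G Generations.
#' @param T_fit Seconds per simulator run.
#' @return Seconds.
#' @export
estimate_total_runtime <- function(M, P, G, T_fit) {
  stopifnot(M >= 1, P >= 1, G >= 1, T_fit > 0)
  M * P * G * T_fit
}
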
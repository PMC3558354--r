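#' Simulator parameters for the virtual mouse
#'
#' Assembles the parameter set of the lattice agent-based model: a toroidal
#' square lattice on which immune cells (B, T helper, cytotoxic T, natural
#' killer, dendritic), vaccine cells, antigen and antibody molecules and
#' tumor cells move and interact site-locally.  Recognition between a
#' receptor and an epitope (both `receptor_len`-bit strings) uses the
#' complementarity convention: with Hamming distance `m`, the binding
#' probability is `0` below `min_match` and `affinity_base^(receptor_len -
#' m)` otherwise, reaching 1 for a perfect complement.  Carcinogenesis is
#' continuous: `tumor_birth` newborn tumor cells appear at random sites
#' every step and every existing tumor cell duplicates with probability
#' `p_dup`; the run stops when the tumor-cell count reaches
#' `palpable_threshold`.  A vaccine administration injects `vaccine_dose`
#' cells carrying the tumor-associated antigen plus an allogeneic signal
#' (tolerance is broken by relaxing the match threshold by `allo_relax`
#' bits) and deposits IL-12, which multiplies activation probabilities by
#' `1 + il12_boost * local_field` and decays by `il12_decay` per step.
#'
#' Defaults describe a 400-day run at 3 steps per day (8-hour steps) on a
#' 32 x 32 lattice, calibrated so that untreated mice typically develop a
#' palpable tumor within a few months while the chronic reference protocol
#' protects most mice over the full horizon.
#'
#' @param lattice_side Lattice side length (sites).
#' @param receptor_len Receptor/epitope length in bits (<= 30).
#' @param min_match Minimum Hamming distance for specific recognition.
#' @param affinity_base Base `c` of the affinity function, in (0, 1].
#' @param step_hours Hours of simulated time per step; must divide 24.
#' @param horizon_steps Total steps to simulate.
#' @param tumor_birth Newborn tumor cells seeded per step.
#' @param p_dup Tumor duplication probability per cell per step.
#' @param palpable_threshold Tumor-cell count at which the mouse is scored
#'   unprotected and the run stops.
#' @param baseline Named integer vector `c(B=, Th=, Tc=, NK=, DC=)` of
#'   homeostatic immune population sizes.
#' @param p_aspecific Probability of aspecific (non-receptor-mediated)
#'   encounters: dendritic antigen uptake, T-helper help, NK attack on
#'   vaccine cells.
#' @param nk_kill NK aspecific kill probability against a co-located tumor
#'   cell.
#' @param il12_boost Multiplier weight of the local IL-12 field on
#'   activation probabilities.
#' @param il12_decay Fraction of the IL-12 field lost per step.
#' @param il12_deposit IL-12 deposited per injected vaccine cell.
#' @param vaccine_dose Vaccine cells injected per administration.
#' @param ab_burst Antibodies secreted per successful B-cell recognition.
#' @param ag_burst Antigen particles released per cleared vaccine cell.
#' @param allo_relax Bits by which the allogeneic vaccine relaxes the
#'   T-helper match threshold.
#' @param max_expansion Clonal carrying capacity: no immune class grows by
#'   division beyond `max_expansion * baseline` cells.
#' @param lifespan Named integer vector of per-class lifespans in steps
#'   (`B`, `Th`, `Tc`, `NK`, `DC`, `VC` vaccine cells, `TU` tumor —
#'   ignored, tumor cells are immortal —, `AG` antigen, `AB` antibody).
#' @param taa_epitope Integer bit pattern of the tumor-associated antigen
#'   epitope.
#' @return An object of class `vax_params` (a validated named list).
#' @export
sim_params <- function(lattice_side = 32L,
                       receptor_len = 12L,
                       min_match = 9L,
                       affinity_base = 0.3,
                       step_hours = 8L,
                       horizon_steps = 1200L,
                       tumor_birth = 1L,
                       p_dup = 0.012,
                       palpable_threshold = 1000,
                       baseline = c(B = 150L, Th = 150L, Tc = 150L,
                                    NK = 50L, DC = 100L),
                       p_aspecific = 0.5,
                       nk_kill = 0.05,
                       il12_boost = 2.0,
                       il12_decay = 0.1,
                       il12_deposit = 1.0,
                       vaccine_dose = 50L,
                       ab_burst = 6L,
                       ag_burst = 10L,
                       allo_relax = 2L,
                       max_expansion = 10,
                       lifespan = c(B = 120L, Th = 120L, Tc = 120L,
                                    NK = 120L, DC = 120L, VC = 9L,
                                    TU = 0L, AG = 30L, AB = 60L),
                       taa_epitope = 2730L) {
  p <- list(lattice_side = as.integer(lattice_side),
            receptor_len = as.integer(receptor_len),
            min_match = as.integer(min_match),
            affinity_base = affinity_base,
            step_hours = as.integer(step_hours),
            horizon_steps = as.integer(horizon_steps),
            tumor_birth = as.integer(tumor_birth),
            p_dup = p_dup,
            palpable_threshold = palpable_threshold,
            baseline = vapply(c("B", "Th", "Tc", "NK", "DC"),
                              function(k) as.integer(baseline[[k]]),
                              integer(1)),
            p_aspecific = p_aspecific,
            nk_kill = nk_kill,
            il12_boost = il12_boost,
            il12_decay = il12_decay,
            il12_deposit = il12_deposit,
            vaccine_dose = as.integer(vaccine_dose),
            ab_burst = as.integer(ab_burst),
            ag_burst = as.integer(ag_burst),
            allo_relax = as.integer(allo_relax),
            max_expansion = max_expansion,
            lifespan = vapply(c("B", "Th", "Tc", "NK", "DC",
                                "VC", "TU", "AG", "AB"),
                              function(k) as.integer(lifespan[[k]]),
                              integer(1)),
            taa_epitope = as.integer(taa_epitope))
  validate_sim_params(p)
  class(p) <- "vax_params"
  p
}

validate_sim_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop("invalid sim_params: ", msg)
  chk(p$lattice_side >= 2, "lattice_side must be >= 2")
  chk(p$receptor_len >= 1 && p$receptor_len <= 30,
      "receptor_len must be in 1..30")
  chk(p$min_match >= 0 && p$min_match <= p$receptor_len,
      "min_match must lie in 0..receptor_len")
  chk(p$affinity_base > 0 && p$affinity_base <= 1,
      "affinity_base must be in (0, 1]")
  chk(p$step_hours >= 1 && 24 %% p$step_hours == 0,
      "step_hours must divide 24")
  chk(p$horizon_steps >= 1, "horizon_steps must be >= 1")
  chk(p$tumor_birth >= 0, "tumor_birth must be >= 0")
  chk(p$p_dup >= 0 && p$p_dup <= 1, "p_dup must be in [0, 1]")
  chk(p$p_aspecific >= 0 && p$p_aspecific <= 1,
      "p_aspecific must be in [0, 1]")
  chk(p$nk_kill >= 0 && p$nk_kill <= 1, "nk_kill must be in [0, 1]")
  chk(p$palpable_threshold > 0, "palpable_threshold must be > 0")
  chk(all(p$baseline >= 0), "baseline counts must be >= 0")
  chk(p$il12_decay >= 0 && p$il12_decay <= 1, "il12_decay must be in [0, 1]")
  chk(p$vaccine_dose >= 0, "vaccine_dose must be >= 0")
  chk(p$max_expansion >= 1, "max_expansion must be >= 1")
  invisible(TRUE)
}

#' @export
print.vax_params <- function(x, ...) {
  cat(sprintf(
    "<vax_params> %dx%d lattice, %d steps (%g days at %d h/step), theta = %g\n",
    x$lattice_side, x$lattice_side, x$horizon_steps,
    x$horizon_steps * x$step_hours / 24, x$step_hours,
    x$palpable_threshold))
  invisible(x)
}

#' Receptor-epitope binding affinity
#'
#' Implements the complementarity (lock-and-key) affinity: with `m` the
#' Hamming distance between the two bitstrings, the affinity is `0` for
#' `m < min_match` and `affinity_base^(receptor_len - m)` otherwise, so a
#' perfect complement (`m == receptor_len`) binds with probability 1.
#'
#' @param receptor,epitope Bitstrings of length `params$receptor_len`,
#'   given either as character strings of 0/1 or as 0/1 integer vectors.
#' @param params A [sim_params()] object.
#' @return Binding probability in \[0, 1\].
#' @examples
#' p <- sim_params(receptor_len = 12, min_match = 10, affinity_base = 0.3)
#' affinity("000000000000", "111111111111", p) # perfect complement -> 1
#' affinity("000000000001", "111111111111", p) # m = 11 -> 0.3
#' @export
affinity <- function(receptor, epitope, params) {
  to_bits <- function(b) {
    if (is.character(b)) as.integer(strsplit(b, "")[[1]]) else as.integer(b)
  }
  r <- to_bits(receptor)
  e <- to_bits(epitope)
  if (length(r) != params$receptor_len || length(e) != params$receptor_len)
    stop("receptor and epitope must both have length receptor_len = ",
         params$receptor_len)
  m <- sum(r != e)
  if (m < params$min_match) return(0)
  params$affinity_base^(params$receptor_len - m)
}

# Attach the R RNG stream snapshot to a simulator state so that stepping is
# a pure function of the state object.
capture_rng <- function(state) {
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

restore_rng <- function(state) {
  assign(".Random.seed", state$rng, envir = globalenv())
}

strip_rng <- function(state) {
  s <- unclass(state)
  s$rng <- NULL
  s
}

#' Initialize a virtual-mouse simulation state
#'
#' Places the baseline immune populations uniformly at random on the
#' lattice with random receptors; no tumor cells, no IL-12.  The state
#' carries its own RNG stream (derived deterministically from `seed`), so
#' [sim_step()] is a pure function of the state and the same seed always
#' reproduces the same mouse.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed identifying the virtual mouse.
#' @return An object of class `vax_state`.
#' @export
init_state <- function(params, seed) {
  stopifnot(inherits(params, "vax_params"))
  state <- withr::with_seed(as.integer(seed), {
    st <- cpp_init_state(unclass(params))
    capture_rng(st)
  })
  class(state) <- "vax_state"
  state
}

#' Inject one vaccine administration into a state
#'
#' Adds `vaccine_dose` vaccine cells (carrying the tumor-associated antigen
#' and the allogeneic signal) at uniformly random sites and deposits
#' `il12_deposit` units of IL-12 at each.
#'
#' @param state A `vax_state`.
#' @param params The matching [sim_params()].
#' @return The updated `vax_state`.
#' @export
inject_vaccine <- function(state, params) {
  stopifnot(inherits(state, "vax_state"), inherits(params, "vax_params"))
  out <- withr::with_preserve_seed({
    restore_rng(state)
    capture_rng(cpp_inject(strip_rng(state), unclass(params)))
  })
  class(out) <- "vax_state"
  out
}

#' Advance a simulation state by one step
#'
#' Applies the step phases in fixed order: vaccination (when
#' `schedule_bit == 1` and the state is at the first step of a day),
#' movement, randomized site-local interactions, ageing and homeostatic
#' replenishment, tumor seeding and duplication, IL-12 decay, and the
#' palpable-tumor stopping rule.
#'
#' @param state A `vax_state` that has not stopped.
#' @param schedule_bit 0/1: whether the current day carries an
#'   administration.
#' @param params The matching [sim_params()].
#' @return The updated `vax_state`.
#' @export
sim_step <- function(state, schedule_bit, params) {
  stopifnot(inherits(state, "vax_state"), inherits(params, "vax_params"))
  if (isTRUE(state$stopped))
    stop("cannot step a stopped simulation state")
  out <- withr::with_preserve_seed({
    restore_rng(state)
    capture_rng(cpp_step(strip_rng(state), unclass(params),
                         as.integer(schedule_bit)))
  })
  class(out) <- "vax_state"
  out
}

#' Tumor-cell count of a state
#' @param state A `vax_state`.
#' @return Integer number of tumor cells.
#' @export
tumor_count <- function(state) {
  length(state$agents$TU$site)
}

# Map schedule slots to per-day administration bits over the simulated
# horizon.  Errors if the grid horizon disagrees with the simulated one.
dose_days_from_schedule <- function(schedule, params) {
  grid <- schedule$grid
  n_days <- params$horizon_steps %/% (24L %/% params$step_hours)
  if (grid$T_days * 24 != params$horizon_steps * params$step_hours)
    stop("schedule grid horizon (", grid$T_days, " days) is inconsistent ",
         "with the simulated horizon (",
         params$horizon_steps * params$step_hours / 24, " days)")
  day <- floor(grid$slot_times / 24)
  dose <- integer(n_days)
  on_days <- unique(day[schedule$x == 1L])
  dose[on_days + 1L] <- 1L
  dose
}

#' Simulate one virtual mouse
#'
#' Runs the full agent-based simulation of one mouse under a vaccination
#' schedule.  The mouse is entirely determined by `(params, schedule,
#' seed)`: two calls with identical arguments return identical results,
#' regardless of what else has used the R RNG (the caller's RNG state is
#' preserved).
#'
#' @param params A [sim_params()] object.
#' @param schedule A `vax_schedule` whose grid spans the same horizon as
#'   `params$horizon_steps`.
#' @param seed Integer seed: the identity of the virtual mouse.
#' @return An object of class `vax_mouse_result` with fields `seed`,
#'   `survived` (no palpable tumor before the horizon), `survival_step`
#'   (first step at which the tumor count reached the threshold, or the
#'   horizon), `survival_day`, `peak_burden`, `trajectory` (a data frame
#'   with one row per simulated day: `day`, `tumor_cells`, `B`, `Th`, `Tc`,
#'   `NK`, `DC`, `antibodies`, `vaccine_cells`, `il12_total`), `counters`
#'   (tumor-cell ledger) and `final_counts`.
#' @export
run_mouse <- function(params, schedule, seed) {
  stopifnot(inherits(params, "vax_params"), inherits(schedule, "vax_schedule"))
  v <- validate_schedule(schedule)
  if (nrow(v) > 0)
    stop("invalid schedule: ", v$reason[1])
  dose <- dose_days_from_schedule(schedule, params)
  raw <- withr::with_seed(as.integer(seed),
                          cpp_run_mouse(unclass(params), dose))
  fin <- raw$final_state
  steps_per_day <- 24L %/% params$step_hours
  res <- list(
    seed = as.integer(seed),
    survived = raw$survived,
    survival_step = raw$survival_step,
    survival_day = raw$survival_step / steps_per_day,
    peak_burden = raw$peak_burden,
    trajectory = raw$trajectory,
    counters = fin$counters,
    final_counts = vapply(fin$agents, function(a) length(a$site), integer(1))
  )
  class(res) <- "vax_mouse_result"
  res
}

#' @export
print.vax_mouse_result <- function(x, ...) {
  cat(sprintf(
    "<vax_mouse_result> seed %d: %s (day %.1f), peak burden %g tumor cells\n",
    x$seed, if (x$survived) "protected" else "palpable tumor",
    x$survival_day, x$peak_burden))
  invisible(x)
}

#' Simulate a cohort of virtual mice
#'
#' Runs one independent simulation per seed under the same schedule.  Each
#' mouse carries its own RNG stream derived from its seed, so results do
#' not depend on evaluation order or on any parallel execution topology.
#'
#' @param params A [sim_params()] object.
#' @param schedule A `vax_schedule`.
#' @param seeds Distinct integer seeds, one per mouse.
#' @return List of [run_mouse()] results, aligned with `seeds`.
#' @export
run_cohort <- function(params, schedule, seeds) {
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds))
    stop("cohort seeds must be distinct")
  lapply(seeds, function(s) run_mouse(params, schedule, s))
}

#' Write a trajectory CSV
#'
#' One row per simulated day with columns `day`, `tumor_cells`, `B`, `Th`,
#' `Tc`, `NK`, `DC`, `antibodies`, `vaccine_cells`, `il12_total`.
#'
#' @param result A [run_mouse()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  utils::write.csv(result$trajectory, path, row.names = FALSE)
  invisible(path)
}
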
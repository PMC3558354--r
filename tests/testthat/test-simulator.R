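test_that("affinity follows the complementarity convention", {
  p <- sim_params(receptor_len = 12L, min_match = 10L, affinity_base = 0.3)
  expect_equal(affinity("000000000000", "111111111111", p), 1.0)
  expect_equal(affinity(rep(0L, 12), rep(0L, 12), p), 0.0) # m = 0 < m_min
  # m = 11: one matching bit
  expect_equal(affinity("100000000000", "011111111110", p), 0.3)
  # m = 10 -> c^2; m = 9 -> sub-threshold
  expect_equal(affinity("110000000000", "111111111111", p), 0.09)
  expect_equal(affinity("111000000000", "111111111111", p), 0.0)
  expect_error(affinity("101", "111111111111", p), "length")
})

test_that("state initialization is seed-deterministic", {
  p <- toy_params()
  s1 <- init_state(p, 7L)
  s2 <- init_state(p, 7L)
  expect_identical(s1, s2)

  s3 <- init_state(p, 8L)
  expect_false(identical(s1$agents$B$site, s3$agents$B$site))

  expect_equal(tumor_count(s1), 0L)
  expect_equal(length(s1$agents$B$site), 30L)
  expect_true(all(s1$il12 == 0))

  empty <- init_state(toy_params(
    baseline = c(B = 0L, Th = 0L, Tc = 0L, NK = 0L, DC = 0L)), 1L)
  expect_true(all(vapply(empty$agents, function(a) length(a$site),
                         integer(1)) == 0L))
})

test_that("vaccine injection conserves cell and IL-12 totals", {
  p <- toy_params()
  st <- init_state(p, 1L)
  n_vc <- function(s) length(s$agents$VC$site)

  st0 <- inject_vaccine(st, toy_params(vaccine_dose = 0L))
  expect_equal(n_vc(st0), 0L)
  expect_equal(st0$il12, st$il12)

  st1 <- inject_vaccine(st, p)
  expect_equal(n_vc(st1) - n_vc(st), p$vaccine_dose)
  expect_equal(sum(st1$il12) - sum(st$il12),
               p$vaccine_dose * p$il12_deposit)
})

test_that("step semantics: source-free, pure accumulation, stop rule", {
  # no tumor sources -> tumor count stays zero
  p0 <- toy_params(tumor_birth = 0L, p_dup = 0)
  st <- init_state(p0, 3L)
  for (k in 1:10) st <- sim_step(st, 0L, p0)
  expect_equal(tumor_count(st), 0L)

  # no immune system, no duplication -> count after k steps is exactly k
  pk <- toy_params(tumor_birth = 1L, p_dup = 0,
                   baseline = c(B = 0L, Th = 0L, Tc = 0L, NK = 0L, DC = 0L))
  st <- init_state(pk, 3L)
  for (k in 1:15) {
    st <- sim_step(st, 0L, pk)
    expect_equal(tumor_count(st), k)
  }

  # monotone source: with kills disabled, tumor is non-decreasing
  pm <- toy_params(tumor_birth = 2L, p_dup = 0.1, nk_kill = 0,
                   baseline = c(B = 0L, Th = 0L, Tc = 0L, NK = 0L, DC = 0L))
  st <- init_state(pm, 5L)
  prev <- 0L
  for (k in 1:20) {
    st <- sim_step(st, 0L, pm)
    expect_gte(tumor_count(st), prev)
    prev <- tumor_count(st)
  }

  # stepping a stopped state is an error
  ps <- toy_params(tumor_birth = 5L, palpable_threshold = 5)
  st <- init_state(ps, 1L)
  st <- sim_step(st, 0L, ps)
  expect_true(st$stopped)
  expect_error(sim_step(st, 0L, ps), "stopped")
})

test_that("tumor-cell conservation ledger balances at every step", {
  p <- toy_params(horizon_steps = 30L)
  g <- toy_grid(10)
  s <- chronic_protocol(g, start_week = 0, end_week = 1)
  day_bits <- tapply(s$x, floor(s$grid$slot_times / 24), max)
  st <- init_state(p, 11L)
  for (k in 1:30) {
    st <- sim_step(st, day_bits[[(st$step %/% 3) + 1]], p)
    ctr <- st$counters
    expect_equal(tumor_count(st),
                 ctr[["tumor_born"]] + ctr[["tumor_dup"]] -
                   ctr[["killed_tc"]] - ctr[["killed_ab"]] -
                   ctr[["killed_nk"]])
    if (st$stopped) break
  }
})

test_that("run_mouse is bit-reproducible and consistent with manual stepping", {
  p <- toy_params()
  g <- toy_grid(20)
  s <- chronic_protocol(g, start_week = 0, end_week = 2)

  r1 <- run_mouse(p, s, 42L)
  r2 <- run_mouse(p, s, 42L)
  expect_identical(r1, r2)

  # caller's RNG stream is untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(run_mouse(p, s, 42L))
    expect_equal(runif(1), before)
  })

  # the fast-path loop equals granular init/step calls, same seed
  p6 <- toy_params(horizon_steps = 6L)
  g2 <- toy_grid(2)
  s2 <- new_schedule(g2, as.integer(g2$admissible))
  rf <- run_mouse(p6, s2, 9L)
  day_bits <- tapply(s2$x, floor(g2$slot_times / 24), max)
  st <- init_state(p6, 9L)
  for (k in 1:6) st <- sim_step(st, day_bits[[(st$step %/% 3) + 1]], p6)
  expect_equal(rf$counters, st$counters)
  expect_equal(unname(rf$final_counts),
               unname(vapply(st$agents, function(a) length(a$site),
                             integer(1))))

  # no sources -> guaranteed survival with zero burden
  pz <- toy_params(tumor_birth = 0L, p_dup = 0)
  rz <- run_mouse(pz, s, 1L)
  expect_true(rz$survived)
  expect_equal(rz$peak_burden, 0)
  expect_equal(rz$survival_step, pz$horizon_steps)

  # grid horizon must match the simulated horizon
  expect_error(run_mouse(toy_params(horizon_steps = 30L), s, 1L),
               "inconsistent")
})

test_that("unprotected mice stop at the first threshold crossing", {
  p <- toy_params(tumor_birth = 4L, palpable_threshold = 40,
                  horizon_steps = 60L)
  g <- toy_grid(20)
  r <- run_mouse(p, new_schedule(g, integer(g$N)), 2L)
  expect_false(r$survived)
  expect_lte(r$survival_step, p$horizon_steps)
  expect_gte(r$peak_burden, 40)
  tr <- r$trajectory
  expect_gte(tr$tumor_cells[nrow(tr)], 40)
  expect_true(all(tr$tumor_cells[-nrow(tr)] < 40))
})

test_that("cohorts are order-independent and reject duplicate seeds", {
  p <- toy_params()
  g <- toy_grid(20)
  s <- chronic_protocol(g, 0, 2)

  expect_identical(run_cohort(p, s, integer(0)), list())
  expect_error(run_cohort(p, s, c(1L, 1L)), "distinct")

  seeds <- c(5L, 9L, 2L)
  res <- run_cohort(p, s, seeds)
  expect_length(res, 3L)
  res_perm <- run_cohort(p, s, rev(seeds))
  expect_identical(res_perm, rev(res))
  # each mouse individually reproducible
  expect_identical(res[[2]], run_mouse(p, s, 9L))
})

test_that("trajectory CSV is written with the documented columns", {
  p <- toy_params()
  g <- toy_grid(20)
  r <- run_mouse(p, chronic_protocol(g, 0, 2), 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(r, path)
  tr <- utils::read.csv(path)
  expect_named(tr, c("day", "tumor_cells", "B", "Th", "Tc", "NK", "DC",
                     "antibodies", "vaccine_cells", "il12_total"))
  expect_equal(tr$tumor_cells, r$trajectory$tumor_cells)
})
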
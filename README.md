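# vaxsched

Optimization of cancer-vaccine administration schedules with a genetic
algorithm driven by an agent-based tumor–immune simulator.

## The problem

Cell vaccines that combine a tumor-associated antigen (HER-2/neu) with
adjuvant stimuli (IL-12 and allogeneic MHC) can prevent mammary carcinoma
in HER-2/neu transgenic mice — but the protective reference protocol is
*chronic*: 4-week cycles with four administrations in the first two weeks
of each cycle, from 6 weeks of age onward. That is far too many injections
for clinical translation, which raises a combinatorial question: **does a
schedule with far fewer administrations protect equally well?**

Formally, discretize the trial horizon `[0, T]` into `N` slots and encode
a schedule as a binary vector `x ∈ {0,1}^N` with `n = Σᵢ xᵢ`
administrations. For `T = 400` days and daily slots the search space `D`
has cardinality `2^400`; restricting administrations to two weekdays
(Mondays and Thursdays) reduces it to `2^114` — still far beyond
exhaustive search. `vaxsched` searches this space with a genetic
algorithm whose fitness function is a *simulator*: each candidate schedule
is administered to a cohort of "virtual mice" (seeded runs of a stochastic
lattice agent-based model of immune response versus continuous
carcinogenesis), and schedules are ranked by cohort protection first, then
tumor burden, then administration count:

```
fitness(x) = w1·survivors − w2·mean(min(peak/θ, 1)) − w3·(n / #admissible),
w1 > w2 + w3
```

Because one simulator run per (individual × mouse × generation) is
expensive — 8·80·150·T_fit ≈ a month of serial compute at T_fit = 30 s —
evaluation is organized master–slave: the master evolves the population
serially and distributes the per-generation `P×M` simulation tasks over
workers, with an analytic cost model
`T_g(c) = T_master(P) + T_sync(c) + ceil(P·M/c)·T_fit`
describing the achievable speedup and its plateau.

## Worked example

```r
library(vaxsched)

grid <- time_grid(400, 24, admissible_weekdays = c(0, 3)) # Mon/Thu
grid
#> <vax_grid> 400 days, dt = 24 h, N = 400 slots, 114 admissible (|D| = 2^114)

params <- sim_params()                      # calibrated virtual-mouse model
chronic <- chronic_protocol(grid, start_week = 6)
chronic
#> <vax_schedule> 52 administrations on a 400-day grid

# one virtual mouse = one seed
run_mouse(params, chronic, seed = 1)
#> <vax_mouse_result> seed 1: protected (day 400.0), peak burden 443 tumor cells

# cohort fitness of the chronic protocol vs no vaccination
evaluate_schedule(chronic, params, seeds = 1:8)
#> <vax_fitness> scalar 79.0687: 8/8 protected, burden 0.475, 52 doses
evaluate_schedule(new_schedule(grid, integer(grid$N)), params, seeds = 1:8)
#> <vax_fitness> scalar -1.0000: 0/8 protected, burden 1.000, 0 doses
```

The chronic protocol protects the whole cohort (scalar ≈ 79: 8 survivors
at weight 10, minus burden and dose penalties); without vaccination every
mouse develops a palpable tumor (1000 tumor cells) around day 80–85.

Optimization and parallel evaluation:

```r
cfg <- ga_config(population_size = 80, generations = 150, cohort_size = 8)
hist <- run_ga(cfg, grid,
               simulator_evaluator(params, seeds = 1:8,
                                   backend = multicore_backend(4)))
```

Results are bit-identical for any backend and worker count: each virtual
mouse re-seeds its own RNG stream, and the master's evolution stream is
separate. The cost model quantifies why workers matter:

```r
estimate_total_runtime(8, 80, 150, 30)   # serial: 2,880,000 s ≈ 33 days
cm <- cost_model_params(T_fit = 30, master_alpha = 0.5,
                        sync_const = 1, sync_log = 0.25)
predict_generation_time(cm, 80, 8, c(1, 8, 64, 640))
#> [1] 19241.0  2441.8   342.5    73.3   # seconds; plateau at c >= P*M
```

A command-line wrapper (`inst/scripts/vaxsched`) exposes `simulate`,
`optimize`, `chronic` and `benchmark` subcommands over JSON run
configurations; see `?read_run_config`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— schedule-space accounting on the 400-day twice-weekly grid, the chronic
reference protocol on a default-parameter cohort, and a reduced
simulator-backed optimization — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/schedule.R` — time grid, admissibility, schedule encoding/IO,
  chronic protocol, search-space accounting.
- `R/simulator.R` + `src/sim_core.cpp` — the lattice agent-based virtual
  mouse (Rcpp core; R surface for init/inject/step/run).
- `R/fitness.R` — cohort fitness, total order, reports.
- `R/ga.R` — constraint-preserving genetic operators and the generation
  loop.
- `R/parallel.R` — task building, static partitioning, serial/multicore/
  scripted backends, the generation-time cost model.
- `R/cli.R`, `inst/scripts/vaxsched` — configuration files and commands.
- `vignettes/schedule-optimization.Rmd` — model, calibration and design
  rationale.
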
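---
title: "Vaccination-schedule optimization with a simulator-backed genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vaccination-schedule optimization with a simulator-backed genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxsched)
```

## The optimization problem

An immunopreventive cell vaccine (tumor-associated antigen plus IL-12 and
allogeneic-MHC adjuvants) protects HER-2/neu transgenic mice from mammary
carcinoma when given *chronically*: 4-week cycles, four administrations in
the first two weeks of each cycle, from 6 weeks of age. The schedule, not
the vaccine, is the clinical bottleneck, so we ask whether sparser
schedules protect equally.

The trial horizon `[0, T]` is discretized into `N` slots of width `Δt`
(`time_grid()`); a schedule is a binary vector over the slots
(`x[i] = 1` = one fixed-dose administration), and `n = sum(x)` counts
administrations. Unconstrained, `T = 400` days at daily resolution gives a
`2^400` search space; the experimental constraint that injections happen
at most twice a week (Mondays and Thursdays) shrinks it to `2^114`:

```{r}
log2_search_space(time_grid(400, 24, 0:6))
log2_search_space(time_grid(400, 24, c(0, 3)))
```

**Calendar alignment.** 400 days is not a whole number of weeks, so the
number of admissible slots depends on which weekday day 0 falls on. The
canonical count of 114 corresponds to alignments in which Monday and
Thursday each occur exactly `floor(400/7) = 57` times; the default
`start_weekday = 4` (Friday) is one such alignment. Other alignments give
115–116 admissible slots; `start_weekday` is configurable and the count is
always reported by `log2_search_space()`, never assumed.

**Slot conventions.** Slots are half-open intervals `[t_i, t_i + Δt)`;
slot 0 starts at day 0, hour 0. With sub-daily slots (`Δt < 24 h`) only
the first slot of an admissible day is admissible, so the twice-weekly
constraint keeps its meaning at any resolution. Dose size is fixed and
uniform — the genome is administration/no-administration only.

## The virtual mouse

Fitness evaluation runs a stochastic lattice agent-based model
(`sim_params()`, `run_mouse()`); one run with one seed is one *virtual
mouse*, and a cohort is a set of seeds. The model is a deliberately
minimal reconstruction in the Celada–Seiden lineage — probabilistic
site-local interactions, bitstring receptors, Hamming-distance affinity —
not a re-parameterization of any published simulator (whose full
equation set and constants live outside this package's sources).

Agents occupy sites of a toroidal square lattice (default 32×32) and move
to a uniformly random Moore neighbor each 8-hour step. Classes: B, T
helper (Th), cytotoxic T (Tc), natural killer (NK), dendritic cells (DC),
vaccine cells (VC), tumor cells, free antigen (Ag) and antibodies (Ab).

**Recognition.** Receptors and epitopes are `ℓ = 12`-bit strings; with
Hamming distance `m`, binding probability is `0` below `min_match` and
`c^(ℓ−m)` otherwise (`c = affinity_base = 0.3`), so a perfect complement
binds with probability 1 — the standard lock-and-key convention of this
model family.

**Step phases** (fixed order; within each interaction rule agents act in
freshly randomized order, and a cell takes part in at most one specific
interaction per step):

1. *Vaccination*: on an administration day's first step, `vaccine_dose`
   VC (carrying the tumor antigen and the allogeneic signal) appear at
   random sites and deposit IL-12 locally.
2. *Movement* of all mobile agents (tumor and vaccine cells are
   sessile).
3. *Site-local interactions*: unloaded DC engulf free antigen
   (aspecific, `p_aspecific`); loaded DC present to one naive Th and one
   naive Tc (specific, multiplied by `1 + il12_boost·IL12(site)`);
   vaccine cells activate naive Th with the match threshold relaxed by
   `allo_relax` bits (the allogeneic tolerance break, stimulating
   multiple clones); activated Th trigger division of one co-located
   activated B and Tc (help); B cells recognizing antigen or vaccine
   cells secrete `ab_burst` antibodies *and divide* (clonal selection);
   tumor cells are attacked by activated Tc (specific), antibodies
   (specific, antibody consumed) or NK (aspecific, `nk_kill`); immune
   clearance or decay of a vaccine cell releases `ag_burst` antigen.
4. *Ageing, death, homeostasis*: agents die past their class lifespan;
   each immune class is replenished to its baseline with naive cells
   bearing fresh random receptors (bone-marrow output).
5. *Carcinogenesis*: every tumor cell duplicates with probability
   `p_dup`, then `tumor_birth` newborn tumor cells seed random sites —
   the carcinogenic process is continuous, not an initial inoculum.
6. IL-12 decays by `il12_decay`.
7. If the tumor count reaches `palpable_threshold` the run stops and the
   mouse is scored unprotected.

The tumor ledger (`born + duplicated − killed = alive`) is maintained
exactly and asserted in the test suite at every step.

## Calibration and what it does (not) establish

The package ships one calibrated default world. Two constraints drove it:

* **Untreated course.** With `tumor_birth = 1` per step and
  `p_dup = 0.012`, net growth after background NK surveillance
  (`nk_kill = 0.05` on co-location, ~0.002/cell/step at 50 NK on 1024
  sites) crosses the 1000-cell palpable threshold around day 80–85 —
  after the chronic protocol's week-6 onset (day 42), well before the
  400-day horizon. A duplication probability of 0.05/step (a plausible
  first guess at 8-hour steps) proved far too aggressive: mice would die
  near day 40, before any vaccination could act, so no schedule could
  ever protect.
* **Vaccinated course.** Protection requires an expandable
  antigen-specific compartment. With 12-bit receptors, `min_match = 10`
  leaves ~2 % of the naive repertoire responsive — too sparse on a
  1024-site lattice at reasonable population sizes — so the default is
  `min_match = 9` (~7 % responsive) with baselines B/Th/Tc = 150,
  DC = 100, NK = 50. The B-cell clonal-selection rule (divide on
  successful recognition) is what lets responsive clones amplify; it is
  bounded by a carrying capacity (`max_expansion = 10` × baseline),
  without which expansion is unbounded. Effector pressure is mostly
  humoral (antibody bursts, 60-step antibody lifespan) plus Tc priming
  via DC cross-presentation of vaccine-released antigen.

Tumor kills release no antigen (no cross-priming), so untreated mice
mount no specific response at all: the untreated/vaccinated contrast is
driven purely by the schedule, which is the quantity under optimization.

What the generator emulates: continuous months-scale carcinogenesis,
seed-to-seed variability as individual diversity, adjuvant enhancement,
dose-timing sensitivity (protection collapses if administrations stop or
thin out too far), and a cheap-enough evaluation for thousands of GA
calls. What it does not: real immunological time constants, isotype
switching, affinity maturation, regulatory suppression, tumor spatial
morphology, or any published parameter set. A green calibration test
therefore establishes that *this stated world* separates untreated from
chronically vaccinated cohorts (≥80 % each way on 20 mice), not that the
model predicts murine biology.

## Fitness

`evaluate_schedule()` aggregates a cohort into
`scalar = w1·survivors − w2·burden_penalty − w3·dose_penalty` with
`burden_penalty = mean(min(peak/θ, 1))` and
`dose_penalty = n / #admissible`, defaults `(10, 1, 1)`. Both penalties
lie in `[0, 1]`, so `w1 > w2 + w3` makes protection lexicographically
dominant — a deliberate substitute for the (unpublished) fitness of the
original optimization, motivated by its stated goal: protect a *large
class* of individuals, then minimize administrations. Ties are broken by
survivors, dose, burden, then genome order, making the ranking a total
order and the whole algorithm deterministic. The cohort seeds are fixed
once per run: every individual in every generation faces the same mice.

## Genetic algorithm

Reference scale: population 80, cohort 8, 150 generations. The original
report does not specify its operators; we use standard,
constraint-preserving choices on the *compressed* admissible-gene vector
(length 114 by default): Bernoulli(½) initialization, tournament-2
selection, uniform crossover (rate 0.7), per-gene flip mutation (rate
1/#admissible ⇒ one expected flip), elitism 1. Operating on admissible
genes only means no operator can ever propose an inadmissible
administration, so repair steps are unnecessary.

RNG discipline: evolution draws from a single stream seeded by
`master_seed`; each virtual mouse re-seeds its own stream from its cohort
seed (and restores the caller's RNG state afterwards). Consequently the
full history is a pure function of `(master_seed, cfg, grid)` — for any
backend, worker count or gather order.

## Master–worker evaluation and the cost model

Each generation needs `P·M` independent simulator runs. `build_tasks()`
enumerates them, `partition_tasks()` assigns static blocks differing by
at most one task, and a backend executes them: `serial_backend()` (the
reference), `multicore_backend()` (forked processes, standing in for the
original MPI broadcast → barrier → evaluate → gather cycle behind the
same contract), and `scripted_backend()` (serial execution with permuted
gather order, proving the master's aggregation is order-independent).

The per-generation wall time is modeled as

```
T_g(c) = T_master(P) + T_sync(c) + ceil(P·M / c) · T_fit
```

with `T_master(P) = α·P` (the serial evolution work, an operation-count
proxy) and `T_sync(c) = a + b·log2(c)` — the synchronization term's
functional form is not documented anywhere, so it is a configurable
constant-plus-log placeholder, fit to nothing. The model reproduces the
qualitative structure of master–worker scaling: near-linear decrease of
`T_g` in `c`, a plateau `T_master + T_sync + T_fit` once `c ≥ P·M`, and
plateau growth with `P` (the serial master bottleneck). Published
wall-clock minutes are hardware-bound and are *not* reproduction targets;
`cmd_benchmark()` measures this machine instead and prints both columns.

## Numerical and design choices

* **Weekday encoding** 0–6 with 0 = Monday; `start_weekday` anchors the
  grid (default Friday, see above).
* **Injection hour**: administrations happen at the first step of the
  slot's day (the original hour is unstated).
* **Tumor duplication order**: existing cells duplicate, then newborns
  seed, so a newborn cannot double in its birth step.
* **Clone bookkeeping**: cells created inside a step do not interact
  until the next step; antibodies are consumed by the kill they cause.
* **Degenerate inputs**: empty admissible sets give the singleton search
  space (`2^0`); `vaccine_dose = 0` injections are no-ops; a stopped
  state refuses further stepping; duplicate cohort seeds are rejected.
* **Determinism boundaries**: `run_mouse()` is bit-reproducible and
  leaves the caller's RNG untouched; the granular `init_state()` /
  `sim_step()` path consumes the RNG stream identically to the compiled
  full-run loop (asserted in tests).
* **History files** exclude wall-clock timing columns so identical runs
  produce byte-identical outputs.

## Limitations

The simulator is a calibrated toy: its constants were chosen to realize
the documented untreated/vaccinated contrast on a 32×32 lattice, and
conclusions about *specific* optimized schedules transfer to biology only
through the same in-silico-to-in-vivo loop the original program used
(simulate → optimize → validate in animals). Cohorts of 8 seeds bound
what "protects a large class" can mean statistically. The multicore
backend shares memory; distributed deployment would implement the same
backend contract over a message-passing runtime, which this package
intentionally does not ship.
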
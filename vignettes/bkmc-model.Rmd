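---
title: "A continuous-time stochastic Boolean model of the budding yeast cell cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A continuous-time stochastic Boolean model of the budding yeast cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`bkmcyeast` simulates the budding yeast cell-cycle control network as a
hybrid of a Boolean network and a continuous growth law, updated by a
Boolean flavour of Gillespie's stochastic simulation algorithm (a "Boolean
kinetic Monte-Carlo" scheme). Seven Boolean variables lump the main
regulators:

| Variable | Lumped activities | Role |
|---|---|---|
| `Cdh1`  | Cdh1 + Sic1   | antagonists of Clb kinases in G1 |
| `SBF`   | SBF + MBF     | G1/S transcription factors |
| `Cln2`  | Cln1/2 (+ Swe1-like inhibition of Clb2M) | bud emergence |
| `Clb5`  | Clb5/6        | S-phase cyclins |
| `Clb2G` | residual Clb1/2 | prophase mitotic cyclin activity |
| `Clb2M` | high Clb1/2   | metaphase mitotic cyclin activity |
| `Cdc20` | Cdc20 + Cdc14 | mitotic exit |

A state is the 7-bit vector written in this fixed order, so a newborn G1
cell is `1000000`. Each variable has a target function over the current
state (AND/OR/NOT logic reflecting activation of SBF targets by SBF,
mutual antagonism of Cdh1 and the Clbs, the two-step activation and
two-step destruction of Clb2, and maintenance of Cdc20 by residual Clb2).
At each iteration the engine:

1. evaluates all seven target functions to get candidate bits `B*`;
2. assigns each variable that would change a propensity
   `P_i = p_i |B*_i − B_i|`;
3. selects one variable: the smallest index `j` with
   `sum(P_1..P_j) > r1 * P0` (`P0` the propensity sum, `r1` uniform), so
   updates are asynchronous — exactly one bit flips per event;
4. draws the waiting time `dt = −log(r2)/P0`;
5. applies the flip and grows the cell, `Size <- Size * exp(mu * dt)`.

Three departures from the plain scheme encode cell-cycle physiology:

* **Mitotic delays.** Activations of `Clb2M` and of `Cdc20` are multi-step
  processes in reality; once selected, their waiting time is drawn
  lognormal with `meanlog = log(t_M_mean)`, `sdlog = t_M_CV` instead of
  exponentially. Only the waiting time is replaced; selection
  probabilities are untouched, deactivations keep the exponential clock,
  and both variables share the single `t_M_mean` of the parameter table.
  Delays are not pre-emptive: the selected transition always fires.
* **The Start gate.** In the newborn state `1000000`, SBF can only switch
  on once `Size` exceeds the cell's critical size `S0` (assigned at birth
  from a lognormal with `meanlog = log(S0_mean)`, `sdlog = S0_CV`), and
  then with probability `(Size − S0)^2` per attempt, capped at 1 since a
  large cell can exceed `Size − S0 = 1`. The Bernoulli draw `r0` is fresh
  at every iteration. While the gate stays shut, `P0 = 0` and the cell
  waits an exponential time with rate `p_G1` before re-trying, growing all
  the while. The gate condition requires the state to be exactly
  `1000000`, so SBF can never (re)activate from any other state — the
  state-transition graph has a single Start edge.
* **Unequal division.** When `Clb2G` switches 1 → 0 the cell divides. The
  mother keeps a lognormal fraction `f` (`meanlog = log(f_mean)`,
  `sdlog = f_CV`; redrawn in the extreme-tail case `f` falls outside
  (0,1)) of the post-growth size, the daughter receives the rest, sizes
  summing exactly. Both progeny draw fresh critical sizes — a division is
  the birth of both records. Both continue from the post-division Boolean
  state (`1000001` on the normal cycle).

```r
library(bkmcyeast)
sim <- simulate_cell(state = "1000000", size = 0.65, horizon = 300)
head(sim$events)
```

## Parameters

All defaults are the published calibration. Rates are per minute; sizes
are dimensionless "physiological size" (1 size unit ≈ 61.4 fL when
comparing to volumes).

| Parameter | Default | Meaning |
|---|---|---|
| `p_Cdh1` … `p_Cdc20` | 1 min⁻¹ | flip propensities; equal so no switch is biased |
| `p_Cln2` | 10 min⁻¹ | Cln1/2 are unstable and track SBF quickly |
| `p_G1` | 1 min⁻¹ | rate of gate re-trials during G1 waiting |
| `mu` | 0.007 min⁻¹ | specific growth rate (mass-doubling time ≈ 99 min) |
| `t_M_mean`, `t_M_CV` | 30 min, 0.30 | mitotic delay scale; calibrated to the budded period |
| `S0_mean`, `S0_CV` | 0.4, 0.05 | birth-assigned critical size distribution |
| `f_mean`, `f_CV` | 0.58, 0.05 | mother's share at division |

`default_params(mu = log(2)/150)` models growth on a poor carbon source.
Mutant genotypes are rule-set overrides (`mutant_ruleset()`): the
single-cyclin strain forces `Clb5* = 0` and adds `| SBF` to the `Clb2G`
rule; its methionine-repressed variant additionally forces `Cln2* = 0` and
doubles `S0_mean`; a `cln3` deletion only raises `S0_mean` (default 0.68,
i.e. ~70% larger cells — the published account states only the
qualitative increase, so the value is exposed as an argument). Arbitrary
rule overrides can be given as Boolean expression strings, also from a
YAML/JSON config (`load_config()`).

## The state-transition graph

`build_graph()` connects each of the 128 states to the states reachable by
one enabled flip, weighted by propensity. Without the Start edge the
wild-type graph is acyclic (`is_acyclic()` implements Kahn's algorithm and
returns a verifiable topological order) with a single root `1101010` and a
single sink `1000000`. With the Start edge the unique recurrent class is
the 14-state cell-cycle highway of `highway_reference()`, in order.

`steps_to_highway()` solves the expected number of Boolean updates to
reach the highway exactly, by first-step linear equations on the
propensity-weighted jump chain (branching along a `Cln2` edge is 10 times
likelier than along a unit-rate edge), plus the full step-count
distribution. Because a single "average" depends on the averaging set,
which the published account leaves implicit, two means are reported: the
uniform mean over all 114 off-highway states and the uniform mean over the
largest weakly connected component of the off-highway subgraph. For the
wild-type rules that component contains all 114 states, so both equal
2.88, i.e. three steps when rounded.

## Population simulations

`run_population()` starts `n_founders` cells and follows all progeny to
the horizon. Cells do not interact, so lineages are simulated one cell at
a time in birth (FIFO) order from a single seeded RNG stream; a fixed
`(seed, configuration)` pair reproduces event logs byte-for-byte. A cell's
"birth" timestamp is the `Clb2G` switch-off of the division that created
it, so the unbudded interval `T_G1` (birth to SBF activation, including
the brief `1000001 → 1000000` step) and the budded interval `T_bud` (SBF
activation to division) partition the cycle time exactly:
`T_c = T_G1 + T_bud`. Cycles are pedigree-labelled by bud-scar count:
0 scars = daughter, otherwise mother.

Protocol sizes used by the tests and the acceptance script, chosen once:

* synchronized outgrowth: 20 founders of size 0.65 for 400 min;
* asynchronous statistics at default growth: 7 founders to 900 min,
  cycles starting before 400 min discarded — about 1500 cycles per
  pedigree class, matching the size of the published samples;
* slow growth (`mu = ln 2 / 150`): 12 founders to 1200 min, 400 min
  burn-in, about 3400 cycles.

With these, the suite reproduces mother/daughter mean cycle times of
about 117 and 183 min at the 150-min mass-doubling time, and a population
number-doubling time equal to the mass-doubling time within 5%.

### Size-control slopes

`binned_slope()` reproduces the experimentalists' analysis: cells are
binned by size at birth in 2-fL bins (61.4 fL per size unit; the
conversion only affects binning, all computation is dimensionless), and
the per-bin mean of `mu * T_G1` is regressed on the per-bin mean of
`ln(size-at-birth)`. A slope of −1 is a perfect sizer, 0 is no size
control; both limits are recovered exactly on synthetic records by
construction of the estimator. Mothers are fitted with one line (slope
≈ −0.33 at defaults). Daughters get two lines. The breakpoint needs care:
chosen by minimizing the total squared error it lands near the daughter
size mode and the small-cell limb steepens to ≈ −0.95, the near-sizer
limit. Anchoring the breakpoint at the average mother size at birth — the
natural unit of the relative-size axis this analysis is plotted on —
gives small/large daughter slopes of ≈ −0.8 and ≈ −0.33, the published
decomposition; `breakpoint_fl` exposes the choice, with min-SSE as the
fallback when it is `NULL`. Bins with fewer than `min_per_bin` records
(default 5; 15 is used in the acceptance checks to stabilise tails) are
dropped.

## The perturbation screen

`enumerate_perturbations()` lists the 70 single flips off the highway:
five per state, excluding the variable just updated and the one to be
updated next; flipping `Clb2M` on also sets `Clb2G` on (high mitotic
cyclin implies the residual activity). `run_screen()` follows 5000
growth-free trajectories per flip to the G1 sink and classifies each;
`exact_class_probabilities()` computes the same outcome distribution
exactly, by first-step analysis on the Boolean state augmented with the
classification flags — an independent oracle the Monte-Carlo must match
within binomial error.

A trajectory is judged by whether the cell-cycle milestones occur in the
physiological order: bud emergence (Cln2 or Clb5 active) before prophase
(first Clb2G activity), DNA replication, spindle assembly (Clb2M),
chromosome segregation (Cdc20) and mitotic exit. The bookkeeping
conventions matter and are part of the model's definition here:

* *Activity* milestones (budding, prophase entry, Clb2M and Cdc20 having
  been active) count however the variable became active — highway history
  before the flip, the perturbation flip itself, or a spontaneous update.
* *Replication* and *Cdc20 firing* are credited only for genuine events
  (spontaneous 0→1 updates, including highway history): a spurious flip
  of a cyclin does not by itself replicate DNA.
* Every spontaneous `Clb2G` 1→0 update is a division. A division in a
  cycle with neither a replication event nor a Cdc20 firing is benign:
  the cell simply re-enters G1 and the bookkeeping restarts from the
  post-division state. A division of a replicated cell that never
  activated `Clb2M` is immediately lethal (no metaphase alignment,
  aneuploid progeny): `exit_without_Clb2M` if Cdc20 was active,
  `exit_without_Cdc20` otherwise. A division of a replicated cell after
  metaphase but before any Cdc20 firing is not judged on the spot — the
  verdict falls at the arrival in stable G1, so a later proper cycle can
  still rescue the walk. Otherwise the division completes a cycle:
  normal if the bud preceded prophase, `no_bud_exit` if not.
* The bookkeeping cycle boundary is the return to stable G1 (`1000000`),
  not the division, so perturbations of the two post-division highway
  states carry the whole previous cycle's milestones.

These conventions were fixed by requiring the exact oracle to reproduce
the published screen: the same 12 aberrant flips (premature mitotic
cyclins in G1 → exit without budding; premature Cdc20 in S/prophase →
exit without Clb2M; premature Cdh1 in prophase/metaphase → exit without
Cdc20), each within the sampling error of the published 5000-repeat
percentages, an overall normal fraction of 90.9%, and pooled group rates
of 52% and 41%. Timing rules (the lognormal delays) play no role in an
order-only classification and are skipped in the screen.

```r
screen <- run_screen(n_reps = 5000)
attr(screen, "overall_normal_pct")
exact_class_probabilities(enumerate_perturbations()[31, ])
```

## Numerical and design notes

* Ties in selection cannot occur (the cumulative-propensity rule picks the
  smallest index); candidate evaluation is a total function on the state
  space, so there are no error states.
* The exact hitting-step solve uses a dense 114×114 linear system; the
  screen oracle memoizes over at most 128 × 2⁷ augmented states; both are
  exact up to floating point.
* `mu = 0` is allowed (cells below `S0` then never pass Start), which the
  tests use as a degenerate-input check.
* Under mutant rules a non-G1 state can become absorbing; the engine then
  lets the cell grow without further Boolean events rather than erroring,
  which is the observed phenotype of the methionine-repressed strain (no
  division).
* Daughters inherit the mother's post-division Boolean state; their
  first event is almost always the Cdc20 switch-off completing mitotic
  exit.

## What the generator does and does not emulate

Simulated data reproduce the order of cell-cycle events, stochastic phase
durations, mother/daughter asymmetry, size control at Start, loss of
synchrony in outgrowth experiments, and exponential population growth.
They do not emulate: measurement noise of microscopy volumes (the fL
conversion is a fixed constant), nutrient feedback beyond a fixed growth
rate, cell death, mother-size trends across generations (the "size" is
physiological, and a mother's size can shrink between divisions), or the
gene-level redundancies that make real knockouts milder than setting a
Boolean variable to zero. The model is also known to overestimate the
coefficient of variation of `T_G1`; passing tests therefore certify the
model's published behaviour, not experimental fidelity of every moment.
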
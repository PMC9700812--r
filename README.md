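# bkmcyeast

Continuous-time stochastic Boolean simulation of the budding yeast
(*Saccharomyces cerevisiae*) cell-division cycle, for systems biologists
who want quantitative, experiment-comparable statistics out of a logical
model instead of a full reaction-kinetic ODE system.

## The model

Seven Boolean variables track the activities of the core regulators —
(Cdh1, SBF, Cln2, Clb5, Clb2<sub>G</sub>, Clb2<sub>M</sub>, Cdc20), written
as a 7-digit state such as `1000000` (newborn G1) — plus one continuous
variable, Size(t), growing as Size·e^(μΔt). Updating is asynchronous and
embedded in continuous time by a Gillespie-style kinetic Monte-Carlo
scheme: target functions B\*ᵢ = Fᵢ(B₁,…,B₇) give each variable's candidate
value, a propensity Pᵢ = pᵢ·|B\*ᵢ − Bᵢ| enters a race, the winner is the
smallest index j with Σᵢ≤ⱼ Pᵢ > r₁·P₀, and the waiting time is
Δt = −log(r₂)/P₀. Three physiological rules complete the model: lognormal
delays for the multi-step activations of Clb2<sub>M</sub> and Cdc20; a
size-gated Start transition (SBF activates only once Size exceeds a
birth-assigned critical size S₀, with probability (Size−S₀)² per attempt);
and unequal division at the Clb2<sub>G</sub> switch-off, the mother keeping
a lognormal fraction f (mean 0.58) of the size.

The package provides:

* the wild-type rules, published mutant rule sets, and declarative rule
  overrides (`ruleset()`, `mutant_ruleset()`, `rule_function()`);
* the 128-node asynchronous state-transition graph with Kahn topological
  sorting, root/sink analysis, the globally attracting 14-state
  "cell-cycle highway", and exact propensity-weighted return-step
  statistics (`build_graph()`, `find_highway()`, `steps_to_highway()`);
* single-cell and population simulations with mother/daughter pedigrees,
  cycle-interval statistics and binned size-control slopes
  (`simulate_cell()`, `run_population()`, `extract_cycles()`,
  `binned_slope()`, `budded_fraction()`);
* the 70-flip perturbation-robustness screen with an exact
  first-step-analysis oracle (`run_screen()`,
  `exact_class_probabilities()`).

## Worked example

```r
library(bkmcyeast)

set.seed(42)
sim <- simulate_cell(state = "1000000", size = 0.65, horizon = 300)
head(subset(sim$events, kind != "g1_wait"), 8)
#>   time  kind variable   state  size
#> 1 11.8 start      SBF 1100000 0.706
#> 2 11.9  flip     Cln2 1110000 0.706
#> 3 14.9  flip     Cdh1 0110000 0.721
#> 4 16.2  flip     Clb5 0111000 0.728
#> 5 16.4  flip    Clb2G 0111100 0.729
#> 6 17.0  flip      SBF 0011100 0.732
#> 7 17.0  flip     Cln2 0001100 0.732
#> 8 39.6  flip    Clb2M 0001110 0.858
sum(sim$events$kind == "division")
#> [1] 3
```

The flip sequence is the cell-cycle highway: Start (SBF on) once the size
gate opens, bud emergence (Cln2), Cdh1 off, S phase (Clb5), prophase
(Clb2G), then — after a ~30 min lognormal delay — metaphase (Clb2M),
anaphase (Cdc20) and mitotic exit. This lineage divides 3 times in 300
min. The graph analysis certifies the global attractor structure:

```r
graph_report()[c("n_states", "acyclic_without_start_edge", "roots", "sinks",
                 "mean_steps_off_highway")]
#> 128 states; acyclic TRUE; root "1101010"; sink "1000000";
#> mean return steps over the 114 off-highway states 2.878
```

i.e. a random flip off the highway finds its way back in about three
Boolean updates. The robustness screen quantifies which flips matter:

```r
set.seed(42)
sc <- run_screen(n_reps = 5000)
attr(sc, "overall_normal_pct")
#> [1] 90.93   # ~91% of 350,000 perturbed trajectories resume normally

exact_class_probabilities(subset(enumerate_perturbations(),
  highway_state == "0111100" & variable == "Cdc20"))
#>  normal  no_bud_exit  exit_without_Clb2M  exit_without_Cdc20
#>  0.2273       0.0000              0.7727              0.0000
```

A premature Cdc20 flip in prophase makes 77% of cells divide without ever
activating Clb2<sub>M</sub> — mitotic exit without metaphase alignment,
i.e. aneuploid progeny — matching the Monte-Carlo fraction within
binomial error.

A command-line front end over the same functions ships in
`inst/scripts/bkmc-cli.R` (subcommands `graph`, `simulate`, `synchrony`,
`population`, `perturb`, `mutant`; configuration files are YAML/JSON via
`load_config()`).

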
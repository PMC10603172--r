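# dyadsim

When two people work together — conversing, singing, searching a room —
their behaviors organize into *synchrony* (the same behavior at the same
time) or *complementarity* (opposing or offset behaviors, as in
turn-taking). `dyadsim` is a simulation and analysis toolkit for studying
how the **task context** shapes which of these regimes emerges, aimed at
researchers of interpersonal coordination dynamics who want a transparent,
first-principles model rather than a black box.

## The model

Each agent's behavior is a scalar (attentiveness, speech rate, movement,
...). The dyad's state `B(t) = (b1(t), b2(t))` evolves as a discrete-time,
noise-driven linear map:

```
B(t) = C · I · B(t-1) + U(-0.5, 0.5) - α B(t-1)
```

* `C` is the 2×2 **context matrix** `(S1, O1; O2, S2)` with ternary entries:
  1 = active, 0 = inactive, -1 = inhibitory constraint. `S1`/`S2` are
  self-influences (behavioral autocorrelation); `O1` is how much Person 2
  influences Person 1, `O2` the reverse.
* `I` is a global receptivity scalar, fixed at 1.
* `U(-0.5, 0.5)` is fresh uniform noise, drawn independently per agent per
  step.
* `α = 0.1` is a decay damping runaway growth.

Examples: `C = (0,0;0,0)` is a null task (pure noise); `(1,1;1,1)` is
unison (singing together); `(1,0;1,0)` a lecture (Person 1 drives);
`(1,0;1,-1)` a lecture whose listener inhibits the urge to interrupt.

The per-run outcome statistic is the Pearson correlation `r` between the
two series: `r > 0.25` is classified as synchrony, `r < -0.25` as
complementarity. The full experiment enumerates all `3^4 = 81` ternary
contexts, runs 100 simulations of 500 turns for each (8100 runs), and asks
which context parameters predict `r`: prevalence of inhibitory entries in
each tail (with chi-square tests), and five dummy-coded regression designs
(main effects, pairwise interactions, both, initiator-focused,
self-influence-focused) compared by R², AIC and BIC.

## Worked example

```r
library(dyadsim)

# one "conversation" under the inhibited-lecture context
traj <- simulate_dyad(context_matrix(1, 0, 1, -1), sim_config(seed = 7))
pearson_r(traj)                               # -0.014
spectral_radius(context_matrix(1, 0, 1, -1))  # 1.1  (divergent dynamics)

# the full experiment: 81 contexts x 100 reps x 500 turns, then analysis
sweep <- run_sweep(sim_config(seed = 1), reps = 100)
analyze_sweep(sweep)
```

```
sweep analysis (threshold +/- 0.25): 8100 rows, 0 missing r
complementarity         neutral       synchrony         missing
           2676            2748            2676               0
negative-parameter rate: complementarity 96.2% (n=2676), synchrony 73.7% (n=2676)
           model k_printed        r2    adj_r2      aic      bic
1   main_effects         8 0.0819016 0.0809939 16482.81 16552.80
2   interactions        48 0.7676669 0.7667453  5400.33  5638.32
3        overall        56 0.7676669 0.7667453  5400.33  5638.32
4      initiator        28 0.4385913 0.4366436 12538.78 12748.77
5 self_influence        28 0.7674179 0.7666111  5401.01  5611.00
```

Reading the output: complementary runs almost always come from contexts
containing at least one inhibitory (-1) entry (96.2% of the 2676
complementarity-tail rows), while synchrony is much less selective (73.7%).
Main effects of the context parameters alone explain little of the
variation in `r` (R² = 0.08); adding cross-parameter interaction terms
lifts this to 0.77, and the interactions-only design fits exactly as well
as the full design (their spans coincide), so AIC/BIC favor it. The
self-influence design (both agents' diagonal entries plus their
interactions) performs nearly as well as the full interaction set — how
agents relate to *their own* past behavior carries most of the predictable
signal.

Figure-style metrics for any context family:

```r
runs <- lapply(1:100, function(i) {
  cfg <- sim_config(seed = child_seed(1, i))
  simulate_dyad(context_matrix(1, 0, 1, 0), cfg)
})
cross_correlation(runs, max_lag = 50)  # lagged mean/SD correlation profile
pool_turn_lags(runs, max_lag = 20)     # turn-taking lag histogram
```

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "dyadsim", package = "dyadsim")`):

```sh
Rscript inst/cli/dyadsim simulate --context 1,0,1,-1 --turns 500 --seed 7 --out out/
Rscript inst/cli/dyadsim sweep   --reps 100 --seed 1 --out out/
Rscript inst/cli/dyadsim analyze --sweep out/sweep.csv --out out/
Rscript inst/cli/dyadsim ccf     --context "0,0,0,0;1,1,1,1" --reps 100 --out out/
Rscript inst/cli/dyadsim lags    --context 1,1,1,1 --reps 100 --out out/
```

Every command writes CSV/JSON outputs plus a manifest (tool version, master
seed, resolved configuration, output files) sufficient to reproduce its
results exactly; re-running with the same flags is byte-identical.

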
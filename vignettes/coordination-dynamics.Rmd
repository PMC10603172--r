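---
title: "Modeling task-constrained coordination dynamics with dyadsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling task-constrained coordination dynamics with dyadsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsim)
```

## The model and its assumptions

`dyadsim` treats an interacting dyad as a two-dimensional, discrete-time,
noise-driven linear map. Each agent's momentary behavior is a single real
number; the pair `B(t) = (b1(t), b2(t))` evolves as

$$B(t) = C \cdot I \cdot B(t-1) + U(-0.5, 0.5) - \alpha B(t-1),$$

so the deterministic part of one step is the matrix
$M = C \cdot I - \alpha\,\mathrm{Id}$ applied to the previous state, plus
independent uniform noise per agent. The context matrix
$C = (S_1, O_1; O_2, S_2)$ has ternary entries encoding task constraints on
each channel of influence: active (1), inactive (0) or inhibitory (-1).
Row 1 of $C$ produces Person 1's next behavior, row 2 Person 2's; the
diagonal entries are self-influences, the off-diagonals cross-agent
influences.

The model's assumptions are deliberately strong: behavior is unidimensional
and unbounded; coupling is linear and time-invariant; noise is white,
additive, and identically scaled for both agents; receptivity $I$ is a
constant scalar. These make every aggregate statistic a transparent
function of $C$, at the cost of realism (see *Limitations*).

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `n_turns` | recorded points per agent (index 0 = initial state) | 500 | long enough that per-run correlation sampling error (~1/sqrt(500)) is small relative to the +/-0.25 classification thresholds |
| `alpha` | decay fraction per step (unitless, in [0,1]) | 0.1 | 10% proportional damping; prevents trivial saturation without dominating the coupling |
| `influence` | global receptivity scalar `I` | 1 | full receptivity; the reference condition for the context sweep |
| `noise_low/high` | per-agent uniform noise bounds | -0.5, 0.5 | unit-width noise sets the behavioral scale |
| `init_low/high` | uniform initial-state bounds | -0.5, 0.5 | matches the noise scale, so the initial transient is no larger than one noise shock |
| `start_agent` | who gets a random initial state | `both` | the unconstrained choice; `agent1`/`agent2` model one agent "starting the conversation" (the other starts at 0) |
| `update_mode` | `synchronous` or `alternating` | `synchronous` | the displayed equation is a simultaneous two-component map; see below |
| `seed` | master seed | 1 | all randomness flows from it |

Sweep scale: `run_sweep()` defaults to all 81 ternary contexts x 100
repetitions x 500 turns (8100 runs, about 4 million scalar updates — a few
seconds on one core). The test suite exercises the same code paths at both
this scale and reduced scales.

## Update semantics: a genuinely open design choice

The update equation is written as a simultaneous map: both components of
`B(t)` are computed from `B(t-1)`. A turn-taking narrative, however,
suggests sequential updating — one agent acts, then the other responds to
the *new* state. Both readings are implemented:

* `synchronous` (default): `B(t) = M B(t-1) + e(t)`. This is the literal
  reading of the equation and the package contract for `step_dyad()`.
* `alternating`: one component updates per step while the other holds its
  value, starting with the starting agent.

The choice matters more than it may appear. Under the synchronous map, the
anti-phase "exchange" mode of mutually-coupled contexts (for example
`C = (0,1;1,0)`, each agent copying the other) has eigenvalue
`-(1 + alpha)` and diverges in alternation, driving the per-run correlation
to -1; sequential updating damps exactly this mode and yields positive
correlation for the same context. Aggregate statistics that condition on
the correlation tails — in particular the prevalence of inhibitory
parameters among complementary runs, and the variance structure the
regression designs can capture — are therefore sensitive to the update
semantics. The package fixes `synchronous` as the default because it is the
equation's literal meaning, and exposes `alternating` so users can probe
this sensitivity directly.

## Divergence and overflow-safe statistics

With ternary entries, `alpha = 0.1` and `I = 1`, 53 of the 81 contexts have
a decayed coupling matrix with spectral radius above 1 (up to 2.1 for
`C = (-1,-1;-1,-1)`); their trajectories grow exponentially, by design —
no clipping or discarding is applied, since the model text prescribes none
and the downstream statistics are scale-invariant. Two numerical
consequences are handled explicitly:

* **Magnitudes** stay below the double-precision ceiling (worst case
  `2.1^500 ≈ 1e161`), but naive correlation sums of squares would overflow.
  Every correlation in the package is therefore computed on max-abs
  rescaled series (`normalize_series()`); by the scale invariance of the
  Pearson correlation this is exact, not approximate.
* **Stability diagnostics**: `spectral_radius()` flags divergent contexts.
  For stable contexts the state obeys the accumulated operator-norm bound
  $\|B(t)\| \le \|M^t\|\|B(0)\| + \sum_{k<t}\|M^k\|\,\|e\|$, which the
  property suite verifies. (A bound based on the spectral radius alone
  would be wrong: non-normal coupling matrices overshoot it transiently.)

Runs with undefined correlation (a constant series, or non-finite values
under non-default configurations) are retained in sweep tables as missing
values, never dropped silently; all downstream analyses exclude them
listwise and report the exclusion count.

## Random-number discipline

A master seed spawns one child seed per (context, repetition) pair via a
documented counter scheme, `(master + counter * 1000003) mod 2147483629`
with 1-based counters in row order, so any single run is reproducible in
isolation from its recorded seed. Within a run, draws occur in a fixed
order: initial state(s), then agent 1's full noise block, then agent 2's.
Two sweeps with the same master seed are identical row for row.

## Metrics: conventions and tie-breaks

* **Cross-correlation function** (`cross_correlation()`): per run and lag
  `k` in `[-max_lag, max_lag]` (default 50), the correlation of `b1(t)`
  with `b2(t+k)` over the overlapping window only (no padding, so each lag
  is an unbiased Pearson estimate). *Positive lag means Person 1 leads.*
  The sign convention is arbitrary but fixed and documented; the lag-0
  value reproduces `pearson_r()` exactly because both share the
  normalization path.
* **On-states** (`binarize_on_states()`): each series is thresholded at its
  own mean with strict inequality, so a constant series is all-off.
* **Turn-taking lags** (`turn_lags()`, window default +/-20): for each
  agent-1 on-event, the signed offset to the nearest agent-2 on-state.
  Equidistant ties resolve to the *negative* lag — any fixed rule would do;
  this one is covered by a hand-enumerated test. Events with no partner
  on-state inside the window are excluded from the histogram mass but
  counted, since the histogram is meant to describe realized transitions.
  By default only agent 1's on-events are scored (with `events = "both"`
  for the symmetric pooled variant), mirroring the asymmetric "initiator"
  reading of the lag analysis.

## Regression designs and information criteria

Each ternary parameter is dummy coded with 0 as the reference level
(indicators `s_1p, s_1n, ..., s_2n`). The five designs are built as
factor-style formulas, so an "interaction term" between two parameters
contributes the full four products of their indicators *and spans their
margins*. Two consequences are deliberate:

* The interactions-only design (printed count 48 = 8 dummies x 6 partner
  dummies, double-counting each unordered product) spans intercept + 8
  main-effect + 24 interaction degrees of freedom (rank 33). Adding the
  main effects (the "overall" design, printed count 56) does not change the
  span, so the two models fit identically — an exact structural identity,
  verified to 1e-10 in the tests.
* Fits use rank-revealing least squares (`stats::lm`), tolerating the
  duplicated and aliased columns that the printed counts imply.

Both parameter counts are always reported: `k_printed` (the nominal counts
8/48/56/28/28) and `k_unique` (linearly distinct fitted coefficients,
8/32/32/28/28). For adjusted R², AIC and BIC the default convention is
`"unique"` — the Gaussian log-likelihood at the MLE variance with
`k = rank + 1`, exactly R's own `AIC()`/`BIC()` accounting, under which
models with identical spans score identically (preserving the
interactions/overall identity). The `"printed"` convention
(`k = k_printed + intercept + variance`) is available via a switch, and
shifts AIC by `2 (k_printed - k_unique)`; the choice is logged in every
fit result.

## Chi-square nulls

The prevalence test for inhibitory parameters in the complementarity tail
needs a null proportion, and "uniform" admits two readings. Both are
computed and reported, neither privileged scientifically:
`fifty_fifty` (0.5/0.5) and `structural` (65/81 vs 16/81 — the fraction of
ternary matrices containing at least one -1 entry). The two-proportion
variant compares the complementarity and synchrony tails directly. All
statistics are plain Pearson chi-squares without continuity correction;
no multiple-testing adjustment is applied anywhere, since the analysis is
descriptive of a simulated population.

## What the simulation does and does not emulate

The generator *is* the study object here — there is no external data. Its
defaults define the reference conditions (81 x 100 x 500, noise and decay
as above). What passing tests demonstrate is therefore internal: the
implementation honors its contracts, symmetries (agent relabeling,
rescaling invariance), closed forms (matrix-power trajectories), and the
documented statistical pipeline. They do not demonstrate that real dyads
behave like the model: real behavior is multimodal, bounded, non-stationary
across a conversation, and coupled through receptivity that varies with
content — none of which the linear time-invariant map represents. Metrics
accept external two-channel CSV series (`read_trajectory()`), so the same
pipeline can be pointed at empirical data, but the package makes no claim
that the fitted regression structure transfers.

## Known limitations

* Divergent contexts dominate several aggregate statistics; conclusions
  about tail prevalence and variance explained are tied to the update
  semantics and to how divergence plays out (see above), and shift
  substantially between the synchronous and alternating modes.
* Exactly two agents, one behavioral dimension, constant `C` and `I`;
  time-varying or multi-behavior extensions are out of scope.
* The per-run correlation is a blunt summary: it cannot distinguish
  leading/following from simultaneous synchrony (use the cross-correlation
  function for that) nor division-of-labor from alternation (use turn
  lags).
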
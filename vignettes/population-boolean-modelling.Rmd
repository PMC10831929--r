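---
title: "Stochastic Boolean population models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Boolean population models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`boolpop` simulates logical models of intercellular signalling — the kind
used to describe chronic inflammatory skin disease, where keratinocytes,
innate and adaptive immune cells communicate through ligand/receptor pairs
and transcription-factor programs — as continuous-time Markov chains over
Boolean states (MaBoSS semantics), with a population layer on top
(UPMaBoSS semantics).

Each node $i$ holds a state $x_i \in \{0, 1\}$ and a logic rule
$B_i(\mathbf{x})$ over its regulators. Whenever the rule value disagrees
with the state, the node is *enabled*: it flips $0 \to 1$ at its activation
rate $k^\uparrow_i$ and $1 \to 0$ at its inactivation rate $k^\downarrow_i$
(units: per hour; time is measured in hours throughout). The joint process
is a CTMC: the waiting time to the next flip is exponential with rate
$\sum_j r_j$ over the enabled nodes, and the flipped node is drawn with
probability $r_j / \sum r_j$ (Gillespie's algorithm). A state with no
enabled node is absorbing. The quantity of interest is the marginal
activation probability $P(x_i = 1)$ per reporting window, estimated as the
ensemble- and time-averaged occupancy of state 1 within the window.

### The population layer

Cell division and death are represented by two utility nodes. The CTMC runs
in synchronous steps of `step_dt` hours; at the end of each step the
weighted distribution of joint states is adjusted:

* mass on states with the Death node active is set to zero;
* mass on states with the Division node active is doubled, and the Division
  bit is reset to 0 (daughters inherit the mother's other node states);
* when a state carries both, `death_precedence` (default `TRUE`) decides —
  the conservative reading, configurable because the convention is not
  forced by the semantics.

The total mass after adjustment is the step's growth factor, which equals
$1 + P(\text{division}) - P(\text{death})$ when the two events are
disjoint, and always lies in $[0, 2]$. It accumulates multiplicatively into
`pop_ratio`, the population size relative to $t = 0$. A cell population's
size readout is its node marginal times `pop_ratio` at the same step. If
all mass dies the run terminates with an extinction flag.

Cell communication enters through *update rules*: after every step, listed
rate parameters are recomputed from the end-of-step marginals, e.g.
`ku_IL10R = c * p(IL10)` — the more ligand present, the faster its receptor
activates. Which parameters are external is always taken verbatim from the
`.upp` file, never inferred.

### Chained perturbation runs

Treatments are simulated with a two-phase protocol: the untreated arm runs
from the trigger at $t = 0$ to `t_max` (default 600 h); the treated arm
reuses the untreated population state at `switch_time` (default 300 h),
applies the perturbation — node clamps (inhibition = fixed at 0,
activation = fixed at 1) and/or rate-parameter multipliers — and continues.
Both arms share the random stream up to and at the switch, so pre-switch
windows are *identical* and post-switch differences are treatment, not
Monte-Carlo noise. Responses are quantified per readout as

$$ \text{response} = 100 \cdot \frac{p_\text{treated} - p_\text{untreated}}{p_\text{untreated}} $$

at the evaluation time (default `t_max`), reported as not-applicable when
the untreated probability is zero. Readouts carry an explicit `measure`
column — `"marginal"` (activation probability) or `"size"` (probability ×
`pop_ratio`) — because clinical proxies like epidermal thickening are
population sizes while immune activation readouts are probabilities; the
result table always states which was used.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `n_trajectories` | 50 000 | — | ensemble size; Monte-Carlo SE $\approx \sqrt{p(1-p)/n}$ |
| `window_dt` | 1 | h | reporting window; also the default `step_dt` |
| `step_dt` | 1 | h | population step; growth bias per step is $O(d\cdot\text{dt})$ |
| `switch_time` / `t_max` | 300 / 600 | h | chained-run protocol |
| sensitivity `factor` | 0.5 | — | ±50 % one-at-a-time scan |
| sensitivity `horizon` | 200 | h | comparison horizon |
| robustness `threshold` | 0.1 | probability | deviation flag level |
| PRINCE `alpha` | 0.85 | — | smoothing/restart weight |
| CheiRank `damping` | 0.85 | — | PageRank damping on the reversed graph |
| `top_fraction` | 0.2 | — | per-metric "top" cut for the intersection |

The simulation defaults (ensemble size, window width) are this package's
own choices — reasonable Monte-Carlo practice for probabilities resolved to
two decimals — and every one is config-overridable.

## Numerical choices

**Window-wise simulation.** The vectorised engine advances the whole
ensemble one reporting window at a time and redraws the exponential waiting
time at window boundaries. By memorylessness of the exponential
distribution this leaves the law of the process unchanged; it is what makes
occupancy accounting and synchronous population updates cheap. The scalar
`simulate_trajectory()` API instead produces explicit jump sequences, one
seedable stream per trajectory derived from the master seed, so a single
trajectory can be reproduced in isolation. The ensemble engine draws from
one seeded stream: results are exactly reproducible from the master seed,
which is the contract the chained protocol relies on.

**Resampling.** Division multiplies trajectory weights by 2; over hundreds
of steps weights degenerate as $2^{\#\text{divisions}}$ and the effective
sample size $1/\sum w_i^2$ collapses, inflating variance without biasing
the mean. When the effective sample size falls below half the ensemble, the
engine performs systematic resampling (one uniform draw, stratified
positions), restoring equal weights. This is the distribution-redraw step
of population-update semantics in particle-filter form; it never triggers
in a model without division/death, so a population run with no
Division/Death nodes and no update rules reproduces the plain ensemble run
number for number under the same seed.

**Degenerate inputs.** A zero total rate is an absorbing state, not a
division by zero; marginals stay constant afterwards. Clamped nodes are
excluded from the enabled set and pinned in the initial ensemble. Rates
must evaluate nonnegative and finite under the bound parameters, and update
rules must produce nonnegative rates, both enforced at run time.
`response_pct` with a zero baseline returns `NA`.

**Propagation metrics.** PRINCE iterates
$F \leftarrow \alpha W' F + (1-\alpha) Y$ with $W'$ the symmetric
degree-normalised adjacency of the underlying undirected graph, to a
$10^{-9}$ fixed-point tolerance (the fixed point equals the direct linear
solve $(I - \alpha W')^{-1} (1-\alpha) Y$, used as the oracle in tests).
The directed, sign-aware variant ("modified PRINCE") normalises by
out-degree and carries edge signs as weights, so scores can be negative;
rankings aggregate absolute values. CheiRank is PageRank on the
edge-reversed graph (damping 0.85), scoring outgoing influence; a node with
no outgoing edges therefore cannot lead the CheiRank ordering. The
reference description of these measures leaves the aggregation
unspecified, so the choices here are: pair score = sum of pair-seeded
propagation scores over all nodes (PRINCE variants) and sum of the two
members' CheiRank; dense per-metric ranks; the "intersection" is
membership in the top `top_fraction` of *all three* metrics, intersection
members ranked first by mean rank, the rest after, ties broken
lexicographically — so the output is total, deterministic, and auditable.

**FVS counting.** "Two-node FVS" means an unordered pair of
cycle-participating nodes whose joint removal makes the influence graph
acyclic. Singleton FVSs, if any, are reported separately
(`fvs_singletons()`). Druggability filtering keeps pairs whose *both*
members are ligands, receptors or transcription factors, and reports both
counting conventions (pairs containing ≥ 1 non-druggable member vs pairs
with both druggable) in a `counts` attribute, since the two conventions
differ and published counts do not always say which was used. Utility
nodes (Division, Death, Trigger) are excluded from the influence graph for
control analyses — they are artefacts of the population layer, not disease
circuitry.

**Sensitivity aggregation.** The deviation of a variant from wild type is
aggregated per node as the *maximum* windowed absolute difference over the
horizon — the conservative reading of "deviation" — with the mean reported
alongside. Wild type and variants share the master seed by default so
common Monte-Carlo noise cancels; `shared_seed = FALSE` switches to
independent streams.

**Influence-graph signs** are syntactic: the parity of `NOT` nesting around
each regulator occurrence. A regulator appearing under both parities
contributes two opposite-signed edges, surfacing the ambiguity instead of
hiding it.

## What the synthetic models emulate — and what they do not

`make_toy_multiscale()` reproduces the *architecture* of the full
psoriasis-type model at oracle-checkable size: a trigger, an immune-cell
layer, ligand → receptor → transcription-factor chains, a proliferating
cell state wired to Division/Death, receptor rates recomputed from ligand
probabilities, and an optional cross-layer feedback loop that makes the
disease-like state self-sustaining. Rates are sampled log-uniformly within
type-specific bands of [0.01, 10] /h, with ligands decaying fast (the
standard fast-cytokine-turnover convention). Toys stay ≤ 20 nodes so the
master-equation oracle ($2^m$ states, integrated with `deSolve`) remains
exact and cheap.

What passing tests on these models shows: the *engine* implements the
stated semantics — closed forms, master-equation agreement, growth laws,
protocol contracts, enumeration and propagation identities. What it does
not show: that any particular curated disease model is biologically
faithful; that rate magnitudes transfer to real tissue kinetics; or
anything about spatial effects, which this framework cannot represent.

## Problem sizes

The shipped tests and the acceptance script use: 50 000 trajectories for
the closed-form activation check; 20 000 for master-equation and
steady-state comparisons (agreement asserted within 3 binomial standard
errors); 50 000 trajectories × 1 000 steps of 0.1 h for the birth-process
law (5 % band around $e^{dT}$, which also absorbs the $O(d\,\mathrm{dt})$
discretisation bias); 100 random 8-node digraphs against the exhaustive
FVS oracle; and 50-node graphs against the PRINCE linear solve at
$10^{-6}$.

## Known limitations

* Rates must be constant between population steps; state-dependent rate
  expressions inside a step are not supported (rate modulation happens
  through update rules at step boundaries).
* The master-equation oracle is capped at 14 nodes by memory/time of the
  $2^m$ state space.
* Exact transient solutions of large models, variance-reduction schemes,
  global (Sobol / Latin-hypercube) sensitivity analysis and FVSs of size
  > 2 are out of scope.
* SBML-qual import/export is not provided; models enter through the
  `.bnd`/`.cfg`/`.upp` dialect or the programmatic constructors.
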
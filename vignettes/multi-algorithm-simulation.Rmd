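---
title: "Multi-algorithm whole-cell simulation with a central request controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-algorithm whole-cell simulation with a central request controller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcsim)
```

## The problem

Whole-cell models describe a cell as a collection of pathway submodels,
each written in whatever mathematical formalism suits that pathway:
stochastic simulation for low-copy processes such as transcription,
ordinary differential equations for smooth kinetics, flux balance
analysis for metabolism, and Boolean rules for coarse regulation. The
submodels are not independent — they compete for the same molecule
pools (nucleotides, polymerases, energy carriers). The scientific
problem this package addresses is how to integrate such
formalism-heterogeneous submodels over a shared state without letting
any submodel observe another's uncommitted output, while keeping every
species count a non-negative integer.

## The integration meta-algorithm

One simulation step works as follows.

1. **Snapshot.** The controller freezes the global state: time, integer
   molecule counts for every global species, and current parameter
   values. The snapshot is immutable; every submodel in the step reads
   exactly this state. This is what enforces the *arrow of time*: the
   outcome of step $k$ depends only on the state at the start of step
   $k$, never on a sibling submodel's in-flight changes.
2. **Request collection.** Each dynamical submodel is integrated over
   $[t, t+\Delta t)$ on a private copy of the snapshot and returns a
   *change request*: a vector of proposed integer deltas over its
   interface species (negative = consumption).
3. **Arbitration.** The controller accepts production in full and
   checks, per species, whether total requested consumption $C_s$
   exceeds availability $A_s$ (current count plus total production in
   the step). If it does, each consumer's share is scaled to
   $\lfloor r_i A_s / C_s \rfloor$ and the remaining units are assigned
   by largest fractional remainder, ties broken by ascending submodel
   id. This apportionment is deterministic, exactly integer, and
   preserves each submodel's intent proportionally rather than starving
   any one submodel.
4. **Step adaptation.** Scaling distorts kinetics, so when any scaling
   occurred and the step may still shrink, the controller *redoes* the
   step from the same snapshot at half the step length with fresh
   (retry-indexed) random substreams. Only at the floor `dt_min` (or
   after the retry budget) does it commit scaled requests, flagging the
   step with a warning. After `clean_steps_to_grow` consecutive
   scale-free commits the step doubles, bounded by `dt_max`.
5. **Commit.** The accepted deltas are applied; the committed state is
   non-negative by construction. Boolean rules were evaluated against
   the step's snapshot; their parameter/enablement updates are applied
   now, so they take effect in the *next* snapshot. Boolean submodels
   are thus one-step-delayed observers and never write species counts
   directly — arbitration remains the sole writer of the pool.

A deliberate consequence of "production in full, consumption
curtailed": a scaled commit is not mass-conserving. That is exactly why
scaling is the last resort behind redo-at-smaller-dt, and why such
commits are flagged in the trajectory diagnostics. Conservation
invariants hold across all clean commits.

## The four engines

**SSA** (`ssa_advance`) is the Gillespie direct method: exponential
waiting times at the total propensity, reaction choice proportional to
individual propensities. The propensity convention is combinatorial,
$a = c \prod_i \binom{n_i}{s_i}$: $c$ multiplies the number of distinct
reactant combinations. Rate constants calibrated under the
permutation convention (with $s_i!$ factors) must be divided by
$\prod_i s_i!$ before use. The event whose firing time would exceed the
step end is discarded (integrate-to-barrier), so every request is
attributable to its step.

**ODE** (`ode_advance`) integrates the count-based deterministic law
$v = c \prod_i n_i^{s_i}$ — counts, not concentrations, so an SSA and
an ODE encoding of the same reaction agree in the large-count limit
with the *same* constant and no unit conversion. Integration is
classical fixed-substep RK4 with `h_max = dt/10` by default; since the
controller already adapts the outer step, a fixed inner step buys exact
reproducibility at negligible cost. The fractional part of each
continuous delta is kept in a per-species *residual carry* in
$(-1, 1)$: the integer request is `round(delta + carry)`, and over any
run of steps the summed integer requests track the summed continuous
deltas to within one molecule per species. Rounding is deterministic
nearest-integer with carry (not stochastic rounding), which is unbiased
over time without adding noise. If the rounded delta would drive the
submodel's private copy negative (possible only when coarse integration
overshoots), it is clipped at the available amount and the residual
reset to zero — the unsatisfiable deficit is dropped rather than
remembered.

**FBA** (`fba_advance`) builds a per-step linear program: maximize the
objective subject to steady state on internal metabolites
($S_{\text{int}} v = 0$), static flux bounds, and *availability*
constraints — per-reaction bounds tightened to $n_s/(k\,\Delta t)$ for
each consumed boundary species, plus an aggregate row limiting the
total consumption of each boundary species to $n_s/\Delta t$. An FBA
request alone therefore can never overdraw a pool. Optimal boundary
fluxes convert to deltas as flux $\times\,\Delta t$ with the same
residual-carry integerization as the ODE engine; internal metabolites
contribute no deltas. Fluxes are in molecules per second to match the
integer pool; models calibrated in mmol/gDW/h must be rescaled by
(cell mass $\times N_A$ / 3600). Degenerate optima are accepted: the
objective value is unique and is the only quantity used downstream;
the flux split is solver-dependent. An infeasible or unbounded LP
degrades to a flagged zero request — a cell whose metabolism halts for
a step — rather than aborting the run.

**Boolean** (`evaluate_rules`) evaluates threshold predicates (a single
species count or parameter compared against a constant, combined with
and/or/not) against the snapshot, synchronously: rule order can never
change the update set, and two true rules disagreeing about one target
are an error, not a race. Comparison at an exact threshold follows the
declared operator with no epsilon adjustment — counts are integers.

## Randomness and reproducibility

Every stochastic draw happens under a seed derived by hashing (master
seed, submodel id, step index, retry index). Because a submodel's
substream depends only on those labels — never on how many draws other
submodels made — the invocation order is unobservable in the results,
and a redone step gets independent draws from the same snapshot.
Identical (model, config) inputs give bit-identical trajectories.

## Composition: manifest, not hierarchical SBML

Each submodel is a standalone SBML Level 3 core document (mass-action
kinetic laws, integer initial amounts with substance-units semantics,
FBC bounds/objective for FBA). Composition is declared in an explicit
JSON/YAML manifest: formalism per submodel, an explicit local-to-global
species identity map (`<name>_<compartment>` by convention, never
inferred by string matching), global initial counts, parameters, and
the Boolean rules. Hierarchical-composition packages and shared-variable
experiment descriptions could express the same thing, but neither is
widely supported by tooling; a manifest keeps each submodel file
independently valid while making the shared-species map a first-class,
reviewable artifact. Because per-submodel files can disagree about
initial values, the manifest's global counts are authoritative and
per-file amounts are ignored at composition time — one precedence rule
instead of a reconciliation problem. Everything outside the documented
SBML subset (events, rate/assignment/algebraic rules, constraints,
initial assignments, function definitions, non-mass-action laws) is
rejected with an error naming the construct, never silently dropped.
One codec limitation: a reversible reaction is split into `_fwd`/`_rev`
halves that share the single parsed constant, because the subset's
kinetic law carries one constant; encode direction-specific kinetics as
two irreversible reactions.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `dt_init` | s | 1 | starting step; problem-dependent |
| `dt_min` | s | `dt_init/8` | floor below which scaling is accepted |
| `dt_max` | s | `dt_init*4` | cap on step growth |
| `clean_steps_to_grow` | steps | 3 | hysteresis before doubling the step |
| `max_retries` | — | 8 | redo budget per step |
| `output_stride` | steps | 1 | thinning of recorded rows |
| `h_max` (ODE) | s | `dt/10` | RK4 substep; halving it cuts error ~16× |

## What the generators emulate — and what they do not

`make_transcription_submodel()` builds the lumped encoding of
transcription: one stochastic reaction per RNA species,
RNAP + (composition) NTPs → RNAP + RNA, with no per-base elongation
reactions and no explicit DNA–protein binding. An optional variant adds
a small Markov model of polymerase availability (free ↔ non-specifically
bound). `make_minimal_cell_model()` wires four submodels — SSA
transcription, ODE RNA degradation (recycling nucleotides), FBA
metabolism importing glucose through a membrane transporter, and a
Boolean degradation throttle — across exactly three compartments
(extracellular, membrane, cytosol). Default constants are arbitrary but
chosen once so a 10-second demonstration stays in the
hundreds-of-molecules regime with no request conflicts: transcription
fires about once per second per RNA, degradation at 0.05/s, uptake at
40 molecules/s against a 600-molecule glucose reserve, and growth at
8/s so nucleotide pools hold roughly steady.

These fixtures exercise every code path but are not biology: real
whole-cell models have dozens of submodels, thousands of species,
measured rate constants spanning many orders of magnitude, and strong
coupling (e.g. protein occupancy of the chromosome) that the shared-pool
interface only approximates. Passing tests show the *integration
machinery* is correct — exact arbitration arithmetic, non-negativity,
conservation across clean commits, convergence of the operator
splitting as the step shrinks — not that any particular cell's biology
is captured.

`make_random_hybrid_model()` is a fuzz surface: seeded, deterministic
random SSA/ODE submodels over an overlapping species pool, used to
assert that no committed state is ever negative under arbitrary
composition.

## Numerical choices and problem sizes

Verification runs use deliberately small problems so the full suite
stays fast and exactly reproducible:

* the immigration–death process ($b = 10$/s, $d = 0.1$/s) has
  stationary mean and variance $b/d = 100$; 20 replicate windows of
  100 s (discarding the first 50 s as burn-in, about five relaxation
  times $1/d$) put the time-average within 3 standard errors of 100;
* LP objectives are checked to $10^{-9}$ against brute-force vertex
  enumeration on all fixture polytopes with at most 6 reactions;
* the hybrid convergence experiment couples A→B (SSA, $k_1 = 0.2$/s)
  to B→C (ODE, $k_2 = 0.05$/s) with $A_0 = 250$ over 10 s and compares
  mean $C(10)$ against a pure-SSA simulation of the full network at
  $\Delta t \in \{1, 0.5, 0.25\}$, 200 replicates each. The constants
  come from a power analysis on the closed-form mean and variance of
  the linear chain: the operator-splitting bias at $\Delta t = 1$
  (several molecules) must stand clearly above the Monte-Carlo standard
  error (~0.5), while the bias at $\Delta t = 0.25$ must sit inside the
  3-SE acceptance band — so the monotone decay of the coupling error is
  resolvable and its small-step limit is statistically indistinguishable
  from the exact process;
* conservation is asserted exactly (integer arithmetic) over $10^4$
  committed steps of a closed two-state toggle, and non-negativity over
  100 seeded random hybrid models.

Other numerical decisions: propensity overflow raises an error naming
the reaction (relevant for high-order lumped reactions, whose
combinatorial factors grow astronomically — choose constants under the
combinatorial convention accordingly); infinite flux bounds are capped
at $10^{12}$ inside the solver and an optimum pressed against the cap
is reported as unbounded; the final step of a run is clamped to end
exactly at `t_max`.

## Known limitations

* No tau-leaping or next-reaction optimizations; the SSA engine is the
  plain direct method, so stiff high-propensity systems are slow.
* No stiff ODE solver, events, or algebraic constraints; fixed-substep
  RK4 assumes smooth, non-stiff kinetics within a step.
* No parsimonious FBA or flux variability analysis; only the objective
  value is reproducible across solvers.
* Boolean effects are restricted to parameters and reaction
  enablement; rules cannot write species counts.
* Submodels run sequentially in one process; the per-submodel stream
  design makes results order-independent (logical concurrency), but
  hardware parallelism is out of scope.
* Trajectory export is CSV; the layout is lossless for integer counts.
* The sequential integration strategy is available as a reference mode
  (`mode = "sequential"`) for comparison; it is first-order in the
  step length and not recommended for production runs.
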
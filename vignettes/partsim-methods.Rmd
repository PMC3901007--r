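---
title: "partsim: model language, simulator semantics, and packaged examples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{partsim: model language, simulator semantics, and packaged examples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partsim)
```

## The modeling idea

`partsim` describes dynamical models of neural and cellular systems as
**parts**: named, largely self-contained equation sets (a neuron, an ion
channel, a synapse, a stem cell).  A part's attributes are its variables,
and each equation states how one variable is defined or evolves:

```
part Decay
  tau = 10
  V = 1 @ $init
  V' = -V / tau
```

Order-0 unconditioned equations are algebraic definitions (constants or
expressions recomputed from the current state); primed targets are time
derivatives (`V'`, and `x''` for second order, integrated through a
companion first-order state); an `@` clause restricts an equation to the
steps on which its condition holds, with `@ $init` marking
initialization.  Metadata travels with the part (`$meta`), including
measurement notation with uncertainty (`12481.9 ± 2998.9 um`), and
`$ref` attaches citation keys.  Dollar-prefixed names are reserved
built-ins: `$t` (time), `$dt` (step), `$n` (population size), `$p`
(connection predicate/probability), `$type` (type transition), `$index`
(instance id), `$init`.

Two composition mechanisms combine parts:

* **Inheritance (is-a)** — a part absorbs all equations and metadata of
  its parents; a definition in the child *hides* any same-named
  definition in a parent.  With multiple parents the child wins over
  all of them and, among parents, the leftmost listed wins.  The
  defining part of every surviving equation is kept as provenance.
* **Inclusion (has-a)** — an included part's definitions are embedded
  under a dotted prefix (`Na.gbar`), to any nesting depth; a prefixed
  definition in the includer hides the included one.  References to
  names the included part defines are rewritten under the prefix;
  references it leaves free (and all `$`-builtins) bind in the
  including scope.  This is what lets an ion-channel part read the
  membrane potential `V` of whatever compartment hosts it.

A **model** is itself a part whose inclusions become *populations*
(ordinary parts; initial size from `$n`, default 1) and *connection
templates* (parts with a `connect A = X, B = Y` declaration).  An
equation set is a template for stamping out instances: at run time each
population holds per-instance state vectors, and connection instances
are created for endpoint pairs accepted by the template's `$p`
equation — a predicate (`A.$index + 1 == B.$index` for a cable), a
probability, or any mixture.  Connection equations address endpoint
variables through the declared aliases (`A.V`, `B.gE`) and *add* their
contributions, so converging synapses compose.

## Simulator semantics

Each step is synchronous:

1. previous-step values are saved for edge detection;
2. per-step random algebraic values (`uniform()`, `gaussian()`) are
   drawn once;
3. derivatives are evaluated from the stage state — population
   algebraic equations in dependency order, then local derivatives,
   then connection contributions summed into their endpoints'
   derivative accumulators;
4. every state variable advances by explicit Euler or classical RK4;
5. conditioned order-0 equations whose condition holds assign after the
   advance; `crossed(x, th)` is true exactly on steps where `x` was
   below `th` and now is not (one-step resolution, no sub-step
   interpolation);
6. structural `$type` transitions apply *between* steps: an instance
   whose condition fired becomes the listed parts — `[]` is death,
   `[Q]` differentiation, `[Q, R]` a split.  Values with matching names
   are copied into each new instance (after the target part's own
   `@ $init` equations run), all new instances get fresh ids — ids are
   never reused — and new candidate pairs are immediately eligible for
   connection wiring.  When several `$type` equations could fire for
   one instance, the first in (canonical) template order wins; the
   packaged lineage models sidestep order-dependence entirely by
   writing mutually exclusive outcomes as disjoint two-sided bands
   (`u >= lo && u < hi`) over one per-step uniform draw, omitting
   zero-width bands so degenerate rates (an event probability of 0 or
   1) stay well-defined.

A variable may be defined *either* by an unconditioned algebraic
equation *or* by a derivative/event pair, never both; the planner
rejects the ambiguous combination.  Conditions evaluated after the
advance should reference state variables, per-step draws, or constants;
state-dependent algebraic values are refreshed before structural
decisions.  Any non-finite state aborts the run naming the variable and
instance.

All arithmetic is vectorized over instances: expressions are compiled
once into R language objects and evaluated in per-population
environments whose bindings are instance vectors, with scatter-adds for
connection sums.  This keeps the reference semantics transparent while
making desk-scale networks (a few thousand instances) tractable.

**Randomness and repeatability.**  One run seed drives three derived
sub-streams — connection wiring, structural decisions, and noise
functions — so a change in one consumer's draw count cannot perturb the
others.  Child seeds are SHA-256 derivations truncated to 31 bits
(valid R seeds).  Identical (model, configuration, seed) gives
bit-identical results, including the event log; ensembles additionally
share one wiring seed across runs (recorded in the manifest) so all
runs see the same network structure while dynamics seeds vary.

## Ensembles

Any order-0 constant in the compiled model can be swept by dotted path.
Step designs form inclusive, evenly spaced grids crossed
full-factorially (two 11-level parameters give 121 runs); Monte-Carlo
and Latin-hypercube designs draw jointly, the latter using one draw per
stratum with independently permuted strata per parameter (via the
`lhs` package).  The manifest records the model content hash (SHA-256
of the canonical serialization), every assignment, and every seed —
enough to re-execute any run byte-identically.

## Packaged examples and their constants

**HH cable.**  Seven parts: an abstract ohmic channel; Na and K
channels inheriting from it with the classic squid-axon rate functions
(resting potential near -65 mV; `gNa` 120, `gK` 36, `gleak`
0.3 mS/cm², `ENa` 50, `EK` -77, `Eleak` -54.387 mV, `C` 1 uF/cm²); a
passive compartment; the HH compartment that inherits it and includes
both channels; a cable-coupling connection implementing the
antisymmetric pair `A.V' += g_r (B.V - A.V)`, `B.V' += g_r (A.V -
B.V)` with `g_r` 0.3 mS/cm² between `$index`-adjacent compartments;
and the three-compartment model.  The compartment area is fixed at
100 um² so a 10 pA injection is 10 uA/cm² — comfortably
suprathreshold — and the current steps on at t = 1 ms so the resting
level is read off the pre-onset trace.  Rate-function denominators
carry a 1e-9 offset to keep the removable singularities finite; the
perturbation is orders of magnitude below integration error.  At dt =
0.01 ms with RK4 the injected compartment fires a ~104 mV spike
(peak minus rest) that reaches compartment 3 after a delay of roughly
2 ms.

**80/20 E-I network.**  One population of N conductance-based HH
neurons with Traub-Miles kinetics and threshold parameter VT = -63 mV;
one conductance-based exponential synapse part included twice, E and I
differing only by model-level overrides (weight `we`/`wi`, reversal
0/-80 mV, decay 5/10 ms); excitatory templates restrict *sources* to
`$index < 0.8 $n`, inhibitory to the rest, so E/I identity attaches to
the presynaptic cell; and a small Poisson spiker population that kicks
the network through a separate input synapse for the first 50 ms.
Two constants depart deliberately from the large-network benchmark
this follows: the leak reversal is -65 mV so an undriven neuron is
quiescent (the silent regime must be reachable), and peak Na/K
conductances are 6000/1800 nS so explicit Euler at dt = 0.05 ms stays
stable across the whole conductance sweep; spikes still overshoot
0 mV, the raster threshold.  Recurrent connectivity is 10% rather
than the benchmark's 2%: at N = 200, two-percent wiring would leave
in-degrees near 2 and no recurrent dynamics to observe.  The packaged
sweep covers `we` in [0, 8] nS and `wi` in [0, 67] nS (11 levels each,
121 runs; a 5x5 variant for quick reports).  Within that range all
four regimes appear: silent (no recurrent ignition), hyperactive
(strong E, weak I), skewed (weak E with moderate I — only a
well-connected subset sustains activity), and asynchronous (moderate
rate, broad participation) toward the balanced corner.  Regime labels
use transparent thresholds — silent below 0.5 Hz mean rate,
hyperactive at 50 Hz with participation at least 0.5, skewed when
participation falls below 0.5 — and the Gini coefficient of
per-neuron rates is reported as the dispersion measure.  Above `we`
around 10-15 nS the mean rate *falls* again with E (depolarization
block), and very strong inhibition can itself drive rebound firing;
both effects are real features of HH dynamics at these scales and are
why the packaged range ends at 8 nS.

**Structural dynamics.**  The growth cone draws one uniform variate
per step and tests it against cumulative probability bands: elongate
(`[Segment, GrowthCone]`), branch (`[Segment, GrowthCone,
GrowthCone]`), differentiate (`[Segment]`), die (`[]`); defaults 0.2 /
0.05 / 0.01 / 0.01 per step.  The neurogenesis lineage has a radial
glial cell dividing asymmetrically (`[RadialGlia, Progenitor]`, p =
0.05 per step) and progenitors dividing symmetrically (0.1),
differentiating into granule cells (0.05), or dying (0.05).  Both are
branching processes whose expected counts obey linear recursions
(e.g. cones multiply by `1 + b - f - d` per step); the tests recover
these against independent matrix-power oracles within Monte-Carlo
error, 3 standard errors at 1000 replicates.

## What the synthetic examples do and do not show

The fixtures exercise every language and runtime feature at desk
scale: composition depth, connection coupling, event-driven synapses,
probabilistic structural change, sweep machinery.  Numbers produced at
these sizes (N = 200 networks, 1 s of activity, per-step lineage
probabilities) characterize the *software*, not biology: the E-I
regime map's precise boundaries depend on the desk-scale constants
above and would shift at benchmark scale, spike rates in the
hyperactive corner are far beyond cortical rates, and the lineage
models compress development into a handful of steps.  Passing tests
demonstrate correct semantics and reproducibility, not quantitative
agreement with any biological dataset.

## Numerical choices and limitations

* Fixed-step synchronous integration only (default dt = 0.01 ms for
  the neural examples; the E-I sweep uses 0.05 ms with Euler for
  throughput, sized so the full 5x5 report runs in minutes on one
  CPU).  No adaptive stepping, no implicit methods, so stiff regimes
  bound the usable dt; the E-I fixture's conductance scaling is chosen
  accordingly.
* Event detection is edge-triggered at one-step resolution; spikes
  shorter than dt are missed, and a synapse sees a presynaptic spike
  one step after the crossing.
* Candidate-pair enumeration is O(|A| x |B|) at wiring time and after
  structural changes; fine for thousands of instances, wrong for
  millions.
* `$p` is re-evaluated only for *new* candidate pairs after structural
  changes; existing connections are never re-drawn, and a split's
  children get fresh wiring draws with fresh ids (lineage is in the
  event log).
* Sequential execution; results are ordered by run index, and a
  process-parallel executor would have to preserve the per-run seeds
  to remain manifest-compatible.
* Units are opaque tokens in metadata and comments; nothing checks
  dimensional consistency.
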
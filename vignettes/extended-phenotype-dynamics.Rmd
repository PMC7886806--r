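---
title: "Extended-phenotype dynamics on scale-free networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-phenotype dynamics on scale-free networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epmoran)
```

## The question the package addresses

Extended phenotypes — nests, webs, dams, food hoards — are gene effects
expressed outside the body of the organism carrying the genes. Because they
are physical objects, they can outlive their builder and be taken over by a
conspecific, so their fitness effects are not confined to the individual
that produced them. `epmoran` is a simulation platform for asking how much
that *shared use* contributes to the success of a population: two
populations, identical except in how they produce, use and share
extended-phenotype tokens, compete on the same contact network until one of
them takes over.

## The population model

Individuals are the nodes of an undirected contact graph. The package grows
Barabási–Albert scale-free graphs (`generate_ba_graph()`): starting from
`m` isolated seed nodes, each new node attaches `m` edges to existing
nodes with probability proportional to current degree. The default is
`n = 500`, `m = 4`, which gives exactly `m (n − m) = 1984` edges and a
heavy-tailed degree distribution similar to many natural contact networks.
Note that `m` bounds the degree of *grown* nodes from below; the initial
seed nodes can end up with fewer edges, which is a property of the standard
construction rather than a defect.

Evolution follows a death–birth Moran process. Each cycle,
`round(renewal_rate × N)` sequential events occur (20 per cycle at the
defaults): a node chosen uniformly at random dies, and one of its
neighbours is chosen to reproduce into the vacancy with probability
proportional to *relative fitness*. The newborn inherits the parent's
type. There is no mutation: the two types A and B, seeded 250/250 at
random positions, can change in frequency only through replacement, and a
run ends when one type **fixes** or when the cycle limit is reached, in
which case it is classified **undefined**.

The same node can die more than once per cycle (events are sequential with
immediate replacement), and fixation is checked at cycle boundaries only.
Both choices follow the per-cycle structure of the process; checking
mid-cycle would change undefined counts slightly.

## Extended-phenotype tokens

A token represents one extended phenotype. It is attached to at most one
node, and it expires `ep_lifetime` cycles (default 30) after creation.
The timer is decremented once at the end of every cycle and — this matters
— it is *not* reset when the token changes hands: a token with 10 cycles
left when its owner dies still has 10 cycles left for the next owner.

When a token holder dies, the token is offered to a new holder before the
newborn is placed (the newborn itself is never a candidate):

* **Framework 1** (birth-attached tokens): a token-less node of the *same
  type* as the deceased, chosen uniformly among neighbours first, then
  among all such nodes in the graph; reuse is conspecific-only, and a type
  with `gamma = -1` never reuses. If no candidate exists the token
  vanishes. This mirrors how, say, an abandoned web is only useful to a
  conspecific spider.
* **Framework 2** (behavioural states): a token-less node *in the
  searching state* of any reuse-capable type, neighbours first, then
  graph-wide; the recipient switches to the using-other state. The
  searching requirement replaces the type clause here because searching is
  what defines receptivity in this engine.

## Framework 1: fitness from possession

Nodes holding a token have relative fitness `1 + alpha` of their type;
everyone else has fitness 1. Tokens enter the population at initialisation
(each node of a producing type starts with a token independently with
probability `birth_ep_chance`, default 0.5, with full timer) and at birth
(same probability, producing types only). The two classic experimental
configurations are:

* only type A produces and reuses (`produces_b = FALSE`, `gamma_b = -1`);
* both types produce, only A reuses (`produces_b = TRUE`, `gamma_b = -1`).

```{r, eval = FALSE}
cfg <- sim_config(framework = 1, alpha_a = 0.05, alpha_b = 0,
                  gamma_a = 0, gamma_b = -1,
                  produces_a = TRUE, produces_b = FALSE)
batch <- run_batch(cfg, n_graphs = 20, samples_per_graph = 100)
glance(batch)
```

## Framework 2: fitness from behaviour

Each node occupies one of four behavioural states with these relative
fitness values:

| state       | fitness       | meaning                                   |
|-------------|---------------|-------------------------------------------|
| searching   | `1`           | default; waiting to find an abandoned token |
| producing   | `1 − beta`    | paying the cost of building a token       |
| using own   | `1 + alpha`   | using the token it built                  |
| using other | `1 + gamma`   | using a token built by a dead conspecific |

A node that searches for `state_time` cycles (default 30) starts producing
(unless its type has `beta = -1`, a behavioural switch meaning "never
produces"); after `state_time` producing cycles it creates a fresh token
and uses it; when the token expires it searches again. Receiving an
abandoned token moves a searcher to using-other immediately, within the
death–birth event. Newborns always start searching, token-less, so
`birth_ep_chance` is forced to 0 in this engine. Residence counters are
incremented in the end-of-cycle sweep, which runs after all death–birth
events of the cycle, in the order: residence transitions first, then one
timer decrement for every token (so a token created this cycle ends it with
`ep_lifetime − 1` remaining).

### The fitness algebra

At the population level the three bonuses combine into an absolute fitness

\[ \omega_i = \alpha_i - \beta_i + \gamma_i , \]

and sharing is worth favouring when \(\gamma / (\alpha - \beta) > 1\).
`fitness_table()` enumerates the mirrored grid used to compare populations
at *equal* omega: A takes `(alpha, gamma) = (x, y)` and B the mirror
`(y, x)` with `x + y` constant, so any systematic winner reveals which
component of omega matters, not a fitness difference. `project_abundance()`
implements the companion abundance recurrence `n(g+1) = omega * n(g)`
literally; note that omega as defined is typically well below 1, so the
recurrence is a bookkeeping identity rather than a growth model, and the
simulators do not use it.

### Initial behavioural states

The initial distribution over states is configurable (`init_*` fractions,
assigned by largest-remainder rounding to exact counts at random
positions). The default starts **everyone searching with no tokens**. This
is a deliberate design choice: seeding part of the population directly
into token-holding states hands whichever population profits more from
those states a transient selective advantage lasting tens of cycles — for
instance, starting half the population in using-own gives the
higher-alpha type a head start of a full token lifetime before any
sharing dynamics can act, which would contaminate precisely the
equal-omega comparisons the second engine exists for. An all-searching
start is transient-neutral: every bonus any node ever receives is
generated by the dynamics themselves.

## Batches, sweeps and reproducibility

`run_batch()` runs `n_graphs` independently generated graphs ×
`samples_per_graph` runs per graph. The seed schedule is deterministic:
graph `g` is generated with `base_seed + g` and sample `s` on graph `g`
runs with `base_seed + g × samples_per_graph + s`, so any record can be
reproduced in isolation from its stored seed, and aggregation is a pure
fold over the per-sample table (`summarise_samples()` recomputes a summary
from a saved TSV bit-for-bit). Sweeps (`sweep_alpha()`,
`sweep_omega_ratio()`, `sweep_equal_omega()`) offset the schedule by a
fixed stride per grid point so all seeds stay pairwise distinct.

All randomness flows through R's RNG, including inside the compiled
engine, so `(graph, config, seed)` triples reproduce byte-identical
outcomes across platforms with the same RNG defaults.

## Validation strategy and the exact oracle

The death–birth core is validated against an exact solution. With tokens
disabled and a constant per-type baseline fitness, the process is a
classical Moran chain whose state space on a small graph
(`≤ 12` nodes, `2^N ≤ 4096` states) can be enumerated;
`exact_fixation_probability()` builds the sparse one-event transition
matrix (uniform death, fitness-weighted neighbour parent) and solves the
absorption system for fixation of type A with a direct sparse solve. The
oracle runs one event per cycle to keep the chain first-order; batching
events into cycles does not change absorption probabilities because events
are sequential and identically distributed.

`monte_carlo_agrees_with_oracle()` then runs the *actual* simulator in the
same regime and accepts when the observed fixation fraction is within
three binomial standard errors of the exact value. The gate is calibrated
by a deliberate mutant: `parent_selection = "uniform"` ignores fitness
when choosing the parent, and under selection this mutant must fail the
gate — if it did not, the gate would be too weak to certify anything.
Token mechanics, which the exact chain cannot cover (the state space with
timers is astronomically larger), are validated by construction-level
tests instead: deterministic timer-carry-over scenarios, conspecific-only
transfer, uniformity of recipient choice (chi-square), conservation
invariants, and an exhaustive per-token event-log audit showing no token
outlives `ep_lifetime` cycles across any chain of transfers.

## Numerical choices

* Probabilities proportional to fitness are normalised exactly
  (`selection_weights()` sums to 1 within 1e-12); the engine samples by
  cumulative weight in one pass.
* `round(renewal_rate × N)` uses half-up rounding, so the default 4% of
  500 is exactly 20 events.
* The oracle caps the state space at `2^12` and solves with a sparse
  direct method; absorption probabilities from the monomorphic states are
  exactly 0 and 1 by construction.
* Initial tokens carry a full fresh timer (`initial_ep_lifetime`,
  default `ep_lifetime`); the alternative of randomised initial ages is
  exposed through the same option.
* Odd population sizes split `floor(N/2)` type A, remainder type B.
* The cycle limit defaults to 5,000. Undefined fractions are by definition
  conditional on this choice: a longer limit converts some undefined runs
  into fixations.

## Problem sizes used in the validation suite

The package's own test and acceptance runs use desk-scale replication:
batches of 20 graphs × 100 samples (2,000 runs) per framework-1
experimental condition — the binomial 95% half-width at 2,000 runs is
about 2.2 percentage points — an alpha sweep at reduced per-point
replication for the monotonicity check, and the framework-2 equal-omega
comparison at the full population size (`N = 500`; selection differences
this subtle need the weakest drift affordable) with 10,000 runs per cell,
one cell per distinct
alpha/gamma pair at a representative production cost (mirrored pairs are
the same comparison with the population labels swapped, and the cost axis
does not move the A:B proportions). Oracle comparisons use 3- and 4-node
fixtures at 10,000 runs. These sizes are the package's choices for routine
validation; all of them scale up by changing `n_graphs`,
`samples_per_graph` and `n_nodes`.

## Known limitations

* The synthetic populations are stylised: two types, no mutation, no
  cheater genotypes (types that reuse but never produce), no modification
  of occupied tokens, and a single graph family. Regular lattices (e.g.
  for biofilm-like systems) are not generated here, though any edge list
  with the documented invariants can be supplied.
* Searching carries no cost, and token encounters are modelled as
  fortuitous (neighbours first, then anywhere), not as spatial search.
* The exact oracle certifies the death–birth core only; token mechanics
  are validated by invariants and symmetry/monotonicity properties, not by
  closed-form results.
* Fixation-fraction differences between populations at equal omega are
  small relative to binomial noise at desk-scale replication; detecting
  them reliably in every grid cell requires replication closer to the
  full-scale design than to the reduced sizes used in routine tests.
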
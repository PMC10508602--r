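---
title: "Collective dynamics on hypernetworks: the model behind hyperurn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective dynamics on hypernetworks: the model behind hyperurn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperurn)
```

## The model

`hyperurn` simulates a population of `m` individuals who each make one
binary choice (RED or BLUE) in random order, under three competing forces:

* **Social influence** (`ps`): with probability `ps` the decider imitates a
  uniformly drawn group-mate who has already decided. Imitation is the
  Pólya-urn mechanism — every adoption makes future adoptions of that
  colour more likely — restricted to the decider's *local urn*, the set of
  decided members of its own groups.
* **Conformity** (`pc`): failing imitation, with probability `pc` the
  decider adopts the *purpose* (group norm) of one of its hyperedges,
  sampled uniformly when it belongs to several. Purposes are drawn RED
  independently per hyperedge with probability `delta1`.
* **Personal preference** (`qs`): otherwise the decider chooses RED with
  probability `qs`. The shipped designs use `qs = 1`: RED is the
  quality-1 product, BLUE the quality-0 product, so any BLUE dominance is
  purely social.

The population lives on a **hypernetwork**: hyperedges are groups
(workplaces, communities, parties) of arbitrary size, and an individual's
neighbourhood is the union of its groups. A single hyperedge covering
everyone recovers the classic fully-mixed urn; many small hyperedges
localise influence.

The process is seeded by an initial urn of ten balls placed on random
nodes: a *false* start (1 RED, 9 BLUE — popularity contradicts quality),
an *equal* start (5, 5), or a *correct* start (9, 1).

### Decision order and degenerate corners

One decision happens per time step. The decider is drawn uniformly among
undecided individuals whose local urn is non-empty (the printed procedure
re-draws individuals with empty urns; uniform selection over the non-empty
set is the equivalent limit). If *no* undecided individual can see a
decided neighbour — possible with zero seeds or disconnected structures —
a uniformly drawn undecided individual decides through the non-social
branch (`pc` norm, else `qs`), the same rule the first mover in an empty
market follows. An individual belonging to no hyperedge (allowed when
loading external structures, warned about) has no norm to consult and
falls through to preference.

## Exact mean-field theory

Within one fully-mixed group the model admits closed-form recursions,
implemented in the `analytic_*`/`*_recursion` functions. Writing
`alpha = delta * pc + (1 - pc) * q` for the baseline (non-social) RED
probability, entrant `t` facing `T = B + t - 1` prior deciders with `c`
RED among them picks RED with probability `ps * c / T + (1 - ps) * alpha`
(just `alpha` at `T = 0`). `distribution_recursion()` propagates the full
probability vector of RED counts (no truncation, `O(n^2)` work — exact to
machine precision at the desk scales we target, `n` up to a few thousand).
The printed three-branch recursion for the seeded market contains an
internal inconsistency in its `j = 0` boundary line (an occupancy factor
that contradicts the unrolled small-`n` expansions); the single general
step rule above reproduces the unrolled expansions term-for-term and is
what we implement, verified in the tests against brute-force enumeration
of all `2^n` choice sequences.

Because the next-choice probability is linear in the current share, the
expected share obeys the exact one-line recursion implemented in
`expected_share_recursion()`, and for `ps < 1` converges to

```
M*  =  delta * pc + (1 - pc) * q  =  (delta - q) * pc + q,
```

linear in `pc` with slope `delta - q`: norms pull the market toward
`delta`, preference anchors it at `q` (`convergence_value()`). At
`ps = 1` the share is a martingale with a run-specific random limit — the
classic Pólya result — and `convergence_value()` refuses to answer.

Two quantitative consequences matter for testing and are easy to miss:

* **Mixing is polynomial.** From a seeded start the gap to `M*` contracts
  by `(1 - (1 - ps)/(B + t))` per entrant, i.e. decays like
  `(B/(B+n))^(1-ps)`. At `ps = 0.75` a false-started market is still
  ~0.1 away from its limit after 10,000 entrants; tests that expect
  near-convergence at practical horizons are testing the wrong thing, and
  our convergence checks therefore assert the *exact* gap law
  (gamma-function closed form) rather than an arbitrary closeness.
  From the empty urn the expected share equals `M*` at every `n` exactly.
* **"No point convergence" needs a long horizon.** At the experimental
  scale `m = 100` the `ps = 1` and `ps = 0.5` final-share variances differ
  by only ~1.3x (exact recursion values) because neither process has
  mixed. The martingale-vs-convergence contrast is therefore checked at
  `m = 2000` with the norm pinned RED, where the exact variance ratio is
  25.8.

## Ensemble statistics

Following the independent-worlds experimental tradition, every
configuration is rerun `W = 500` times (fresh seed nodes, fresh norm
draws) and summarised by:

* **Market share** `M_i = N_i / m`, seeds included.
* **Unpredictability** `u_s`: the mean pairwise absolute difference of a
  colour's final share across runs, `sum_{i<j} |M_i - M_j| / C(W, 2)`;
  `U` averages `u_s` over colours (with two colours and complete decisions
  the two are identical). Computed by the sorted-order identity in
  `O(W log W)`, with the literal double loop retained as a test oracle.
* **Inequality** `G`: the Gini-type index
  `sum_{i<j} |M_i - M_j| / (2 N sum_k M_k)` over the `N = 2` colours of a
  run. This is the printed formulation and is implemented verbatim even
  though a textbook Gini would divide by `2 N^2 mean(M)`; for two colours
  summing to one it equals `|M_RED - M_BLUE| / 4`, maximal at 0.25. The
  textbook denominator is available via `inequality(standard = TRUE)`.
  Inequality is computed per run and averaged (one value per parameter
  cell); applying it to ensemble-mean shares instead is reported as
  `inequality_of_mean`.
* **Time-resolved unpredictability**: `u` computed on the share-so-far at
  each decision index, dividing by the number of deciders at that index.
  Time is measured in decision events (index 0 = the seeded state); we do
  not use a "per propagation" unit because its printed definition is
  ambiguous.

## Generators: what the synthetic structures emulate

`generate_uniform_hypernetwork()` draws uniform structures (every
hyperedge the same size) with guaranteed coverage: each node first claims
one slot in a random hyperedge with spare capacity, then remaining slots
fill uniformly without within-edge duplicates. The degree distribution
this induces is a design choice — the membership pattern of the original
experiments is not recoverable — so it is documented rather than claimed.

`generate_overlapping_hypernetwork()` adds a controlled marginal
multi-membership rate (default 0.5, the base design's stated property):
nodes are flagged independently with that probability and flagged nodes
preferentially fill the extra slots. The base experimental structure is
100 nodes in 15 hyperedges of 10 (150 slots, so 50 extra memberships).

For the hyperedge-count sweep (`sweep_hyperedge_count()`) the membership
density is held at the base structure's 1.5 slots per node:
`edge_size = min(m, ceiling(1.5 m / edge_count))`, so one hyperedge
degenerates to the fully-connected network and 30 hyperedges have 5
members each. Holding density rather than edge size keeps structures
comparable as the count varies.

These generators emulate group *membership structure* only: no homophily,
no degree heterogeneity beyond the membership lottery, no dynamics on the
structure (it is static throughout a run). Passing tests on these
structures say nothing about real social systems with correlated group
membership.

## Reproducibility and numerics

All randomness flows through R's RNG. Generators take an optional `seed`
and restore the ambient RNG state; `run_ensemble()` seeds run `w` with
`base_seed + w - 1`, and within a run's substream the structure factory
(norm redraw) fires before seed-node selection, then the dynamics. The
inner simulation loop is compiled (Rcpp) but draws from the same RNG; a
pure-R stepper (`decide_one()`) implements the identical rule and is held
to the exact mean-field distribution in the tests (chi-square at small
`m`), so the compiled and reference paths are cross-validated
statistically rather than bit-for-bit (they consume the stream
differently).

Numerical choices: probability vectors are propagated in full (no
truncation, normalisation asserted to 1e-12); the sorted-order
unpredictability avoids the `O(W^2)` loop but is verified against it to
1e-12; urn ties never arise because exactly one individual decides per
step. Degenerate inputs (empty local urns everywhere, nodes without
groups, zero-seed starts, `B = 0` initial urns in the analytic layer) are
either handled by the documented fallback or rejected with typed errors
(`hyperurn_invalid_config`, `hyperurn_invalid_hypernetwork`,
`hyperurn_no_unique_limit`).

## Design decisions on genuinely open points

* A neighbour sharing several hyperedges with the decider contributes
  *one* ball to the local urn (one choice per neighbour); weighting by
  shared edges is a noted alternative, not implemented.
* A multi-group decider conforming to "its" norm samples one of its
  hyperedges uniformly per decision.
* Seeds count toward market share and are imitable deciders (the global
  urn is initialised with them).
* Whether norms are redrawn per run is configurable: pass a hypernetwork
  for a fixed draw or a factory for per-run redraws. Sweeps redraw per
  run (the norm lottery is part of the between-run variability whenever
  `delta1` is a swept parameter); the analytic comparison supports both
  conventions (`purpose = "redraw"` uses `delta = delta1` in the
  recursion — exact by linearity — and `purpose = "fixed-red"` uses
  `delta = 1`).
* Directional ensemble claims are tested at pre-registered cells: the
  U-vs-`ps` trend on per-`ps` means over `pc` in {0, 0.5, 1} for
  `ps = 0, 0.1, ..., 0.9` (the `ps = 1` endpoint is a different regime —
  conformity is inert there); the equal-start contrast at
  `ps` in {0.75, 0.9, 1}, `pc = 0.5`, where social influence is strong
  enough for the start condition's spread to matter.

## Problem sizes

The shipped tests and the acceptance script use the canonical
experimental scale — 100 nodes, 15 hyperedges of 10, `W = 500`
independent runs per cell — plus `m = 2000` for the martingale contrast,
10,000 runs at `m = 12` for the distributional goodness-of-fit, and
`n = 10,000` entrants in the analytic recursions. These are desk-scale
choices: the compiled engine simulates a 100-node run in well under a
millisecond, so wider grids or larger `W` are a matter of patience, not
redesign.

## A worked sweep

```{r sweep, eval = FALSE}
spec <- sweep_spec(ps = seq(0, 1, 0.25), pc = seq(0, 1, 0.25),
                   delta1 = 0.5, starts = "false", runs = 200,
                   base_seed = 1)
sw <- run_sweep(spec)
autoplot(sw, statistic = "U")
```

## Known limitations

Two colours only (the types are written for two; the statistics would
generalise but the engine assumes RED/BLUE). No agent revises a decision.
The analytic layer is mean-field — it describes one fully-mixed group,
not multi-hyperedge topologies, which is precisely why the fully-connected
network is the comparison case. Inequality uses the printed
non-normalised denominator by default; compare across `N` only with
`standard = TRUE`.
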
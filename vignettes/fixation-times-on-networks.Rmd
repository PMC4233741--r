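---
title: "Fixation probabilities and fixation times on networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation probabilities and fixation times on networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranet)
```

## The model

`moranet` studies the birth–death Moran process with constant selection on
connected undirected graphs with equal link weights. Wild-type individuals
have fitness 1, mutants fitness `r > 0` (`r = 1` is neutrality). One
elementary event consists of (i) choosing an individual for birth with
probability proportional to its fitness and (ii) replacing a uniformly
chosen *neighbour* of that individual with its identical offspring. An
individual never replaces itself, so on the complete graph of size `N` the
replaced individual is uniform over the other `N − 1` nodes and the process
coincides exactly with the classical well-mixed Moran model — this is why
the well-mixed transition probabilities in `wellmixed_transitions()` carry
the `1/(N − 1)` factor, and why the complete graph serves as the oracle for
everything else.

Mutation is absent: once the mutants are extinct or fixed, nothing changes.
Time is measured in elementary events, *including* events in which like
replaces like and the configuration stays the same. All times reported by
the exact solver and the simulator use this convention; no per-generation
rescaling is applied anywhere.

Assumptions worth stating explicitly: fitness is constant (no
frequency dependence), graphs are undirected, simple and connected, and
updating is birth–death with global fitness-proportional birth. Death–birth
or imitation updating would change every number downstream and is out of
scope.

## State space and symmetry reduction

A configuration is the set of mutant-occupied nodes, a bit mask over `2^n`
subsets. The all-wild-type and all-mutant configurations are the two
absorbing states; the rest are transient. `full_state_space()` enumerates
all of them in a deterministic order: ascending mutant count, then
ascending mask value, with the absorbing pair (extinction, then fixation)
last — the canonical-form ordering every downstream matrix relies on.

Configurations related by a graph automorphism behave identically, so
`reduce_state_space()` collapses them into orbit states. Automorphisms are
found by brute force over all `n!` permutations (bounded at `n ≤ 8`), which
is transparent and plenty at desk scale; the package deliberately avoids a
canonical-labelling dependency. Orbits are *verified*, not trusted: when
`build_canonical_chain()` aggregates transition probabilities over an
orbit, it recomputes the row from every orbit member and raises an error if
any member disagrees beyond 1e-12 (a lumpability failure would indicate a
state-space bug). The test suite additionally checks that the full `2^n`
chain and the reduced chain give identical fixation probabilities and
times on all six four-node motifs and on random graphs up to `n = 6`.

`prune_unreachable()` removes states that cannot be reached from any
single-mutant configuration. Reachability is assessed at `r = 1`, which is
sufficient because the zero pattern of the transition probabilities does
not depend on `r` for `r > 0`. On the ring of four this removes the
opposite-pair two-mutant orbit (mutants invade as a contiguous cluster),
giving the familiar five-state birth–death chain; on the diamond nothing is
removed and nine states remain, seven of them transient. State numbering is
canonical by construction (count, then lexicographic representative), not
the Roman numerals sometimes used for the diamond; analyses that need a
specific diamond state (the three-mutant state with the wild-type on a
degree-2 node, say) identify it *structurally* from degrees, never by
position in a figure.

## Solving the absorbing chain

With transient-first ordering the transition matrix is `[Q R; 0 I]`.
`solve_chain()` computes the fundamental matrix `F = (I − Q)^(−1)` via one
LU factorisation with a matrix right-hand side (no explicit inverse), then

* `Φ = F·R` — absorption probabilities (rows sum to 1),
* `τ_unc = rowSums(F)` — unconditional fixation times,
* `T_cond[i, j] = F[i, j]·Φ[j, fix]/Φ[i, fix]` — sojourn times conditioned
  on fixation, and `τ_cond = rowSums(T_cond)`.

The conditional construction is validated against the independent
closed-form birth–death sum `conditional_time_wellmixed()` on complete
graphs (agreement to 1e-9 across `N ≤ 6` and a fitness grid) — the
construction holds on *any* network, but only the birth–death case has a
closed form to compare against. Neutrality needs no special-casing in the
linear solve; only the closed-form fixation probability has its removable
singularity at `r = 1` patched to `i/N`.

All arithmetic is double precision. At desk scale (`t ≤ 14` for the
four-node motifs) the systems are so well conditioned that the headline
rational values (staying probabilities 1/2 and 1/3, neutral times 9 and 10,
the exact +1 sojourn step on the ring) are reproduced to better than
1e-12, which is the tolerance the invariants are tested at. For strongly
deleterious mutants `Φ[i, fix]` underflows eventually; the solver guards
against non-positive fixation probabilities and the analyses stay within
`r ∈ [0.1, 10]`, where everything is comfortably representable.

Start averaging: the first mutant arises on a uniformly chosen *node*, so
each single-mutant orbit gets weight `orbit size / n` (diamond: 1/2 hub,
1/2 degree-2; star of four: 1/4 centre, 3/4 leaf). The start-averaged
conditional sojourn time of state `j` is the same weighted average of
`T_cond[i, j]` over the single-mutant starts `i`. This node-uniform
convention is used consistently for fixation probabilities, times and
sojourn curves; a fixation-probability-weighted alternative was considered
for the sojourn curves and rejected to keep a single convention throughout
(for the diamond crossovers the choice barely moves the roots, and the
placement analysis conditions on each start separately anyway).

Strong selection (`r → ∞`) is handled numerically:
`strong_selection_limit()` evaluates the quantity along `r = 10^2 … 10^6`
and flags convergence when successive values differ by less than 1e-4.
The three analytically known limits (complete-graph per-count sojourns
`(N−1)/(N−i)` = (1, 3/2, 3) for `N = 4`; ring matching the complete graph
in its one- and three-mutant states) pin the method down in the tests.

## The crossover analyses

Both crossovers are roots of a difference of two exact curves in `r`,
found by `uniroot()` to 1e-8 after a sign-change check.

* **Sojourn argmax (diamond).** At neutrality the largest start-averaged
  conditional sojourn time belongs to a two-mutant state; under strong
  selection, to the three-mutant state whose remaining wild-type occupies a
  degree-2 node (connected to only two of the three mutants, it is rarely
  replaced while the mutants overwrite each other). The crossover of these
  two curves is bracketed in `(1, 3)` and lands at `r* ≈ 1.648`.
* **Initial placement (diamond).** The conditional fixation time from the
  degree-2 starting orbit exceeds the hub orbit's for small `r` and drops
  below it beyond a crossover bracketed in `(2, 10)`, at `r* ≈ 5.796`.
  The node-uniform curve is exactly the mean of the two, since both orbits
  have weight 1/2.

## The simulator

`simulate_fixation()` realises the same event-level process in C++:
fitness-class sampling (mutants vs wild-types) followed by a uniform choice
within the class and a uniform neighbour, with swap-delete bookkeeping so
each event is O(1). It draws from R's RNG, so a `seed` argument makes runs
bit-reproducible. Standard errors come from the sample variance of per-run
absorption times (conditional times over fixation runs only; a run of zero
fixations reports an undefined conditional time with a flag rather than an
error). The simulator is validated against the exact solver on all six
four-node motifs — the package's own version of checking dots against
lines — at 3 standard errors.

## The lattice study

`make_lattice()` generates `side × side` square lattices along three axes:
boundary (open vs periodic/torus) and diagonal links (`none`, `single` =
one diagonal per cell, `both` = Moore neighbourhood). Periodic lattices are
regular — degree 4, 6, 8 respectively — hence isothermal, and their
simulated fixation probabilities are checked against the well-mixed closed
form. The `single` variant is the tiling of the diamond motif: each unit
cell is a four-cycle plus one chord, which is exactly how the diamond
extends the ring. This identification matters: with *both* diagonals the
open lattice fixes faster than the plain one, and it is the one-diagonal
lattice that reproduces the counterintuitive effect of added links slowing
fixation. `lattice_experiment()` therefore simulates all three variants per
boundary type plus the complete graph and asserts the orderings
statistically, requiring 3 pooled standard errors of separation before a
comparison counts (and reporting it as unassessed otherwise, never as a
failure).

Default problem sizes were chosen as the smallest that show every effect
cleanly: sides 4–7 (populations 16–49), fitness `r = 2`, 10^4 replicates
per network for exploration and 3×10^4 in the acceptance checks. At these
sizes every ordering separates by well over 3 SE; larger lattices (the
generator handles side 11, population 121, without changes) only widen the
gaps at proportionally higher simulation cost.

## What the generators do and do not emulate

The graph generators produce exactly the population structures analysed:
the six four-node motifs, their standard-family generalisations, and the
lattice grid. Synthetic in this package means *structural*, not noisy —
there is no measurement error model, no fitness heterogeneity beyond the
two types, no mutation during spread, and no weighted or directed links.
Passing tests therefore demonstrate correctness of the chain machinery and
the simulation under the stated update rule; they say nothing about
networks with unequal weights, directionality, or frequency-dependent
fitness, all of which are out of scope.

## Known limitations

* Exact solves are capped at `2^16` configurations and automorphism search
  at `n ≤ 8`; beyond that, use the simulator.
* Closed-form expressions in `r` are provided only for the well-mixed
  (complete-graph) case; all other curves are evaluated numerically per
  `r`, which is why the crossovers are located by bisection rather than
  symbolically.
* Double precision limits reliable work to moderate fitness values; the
  strong-selection limit is numerical extrapolation, not a symbolic limit.
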
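---
title: "Lazy random walks on graphs: models, exact methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lazy random walks on graphs: models, exact methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the exact machinery, the parameters that matter,
the places where the design was genuinely open, and the limits of what the
tests demonstrate.

## The model

`m` agents occupy nodes of a connected graph with unit-length edges. Time is
discrete. In each period every agent draws its move independently: with
probability `p` (the *laziness*) it stays; with probability `1 − p` it steps
to a neighbour chosen uniformly at random. On a `Δ`-regular graph the choice
`p = 1/(Δ+1)` makes the move uniform over the closed neighbourhood — the
*loop-random walk*, which plays a special role below. Agents have no memory
and no knowledge of other agents' positions; in the population-dependent
variant an agent may condition its laziness `p_k` on the number `k` of
agents at its own node, evaluated *before* anyone moves. That timing is the
only one consistent with the reduced two-agent chains: when two agents share
a node, both use the population-2 laziness in the same period.

A goal is a set of absorbing configurations:

* **distancing** — minimum pairwise graph distance `d ≥ D`, with `d = 0`
  whenever two agents share a node. Feasibility requires at least `m` nodes
  pairwise at distance `≥ D`; infeasible instances are rejected up front.
  A single agent has no pairwise distance, so `m = 1` is rejected rather
  than declared vacuously distanced.
* **gathering** — all agents on one node. Meetings are *sticky*: agents that
  end a period on a common node coalesce and continue as a single agent
  (with the population-1 laziness). Merging happens after all simultaneous
  moves resolve; this ordering is what the two-state reduction on the
  triangle pins down.
* **capture** — searchers (laziness `s`) and one hider (laziness `h`);
  capture happens iff a searcher and the hider occupy the same node at the
  *end* of a synchronous period. Agents crossing the same edge in opposite
  directions do not capture (see "The two capture blocks" for the full
  story).

Initial placements that already satisfy the goal absorb at time 0. Random
starts place every agent independently and uniformly; their class weights
are always derived by enumerating the `n^m` labelled placements, never typed
in — the familiar weights (6,6,6,6,1)/25 for three agents on the 5-cycle and
(2/9, 2/9, 4/9, 1/9) for two searchers and a hider on the triangle fall out
of this push-forward.

With the non-absorbing states enumerated as `1..N` and `B` the `N × N`
transient block, the fundamental matrix `F = (I − B)⁻¹` gives the expected
absorption times `t = F·1` and absorption probabilities `A = F·R` into the
labelled absorbing classes. Everything downstream — optimisation, games,
tables — is built on this.

## State spaces and symmetry lumping

Agents are exchangeable, so configurations are stored as occupancy vectors
`[j_1, …, j_n]` (distancing), occupied-node sets (gathering), or (searcher
multiset, hider) pairs (capture). On cycles the dihedral group (rotations
and reflections) acts on configurations, and the chain is exactly lumpable
over its orbits. The canonical representative is the lexicographically
smallest image; classes are labelled by *gap coordinates*: the sorted arc
lengths between consecutive agents, of which the first `m − 1` are reported
— `(j, k)` for three agents, a single distance for two. Coalesced states pad
with leading zeros, so "all gathered" on any cycle is `(0,0)` for `m = 3`.

Lumping is a correctness risk, so it is tested two ways: absorption times
from the full occupancy chain are compared class-by-class against the
lumped chain (they agree to 1e-9 across cycles up to `n = 7`, `m = 3`, both
goals), and the exchangeable-agent reduction itself is compared against a
labelled-agent chain that tracks every agent identity on tiny graphs.
Transition *reachability* between gap classes is likewise derived, not
tabulated: for example, the class `(j−2, k−2)` is unreachable from `(j, k)`
— if the closest pair closes by two, the second pair cannot also close by
two — and the builder produces that zero by enumeration; a test asserts it.

## Symbolic chains

When a strategy parameter is a polynomial variable (`poly_var("p")`,
`symbolic_strategy()`), the builder produces `B` and `R` with sparse
multivariate polynomial entries, and the absorption solve returns exact
rational functions of the laziness parameters. Three design choices matter:

* **Double coefficients are exact here.** On the cycle graphs where symbolic
  chains are used, every kernel weight is dyadic (halves and quarters), so
  polynomial arithmetic in doubles incurs no rounding; coefficient-level
  comparisons against hand-derived blocks use exact canonical forms.
* **Cramer's rule, not elimination.** `(I − B) t = 1` is solved by Cramer's
  rule with polynomial determinants: every `t_i` shares the determinant as
  denominator, degrees stay minimal, and no multivariate GCD is ever needed.
  Rational functions are left unreduced and compared by cross-multiplication.
* **Numeric evaluation goes through the numeric chain.** For optimisation,
  the symbolic chain is instantiated at each candidate laziness and the
  linear system solved numerically (backward stable); the symbolic form
  supplies exact derivative root candidates, not the working arithmetic.

Chains that cannot absorb are detected *structurally*, by reachability on
the support of `B`, before any inversion: two adjacent agents on the
4-cycle under pure random walks stay adjacent forever, `I − B` is exactly
singular, and the correct answer is `t = ∞`, not a condition-number
accident. States that can reach both the absorbing set and a trap also get
`t = ∞` (absorption is not almost sure); absorption probabilities are still
reported where defined. Genuinely ill-conditioned solves (condition number
above 1e12) warn and apply one step of iterative refinement.

## Optimising the laziness

The expected time from any start diverges as `p → 1` (everyone freezes), so
the domain is `[0, 1 − 1e−9]` and `p = 1` is reported infeasible rather
than evaluated. The scalar optimiser combines a dense grid (step 1e-3,
cheap because each evaluation is a tiny linear solve) with Brent refinement
(tolerance 1e-8) around the best cell, plus the exact stationary points of
the symbolic derivative (roots of its numerator via `polyroot`) when a
univariate rational objective is available. Ties break toward the smallest
`p`; no instance in the test suite is actually tied except the degenerate
4-cycle case noted below.

The population-dependent optimiser runs multi-start local optimisation
(25 Latin-hypercube starts plus every boundary corner, L-BFGS-B within the
box, Nelder-Mead polish) because the interesting optima sit on the boundary:
on cycles the optimal population-2 laziness is `r̄ = 0` — always move off a
shared node. Near-zero coordinates are snapped to the boundary exactly when
that does not worsen the objective. One degenerate case is worth naming:
for two agents on the 4-cycle starting together, *any* alone-laziness is
optimal once `r = 0` (the together class then exits at rate 1/2 no matter
what), so only `r̄` and the value `t̄ = 2` are unique.

The objective may be a single class's `t_i` or a start-distribution average
(used for the random-start rows of the optimal-laziness tables on the
5-cycle, whose weights come from the placement enumeration).

## The two capture blocks

For the two-searcher/one-hider game on the triangle, the chain builder's
end-of-period capture rule produces a 2×2 transient block whose entries we
also derived by hand and verified by exhaustive enumeration of all
`3 × 3 × 3` joint moves. Under this *kernel* block the game is strikingly
clean: the saddle point is exactly the loop-random-walk pair
`(h*, s*) = (1/3, 1/3)` with value `4/5` — at `s = 1/3` each searcher's
position is uniform each period regardless of history, so the capture
hazard is `5/9` per period from every state and the hider is indifferent;
symmetrically for `h = 1/3` via the one-period capture probability
`W(s, h) = h(1−s)/2 + (1−h)(s/2 + (1−s)/4)`, whose slope in `s` vanishes at
`h = 1/3`. The competitive (race-to-capture) equilibrium is then also the
loop-random walk for everyone.

A second, fixed *benchmark* block is shipped alongside
(`ref_B_c3_search_benchmark`). It agrees with the kernel block in the
apart-to-apart entry but differs in exactly three coefficients (the tests
pin the differences term by term: `¼h′ss′` for `½h′ss′` in apart-to-together,
a spurious `¼hs′²` in together-to-apart, and `½h′s′²` for `⅜h′s′²` in
together-to-together, writing `h′ = 1−h`, `s′ = 1−s`). One of the extra
terms corresponds to an impossible event — from searchers-together with a
staying hider, both searchers moving cannot reach an uncaptured apart state
on the triangle — and we found no capture convention (period-end,
edge-crossing, trail or ambush variants) that generates this block from the
motion rule. It is retained because the game's classical solution is
defined by it: solving the same first-order conditions on the benchmark
block gives the saddle `(h*, s*) ≈ (0.5097, 0.2797)` with value `≈ 0.8390`
and Hessian determinant `≈ −2.4`, and the competitive game's searcher
laziness becomes the unique (0,1) root of the quintic
`14 − 15s − 117s² − 33s³ − 5s⁴ + 60s⁵ ≈ 0.2797`. The solvers therefore take
`block = "benchmark"` (default, matching the classical numbers) or
`block = "kernel"`, and everything downstream — fundamental matrix,
enumerated start weights, Newton iteration on the first-order conditions,
Hessian, envelope check, balance polynomial — is computed identically for
either block.

The saddle verification is two-fold: the Hessian determinant must be
negative and the minimax envelope
`max_h T(h, s*) = T(h*, s*) = min_s T(h*, s)` must hold to 1e-6. The kernel
block passes both. The benchmark block passes the Hessian test but fails
the envelope by about 5e-5 (its `T(·, s*)` is maximised at the `h`
boundaries, not at `h*`), and `find_saddle()` reports exactly that rather
than smoothing it over. We flag this inconsistency as unresolved; the
package's own derivation favours the kernel block.

## The first-to-disperse game

On the line `L_n`, `n` players start together at end node 1; the first
players alone at their node split a unit prize. "Alone" is evaluated at the
end of every period including period 0 (asserted — with everyone at node 1
it never triggers at 0). The exact engine enumerates labelled position
tuples whose every occupied node holds at least two players (the transient
set), builds the absorbing chain with terminal classes keyed by the winner
set, and pays `1/|winners|` each (`tie_rule = "split"`) or nothing on any
tie (`tie_rule = "zero"`, the *modified* payoff that simplifies the closed
forms). Two closed forms are verified against this oracle on a fine grid:
the stay-forever payoff `(1−p)/(1+p)` and the always-move modified payoff
`(1 − 4p + 14p² − 12p³ + 5p⁴)/(3 + 4p − 6p² + 4p³ − p⁴)`, both equal to
`1/3` at `p = 1/2`. The three-player scan then exhibits a strictly
profitable deviation at every symmetric `p` on a 0.01 grid — staying put
beats `1/3` below `1/2`, always moving beats it above, and at `p = 1/2` the
positive tie probability makes always-moving strictly profitable — so no
symmetric equilibrium exists in pure lazinesses. Mixed strategies over `p`
are outside the model's strategy class and deliberately out of scope.

## Monte Carlo engine

For graphs whose exact chains are unwieldy (grids, longer lines) the
simulation engine runs the identical dynamics forward: synchronous moves,
population-dependent laziness on pre-move populations, sticky merging,
stopping at the first absorbing period including period 0. Defaults: 5,000
trials, horizon guard 1e6 steps. Truncated trials are counted, excluded
from the mean with a warning, and flagged as unreliable when they exceed
half the trials — never silently included. Reproducibility comes from R's
Mersenne-Twister stream seeded per run; parameter sweeps advance the base
seed by one per grid point. Every exact fixture is cross-checked to within
four standard errors (dispersion and gathering on small cycles, two-agent
distancing, the capture game), and the grid/line experiments reproduce the
qualitative finding that the mean time to pairwise distance 2 increases
with `p` from a corner, centre or end start — the pure random walk is best
there, in contrast to the interior optima on cycles.

The grid/line experiments do not fix an agent count in the underlying
problem statement; the package defaults to `m = 3`, the smallest team with
a nontrivial *pairwise* distance profile, and the CLI makes `m` explicit.

What the simulations do and do not show: they emulate exactly the abstract
model (independent walkers, unit-length edges, synchronous periods), so
agreement with the exact solver validates the implementation, not the
model's realism. Real contact networks are neither lattices nor cycles, and
real agents are neither memoryless nor homogeneous in compliance; nothing
here speaks to those features.

## Problem sizes and tolerances

The test suite runs exact chains up to `n = 12` nodes and `m = 3` agents
(lumped), full-versus-lumped comparisons up to `n = 7`, labelled-agent
oracles up to `n^m = 256`, and 1,500–5,000 Monte Carlo trials per fixture —
all chosen as comfortable desk-scale sizes for the model's phenomena. Key
tolerances: chain rows sum to 1 within 1e-12 (violations are errors, never
renormalised); exact rational values asserted to 1e-9 or tighter; optimiser
refinement 1e-8 in `p`; values printed to three or four decimals in the
reproduced tables are compared at half a unit in the last printed place
(one table entry is a truncation rather than a rounding and is tested with
the correspondingly wider band, as noted in the test).

## Known limitations

* Symmetry lumping is implemented for cycles only; general automorphism
  lumping is not attempted.
* Game solutions (saddle, competitive equilibrium, disperse game) are for
  the specific small instances; the chain machinery is generic but no
  equilibrium claims are made beyond them.
* Strategies are time-homogeneous lazinesses, possibly population-dependent;
  no memory, no observation of other agents, no mixed strategies.
* The exact engines guard their combinatorics (at most 8 agents in the
  joint-move expansion, `n ≤ 4` players in the disperse game, symbolic
  solves up to 8 states); beyond that, use the Monte Carlo engine.
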
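---
title: "Detecting seed-dependent autocatalytic systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seed-dependent autocatalytic systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdasnet)
```

## The problem

In an open environment receiving a steady influx of simple *food* chemicals,
a subnetwork of reactions can persist only if it is autocatalytic: it must
convert food into more of its own internal species fast enough to offset
dilution. Some autocatalytic subnetworks cannot start by themselves — no
chain of reactions from the food alone reaches them — but a transient
introduction of one or a few *seed* species switches them on permanently.
We call such a subnetwork a seed-dependent autocatalytic system (SDAS).
SDASs matter for origin-of-life research because a reaction system organised
as a hierarchy of SDASs can complexify step by step: each activated tier
produces new species that serve as food for the next, and rare seeding
events play the role that mutations play in genetic systems.

This package detects and analyses SDASs in stoichiometric reaction
databases. It deliberately works with *stoichiometric* autocatalysis rather
than explicit catalysis (the RAF tradition): a set of reactions is
autocatalytic when some non-negative combination of them nets a strictly
positive production of every internal species, whether or not any reaction
is explicitly catalysed. Explicitly catalysed reactions are still supported:
a catalyst is required for a reaction to fire, contributes a zero entry to
the stoichiometric matrix, and — if internal — must itself be sustained.

## The detection procedure

1. **Network expansion** `Ξ(S_O, R)`: starting from a species set, keep
   adding any reaction whose reactants *and* catalysts are all available,
   then its products, until a fixpoint. The fixpoint is unique and
   order-independent, so expansion is a well-defined closure operator.
   The implementation keeps an unmet-requirement counter per reaction and a
   species-to-reaction reverse index, giving near-linear cost in total
   reaction arity.
2. **Tier 0**: the closure of the ultimate food `S_U` is the external food
   system `(S_0, R_0)` — everything reachable with no seed.
3. **Seeding**: for a candidate seed `H` disjoint from the food, compute
   `Ξ(S_0 ∪ H, R)` and subtract the food closure; the remainder
   `(S_1, R_1)` is the internal subnetwork induced by `H`. The
   stoichiometric matrix is partitioned with food rows/columns external
   and induced rows/columns internal; the internal-rows-by-external-columns
   block is structurally zero.
4. **Certification**: `H` induces an SDAS iff there is a flux vector
   `x ≥ 0` over the internal reactions with

   `sum_j x_j s_ij ≥ 1` for every internal species `i`,

   where `s_ij` is the net stoichiometric coefficient. (Strict positivity
   and the `≥ 1` form are equivalent by rescaling; the package tests the
   `≥ 1` system directly as a feasibility LP, which is numerically cleaner
   than probing an unbounded growth objective. The growth-objective probe is
   retained as an optional cross-check in `is_autocatalytic(probe_unbounded
   = TRUE)`: it maximises the net production of one internal species under a
   box on total flux and checks that the optimum scales with the box.)
   External rows are unconstrained — food is assumed freely available.
5. **Classification**: a certified seed is *supported* (the LP forces every
   internal species, including the seed, to be net-produced). Supported
   singleton seeds inducing identical closures form a *clique* and share one
   SDAS; grouping uses an exact sorted-id fingerprint of the closure.
   Species pairs that individually fail but jointly pass are *composite*
   seeds (minimality is checked by re-testing both singletons). A species
   that cannot seed an SDAS itself but whose closure fires every reaction of
   a known SDAS is an *unsupported seed* of that SDAS; when several nested
   SDASs qualify it is assigned to the maximal one by reaction-set
   inclusion. This containment rule is our reading of the verbal definition
   (no reference algorithm exists); mismatches against published counts
   should be flagged, not tuned away.
6. **Tiers**: once SDASs are certified, their species join the food and the
   scan repeats, producing a trophic hierarchy (`build_tiers()`). By
   default every detected SDAS is activated between tiers and candidates
   are all species outside the current food; both are configurable.

## Autocatalytic motifs by integer programming

An SDAS may be much larger than the self-amplifying core inside it. The
package finds minimum-cardinality *autocatalytic motifs* with a binary
selection program: `z_j ∈ {0,1}` selects reactions, `y_i ∈ {0,1}` marks
internal species involved in selected reactions, and a flux `x` with
`0 ≤ x_j ≤ β_j z_j` must net-produce every involved species:

- `sum_j x_j s_ij ≥ 1 − M_i (1 − y_i)` with
  `M_i = 1 − sum_{j: s_ij<0} β_j s_ij`, so the constraint is vacuous for
  uninvolved species (for any `x` in the box the left side cannot fall
  below `1 − M_i`);
- `y_i ≥ z_j` for every internal species `i` involved in reaction `j`,
  *including internal catalysts* — a motif that uses a catalysed reaction
  must sustain its own catalyst (external catalysts impose nothing);
- `sum_j z_j ≥ D` (`min_reactions`), objective `min sum_j z_j`.

The program is solved exactly by depth-first branch-and-bound on the
binaries over the LP relaxation, with proven optimality (nodes are pruned
only when their bound excludes any strictly better integer value). All
optima are enumerated by re-solving under no-good cuts
(`sum_{j∈T} z_j ≤ |T| − 1`) until the optimum grows, and the motif list is
sorted lexicographically by reaction-id set so results do not depend on
solver tie-breaking. Every returned flux is re-checked arithmetically
against the production constraints before it is reported.

**Members versus waste.** The `y = 1` species of a motif split into
*members* — internal species consumed (as reactant or catalyst) by at least
one selected reaction, i.e. the regenerated constituents of the cycle — and
*waste* — involved species that are only produced. The integer program
constrains both (waste is trivially net-produced); the split matters for
ecology: a higher-tier SDAS consuming a lower motif's member is a
predator/parasite, one consuming its waste is a mutualist, and shared
consumed food means competition. Treating all involved species as members
would make waste identically empty and erase the mutualism category, so the
package keeps the consumed/produced-only distinction explicit.

"Catalytic facilitation" between SDASs is reported only as *candidate*
composite paths — a higher-tier species consumed by one reaction and
regenerated by another such that the pair's net conversion duplicates a
single lower-tier reaction. Whether such a path actually accelerates the
conversion depends on kinetics, which the framework does not model, so no
rate claim is attached.

## Linear and integer programming internals

The feasibility systems involved are small and dense (internal blocks of a
seed-induced partition), so the package ships a compact two-phase primal
simplex (`lp_solve()`) with Bland's anti-cycling rule, used both for SDAS
certification and as the relaxation engine of the motif branch-and-bound.
The test suite cross-validates it on random linear programs against an
independent HiGHS-based implementation (through `scipy.optimize.linprog`,
the tool used in the original analyses) across optimal, infeasible and
unbounded statuses, and validates the certification end-to-end against a
brute-force search over integer flux vectors.

Numerical choices:

- pivot/feasibility tolerance `1e-9`; LP feasibility certificate tolerance
  `1e-7`; reported fluxes below `1e-9` are clipped to zero;
- integrality tolerance `1e-6` in the branch-and-bound; branching picks the
  most fractional binary and explores its nearer bound first;
- `β_j` defaults to `1000` for every reaction (configurable globally or per
  reaction); a warning is emitted if any reported flux comes within 1% of
  its bound, since a binding bound can hide motifs;
- reactions whose species are all external are barred from motif selection
  (they can satisfy the cardinality constraint vacuously but sustain
  nothing internal);
- a species appearing on both sides of a reaction with *equal*
  coefficients is normalised into the catalyst set (explicit catalysis:
  required, regenerated, net zero); with *unequal* coefficients the
  reaction is stored as written, so `A + F -> 2A` keeps `A` as a required
  reactant while its matrix entry is the net `+1`;
- degenerate inputs: an identity reaction (`A -> A`) is rejected; a seed
  already inside the food closure is an error ("seed is food"); a candidate
  inducing no reactions is reported as not-a-seed without running the LP;
  empty food yields an empty tier-0 closure.

## The synthetic generator

`generate_tiered_network()` emulates the architecture the detection
pipeline is designed for: per tier, one planted autocatalytic cycle
`C_i + food -> 2 C_(i+1)` (closing on `C_1`) whose all-ones flux nets +1 of
every cycle species, and whose minimality is structural — any proper subset
leaves some reactant unproduced, so the planted cycle length is exactly the
minimum motif cardinality. A configurable fraction of cycle reactions emit
a waste byproduct (consuming an extra food unit to stay mass balanced
under integer pseudo-masses), the remaining species budget becomes
seed-dependent but non-autocatalytic decoy chains, and tiers above the
first feed on species of the tier below, so they are seedable only after
that tier activates. Defaults (two tiers, nine species per tier, cycle
lengths 2–4, waste fraction 0.3, two cross-tier food edges) keep generated
instances at the scale of the embedded toys while exercising every
classification the pipeline makes.

What the generator does *not* emulate: the right-skewed degree
distributions of real reaction databases, multi-reactant combinatorics,
reversibility (planted cycles are unidirectional), and any thermodynamic
or kinetic structure. Passing the recovery tests therefore shows the
pipeline is correct on networks with known ground truth, not that real
databases contain comparable structure.

## Problem sizes used by the tests

The suite certifies: expansion laws (idempotence, monotonicity,
order-independence) on 100 seeded random networks of 10 species / 12
reactions; LP-versus-oracle agreement on every embedded toy and 40 random
internal systems with up to 8 reactions (integer-flux search bounded at 12
per reaction); integer-program-versus-exhaustive motif agreement on all
feasible systems among those, plus the toys; and exact recovery of planted
seeds, motif sizes and waste on generated two-tier networks. The
`fig1_like` fixture reconstructs a published-style hierarchical example —
its food closure `{F0, F1, F2}`, the tier-1 SDAS `({A1, A2, A3},
{R1, R2, R3})` with certificate flux `(4, 5, 1)`, a waste-producing tier-2
SDAS and two tier-3 consumers — from its textual description; it is a
reconstruction, not a transcription of any published figure, and its
masses are chosen to balance every reaction.

## Limitations

- SDAS detection is topological: a certified SDAS may still fail
  kinetically (reactions too slow to beat dilution).
- Composite-seed search is restricted to pairs of failed singletons;
  exhaustive search over larger seed sets grows combinatorially and all
  published composite examples are pairs.
- The motif integer program is exact but exponential in the worst case; it
  is intended for SDASs up to a few tens of internal reactions
  (`run_pipeline()` skips motif enumeration above `motif_max_reactions`,
  default 30).
- The unsupported-seed containment rule and the facilitation-path heuristic
  are stated interpretations of verbal definitions; both are deliberately
  conservative and their evidence lists are reported so users can audit
  them.
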
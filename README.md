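# sdasnet

Detection and analysis of **seed-dependent autocatalytic systems (SDASs)**
in stoichiometric chemical reaction networks.

In an open environment fed by simple chemicals, only autocatalytic
subnetworks can persist against dilution. Some of them cannot arise from
the food alone: they need a transient **seed** to switch on, after which
they sustain themselves by converting food into all of their internal
species. Networks organised as hierarchies of such systems can complexify
step by step — each activated tier feeds the next — which makes SDASs a
candidate mechanism for pre-genetic, chemistry-level evolution. `sdasnet`
provides the complete computational workflow for finding and analysing
them, for researchers working on origin-of-life chemistry, autocatalysis,
and reaction-network theory.

## The method

For a reaction database `R` and ultimate food `S_U`:

1. **Network expansion** `Ξ(S_O, R)` — the closure adding any reaction whose
   reactants and catalysts are all available, then its products, to a
   fixpoint. `Ξ(S_U, R)` is the tier-0 food system `(S_0, R_0)`.
2. **Seeding** — for a candidate seed `H`, the induced internal subnetwork
   is `(S_1, R_1) = Ξ(S_0 ∪ H, R) \ (S_0, R_0)`, arranged as a partitioned
   stoichiometric matrix (food rows/columns external, induced internal).
3. **LP certification** — `H` induces an SDAS iff there is a flux `x ≥ 0`
   over internal reactions with

   ```
   Σ_j x_j s_ij ≥ 1   for every internal species i
   ```

   (equivalent to strict positivity by rescaling). Supported seeds, cliques
   (seeds inducing identical closures), composite seed pairs, and
   unsupported seeds are classified on top of this test, and tiers are
   built by activating detected SDASs as food for the next scan.
4. **Motif integer programming** — minimum-cardinality autocatalytic motifs
   inside an SDAS are found with binary reaction selectors `z_j`, species
   indicators `y_i`, big-M production constraints
   `Σ_j x_j s_ij ≥ 1 − M_i(1 − y_i)`, coupling `y_i ≥ z_j`, and objective
   `min Σ z_j`; all optima are enumerated under no-good cuts. Motif
   species split into *members* (consumed and regenerated) and *waste*
   (produced only), which drives the ecology layer: competition (shared
   food), predation/parasitism (consuming a member), mutualism (consuming
   waste), and candidate catalytic-facilitation paths.

Linear programs are solved by a two-phase primal simplex implemented in
the package (cross-validated in the tests against an independent HiGHS
implementation and a brute-force integer-flux oracle); the motif integer
program is solved exactly by branch-and-bound with proven optimality.

## Worked example

The embedded `fig1_like` fixture is a mass-balanced reconstruction of a
hierarchical multi-SDAS network (food `{F0, F2}`; a tier-1 SDAS seeded by
`A1`; a waste-producing tier-2 SDAS; two tier-3 consumers):

```r
library(sdasnet)

net <- toy_network("fig1_like")
food <- tier0(net, c("F0", "F2"))
sort(food$species)
#> [1] "F0" "F1" "F2"

scan <- scan_singleton_seeds(net, food)
cliques <- group_cliques(scan)
cliques[[1]]$members          # seeds inducing the same SDAS
#> [1] "A1" "A2"
cliques[[1]]$sdas
#> <SDAS: tier 1, 3 species, 3 reactions, 2 known seed(s)>

M <- internal_partition(net, food, "A1")
is_autocatalytic(M)$flux      # a certificate: 4 R1 + 5 R2 + 1 R3
#> R1 R2 R3
#>  4  5  1

motifs <- enumerate_min_motifs(M)
motifs[[1]]$reactions         # the self-amplifying core; A3 is an appendage
#> [1] "R1" "R2"

build_tiers(net, c("F0", "F2"), max_tier = 4)
#> <sdas_tiers: tier-0 3 species / 1 reactions; 3 seeded tier(s)>
#>   tier 1: 1 clique(s), 1 SDAS(s)
#>   tier 2: 1 clique(s), 1 SDAS(s)
#>   tier 3: 2 clique(s), 2 SDAS(s)
```

The flux certificate means 4 firings of `R1`, 5 of `R2` and 1 of `R3`
jointly convert `4 F1 + 5 F2` into one net copy of each internal species
`A1, A2, A3` — the stoichiometric signature of autocatalysis. Reaction
databases are read with `read_reaction_db()` (TSV/CSV, plain-text
equations, or XLSX via readxl), and `run_pipeline()` writes the full
report set (tier-0 closure, seed and clique tables, SDAS memberships,
motifs, interactions) for a database + food configuration. A thin
command-line front-end over the same functions is installed at
`inst/cli/sdasnet.R` with subcommands `expand`, `scan-seeds`, `detect`,
`tiers`, `motifs`, `ablate`, `fixtures`, `generate`.

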
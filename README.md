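# gmcskit

Enumeration of **genetic minimal cut sets (gMCSs)** in constraint-based
metabolic models: essential genes, synthetic-lethal gene sets, and
growth-coupling interventions for strain design.

## The problem

A genome-scale metabolic model is a tuple (M, R, S): metabolites, reactions,
and an m×n stoichiometric matrix over the *internal* metabolites. Its feasible
cone is

    E = { v ∈ Rⁿ : S·v = 0,  lᵢ ≤ vᵢ ≤ uᵢ }

and a *target region* is a polyhedral slice T = { v ∈ E : A·v ≥ b } — for
example all modes with biomass flux ≥ p·v_bio^max (lethality analysis,
p = 0.01 by default), or additionally with zero flux through a product
exchange (growth-coupling analysis). A **gCS** is a gene set whose knockout
— propagated through the boolean gene-protein rules (GPRs) to the reactions
they disable — leaves no feasible mode in T; a **gMCS** is an
inclusion-minimal gCS. Length-1 gMCSs are essential genes; longer ones are
synthetic-lethal combinations.

## The method

Rather than solving mixed-integer programs, gmcskit combines three cheap
ingredients:

1. **Per-reaction cut sets from GPRs.** Each rule is converted DNF → CNF by
   minimal hitting sets of its summands (an incremental Berge construction);
   the reduced CNF factors are the reaction's gMCSs.
2. **Generalized minimal hitting sets across modes.** A gene set cuts a mode
   v iff it contains a member of the mode family gMCS(v) (the reduced union
   of per-reaction families over supp(v)); the gMCSs of a mode collection
   are its minimal hitting sets, enumerated with a cardinality-capped Berge
   algorithm.
3. **k-representative subsets + LP feasibility.** The full target region is
   never enumerated. A small subset T′ ⊂ T is grown incrementally: at each
   cardinality k the minimal hitting sets of T′ (size k) are *candidates*;
   each is either confirmed as a gMCS of T — the knockout LP
   `max 0 s.t. S·v = 0, bounds (blocked → [0,0]), A·v ≥ b` is infeasible —
   or refuted by a witness mode of T that survives the knockout and is added
   to T′. After phase k, T′ is k-representative: its gMCSs of length ≤ k are
   exactly those of T.

Only plain LPs are solved (a built-in two-phase simplex; the backend sits
behind a minimal contract so another solver can be dropped in).

## Worked example

The package ships the ten-reaction textbook fixture (rules r0:g0 … r7:
`g0 and (g5 or g6 or g7)` … r9: `(g1 and g2) or (g3 and g4)`) with a target
region given by three mode supports. Running the driver:

```r
library(gmcskit)
run_toy_demo(k_max = 3)
```

prints

```
<gmcs_catalog 'toy': 5 gMCS(s), k_max=3>
  length 1: 1
    { g0 }
  length 2: 3
    { g1, g2 }
    { g1, g4 }
    { g3, g4 }
  length 3: 1
    { g5, g6, g7 }
target: toy
k       n_gmcs
1       1
2       3
3       1
total   5
```

{g0} is the sole essential gene (every mode needs r0 and r7, both requiring
g0); the three pairs are synthetic lethals; {g5,g6,g7} is the triple
disabling r7's isozyme alternatives. An LP-backed run on a small
stoichiometric model looks like:

```r
m <- read_model(system.file("extdata", "diamond.json", package = "gmcskit"))
t <- build_lethality_target(m, p = 0.01)
compute_gmcs(lp_oracle(t), k_max = 3)
#> <gmcs_catalog 'lethality': 3 gMCS(s), k_max=3>
#>   length 2: 3
#>     { g1, g2 }
#>     { g1, g3 }
#>     { g4, g5 }
```

## Command line

```sh
Rscript inst/cli/gmcs.R --command lethality --model model.json --k-max 4 --out run1
Rscript inst/cli/gmcs.R --command couple --model model.json --product EX_etoh_e \
    --close EX_o2_e --out run2
```

Outputs: `<out>.tsv` and `<out>.json` (one record per gMCS: cardinality,
sorted genes, target, classification) plus `<out>.meta.json` (solver,
tolerances, model checksum). Exit codes: 0 success, 2 configuration error,
3 solver failure.

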
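---
title: "Enumerating genetic minimal cut sets with k-representative subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating genetic minimal cut sets with k-representative subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmcskit)
```

## The model and its assumptions

gmcskit works on constraint-based metabolic models at steady state: fluxes
`v` satisfy `S v = 0` over the internal metabolites and per-reaction bounds
`l ≤ v ≤ u` (irreversibility is encoded as `l ≥ 0`; flux units are whatever
the model declares, typically mmol/gDW/h, and are treated as opaque). The
object of interest is a *target region* `T = { v : S v = 0, l ≤ v ≤ u,
A v ≥ b }` — all flux states one wishes to make impossible. A gene set `G`
is a genetic cut set (gCS) for `T` if knocking out `G` leaves `T` empty;
inclusion-minimal ones are the gMCSs. The machinery assumes:

* **Monotone GPRs.** Gene-protein rules are and/or expressions without
  negation, so a knockout can only disable reactions, never enable them.
  This is what makes "minimal falsifying gene sets" identical to the
  reduced CNF factors of the rule.
* **Knockouts act on bounds.** A disabled reaction gets bounds `[0, 0]`;
  columns are never deleted, so indexing is stable and the change is
  trivially undone.
* **Fixed wild-type threshold.** For growth targets, the biomass bound
  `p · v_bio^max` is computed once on the wild-type model and never
  recomputed after knockouts.

## The enumeration procedure

Three layers, each checked against an independent oracle in the test suite:

1. **Reaction layer.** A rule is normalized to DNF by recursive
   distribution (absorption applied at every product; a configurable guard
   — default 10⁶ intermediate terms — aborts loudly on pathological rules,
   never truncating silently). The minimal hitting sets of the DNF summands
   are the CNF factors, and their reduction is `gMCS(r)`. CNF-shaped rules
   skip the conversion and are just reduced.
2. **Mode layer.** For a mode `v`, `gMCS(v)` is the reduction of the union
   of `gMCS(r)` over `supp(v)`. Cut sets of a mode collection are its
   generalized hitting sets; all minimal ones of size ≤ k are enumerated by
   folding one mode family at a time into the working family (a Berge-style
   step: survivors are kept, failures are extended by each member of the
   incoming family, candidates pruned by the cardinality cap first, then
   reduced). The working family is reduced after *every* mode, which keeps
   it small and makes each intermediate state exactly the minimal hitting
   sets of the prefix.
3. **Driver layer.** `T` is replaced by a growing subset `T′`. Phase `k`
   computes the size-`k` minimal hitting sets of `T′` (families capped at
   `k`) as candidates, removes any candidate containing an
   already-confirmed gMCS, and asks the witness oracle about the rest: an
   infeasible knockout LP confirms the candidate; a feasible one yields a
   witness mode whose support joins `T′` (deduplicated by support — two
   flux vectors with one support carry identical families). After phase
   `k`, `T′` is k-representative, so confirmed sets are never re-tested.

The driver starts at `k = min |G|` over the first mode's family: every cut
set of `T` must contain a member of that family, so shorter phases are
provably empty (they are reported as empty rather than searched). If the
first mode's family is empty the target cannot be blocked genetically and
the catalog is empty.

Two readings of the phase loop appear in the literature describing this
scheme: candidates as an *intersection* of per-mode families versus as
*minimal hitting sets* across modes. Only the hitting-set reading is
consistent with the worked example this package reproduces (an intersection
of the three toy families would contain only `{g0}` and `{g5,g6,g7}` and
could never surface the synthetic-lethal pairs), so that is what is
implemented.

## Candidate refutation without solver calls

When a witness enters `T′` mid-phase, later candidates may already fail to
hit its family. Such candidates are refuted without an LP call — the
surviving mode is already in `T′`, so nothing needs to be added. This is an
optimization only: a candidate that hits every current family still goes to
the solver, and confirmation is always decided against `T` itself, never
against `T′`. A consequence is that `T′` can end up smaller than in a
trace that calls the solver for every candidate; the final catalog is
unaffected (verified by the witness-order-invariance tests).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p` | 0.01 | biomass fraction defining "nontrivial growth" (dimensionless); the standard choice in gene-essentiality screens |
| `k_max` | 4 | cardinality cap; genome-scale studies rarely go beyond quadruple knockouts |
| `tol_supp` | 1e-6 | support threshold on witness fluxes: `supp(v) = { r : |v_r| > tol }`. Fluxes are floating point, so the nonzero-support definition needs a threshold — well above the solver's feasibility tolerance (1e-9), well below meaningful flux scale (order 1–1000) |
| `max_terms` | 1e6 | DNF explosion guard per rule |

## Numerical choices

* **Zero LP objective.** The cut-set characterization holds for *any*
  linear objective; feasibility-only solves are cheapest and cannot be
  unbounded.
* **Solver.** A self-contained dense two-phase simplex with Bland's rule
  (guaranteed termination) backs the oracle; the environment this package
  targets has no external LP library. It is adequate for the desk-scale
  models in the test suite and is cross-checked against an independent
  HiGHS-based implementation there. Genome-scale runs would want a real
  sparse solver behind the same contract (build LP / solve / status +
  primal point); the contract exists precisely so one can be swapped in.
* **Infinite bounds** are replaced by ±1e6 inside the solver; an optimum
  pinned at such a synthetic bound for a declared-infinite bound is
  reported as `unbounded` rather than returned as a number.
* **Ties and ordering.** Gene sets are kept sorted; families are kept in a
  canonical lexicographic order; candidates are processed in that order.
  This makes runs byte-identical given a deterministic oracle.
* **Degenerate inputs.** Empty GPR → reaction never blockable; empty mode
  family → unblockable mode → empty catalog; `v_r = 0` coupling rows are
  encoded as two `≥` inequalities so every target is uniformly `A v ≥ b`;
  wild-type-infeasible targets fail at construction, loudly.

## What the fixtures emulate — and what they do not

The shipped fixtures are deliberately small and fully analyzable:

* the **ten-reaction GPR table** with three explicit mode supports (its
  published figure — the stoichiometry — is not available, so the target is
  carried as explicit supports; the hitting and driver layers accept
  those directly). The source text says "8 reactions" while tabulating ten
  rules; the fixture keeps all ten.
* the **diamond network** (5 reactions, 5 genes, two parallel routes), whose
  elementary modes are known by inspection, giving the LP-vs-enumeration
  agreement test.
* the **coupling toy** (a plain route and a co-producing route to biomass),
  whose single coupling-enforcing intervention and single biomass-blocking
  intervention are derivable by hand.

These exercise every code path but none of the features that make
genome-scale models hard: thousands of reactions, highly redundant isozyme
structure, numerically delicate stoichiometry, or media with dozens of
exchange bounds. A green test establishes algorithmic correctness at desk
scale, not performance or numerical robustness at genome scale; the
genome-scale acceptance test runs only when the published model files are
supplied alongside the repository.

## Known limitations

* The dense simplex is O(rows²·cols) per solve and is not meant for
  genome-scale matrices.
* Candidate evaluation is sequential; the oracle layer is structured so
  batched or parallel LP calls could be added without touching the driver.
* No MILP fallback, no dual-network construction, no gene-deletion matrix:
  these are the prior approaches this method replaces, not features of it.
* GPRs with negation or enzyme stoichiometry are out of scope.
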
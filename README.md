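# zsynkin

Formal reasoning about molecular pathways and reaction kinetics, as an
executable R toolkit. `zsynkin` is aimed at systems biologists and method
developers who want two complementary engines under one roof:

1. **Zsyntax pathway deduction.** Zsyntax is a deductive language for
   molecular biology: an *interaction* is an ordered list of molecules, an
   *aggregate* (conjunction) is an ordered list of interactions, and an
   *EVF* (empirically valid formula) is a lab-validated rewrite rule
   `reactants -> products`. Deduction repeatedly concatenates pairs of
   aggregate members, matches the concatenation against the EVF reactants
   (exact ordered equality — molecular interaction is not associative), and
   on a match consumes the pair and appends the products, respecting
   stoichiometric bookkeeping. The engine is fully deterministic: pairs are
   enumerated with both indices descending and the first match fires. A
   brute-force enumeration oracle (`zs_fixpoints()`) independently explores
   *every* firing order on small instances, so the engine's answer can be
   checked against the complete set of reachable fixpoints.

2. **Mass-action reaction kinetics.** A model is m ordered species and n
   reactions with integer stoichiometries `s`, `s'` and rate constants
   (`kf`, and `kr` for reversible reactions). The flux of reaction j is the
   law of mass action, `v_j = kf * prod_i [X_i]^(s_ij)` (minus the reverse
   term for reversible reactions), the stoichiometric matrix has entries
   `n_ij = s'_ij - s_ij`, and the species balance is the reaction rate
   equation system

   ```
   d[X]/dt = N v
   ```

   The package assembles this system (`ode_rhs()`), integrates it
   numerically (`simulate_model()`, via deSolve), and — its distinctive
   feature — **verifies closed-form solutions**: `verify_solution()`
   differentiates a candidate analytic solution structurally (`stats::D`),
   evaluates both sides of `d[X]/dt = N v` on a time grid, and reports the
   worst scaled residual per species, so a claimed solution is either
   confirmed to machine precision or rejected with the offending species
   named.

A model library ships every worked example: four generic consecutive
reaction schemes (irreversible A→B→C and the three reversible variants)
with their analytic solutions and validity assumptions, and two cancer stem
cell (CSC) tumor growth compartment models — the full model
(CSC/progenitor/differentiated/dead, eight first-order events) and a
reduced CSC/P/M model — plus the TP53 phosphorylation and CSC-death
deduction fixtures.

## Worked example

```r
library(zsynkin)

## Pathway deduction: TP53 phosphorylation
prob <- tp53_fixture()
zs_deduce(prob)
#> [[Kinase], [pTP53], [ADP]]       (final aggregate after two firings)
zs_deduce_check(prob)
#> [[pTP53]]                        (target pTP53 was produced)

## Kinetics: irreversible consecutive reactions A -> B -> C
p   <- list(A0 = 1, k1 = 1, k2 = 2)
sol <- scheme_solution("scheme_01", p)   # analytic catalog entry
solution_state(sol, 1)
#>         A         B         C
#> 0.3678794 0.2325442 0.3995764
verify_solution(build_scheme("scheme_01", p), sol)
#> Verification report (51 grid points, tol = 1e-08): PASS
#>   A        max scaled residual 0.000e+00
#>   B        max scaled residual 2.776e-17
#>   C        max scaled residual 0.000e+00
#>   assumptions: k1_positive=ok, k2_positive=ok, k2_minus_k1_nonzero=ok

## Tumor growth (reduced CSC model): living cells and tumor volume
pr   <- list(k1 = 1, k2 = 0.5, k3 = 2)
solr <- scheme_solution("tumor_reduced", pr)
total_cells(solr, 2)                     # N(2) = CSC(2) + P(2)
#> 0.6192376
tumor_volume(1e6 * total_cells(solr, 2)) # mm^3, at 4.18e-6 mm^3/cell
#> 2.588413
```

`solution_state(sol, 1)` says that one time unit in, 37% of the initial
amount is still A, 23% sits in the intermediate B and 40% has reached C;
the verification report confirms that these expressions satisfy the
assembled rate equations to floating-point precision (residuals ~1e-17,
far below the 1e-8 pass tolerance), with all validity assumptions (positive
rates, non-singular `k2 - k1` denominator) holding.

## Command line

A thin CLI ships at `inst/cli/zsynkin`
(`system.file("cli", "zsynkin", package = "zsynkin")`):

```sh
zsynkin fixtures --list
zsynkin fixtures --emit tp53 --out tp53.json
zsynkin deduce --problem tp53.json --trace
zsynkin build-odes --model scheme01.json
zsynkin simulate --model scheme01.json --t-max 10 --out traj.csv
zsynkin verify-solution --model-id scheme_03 --seed 7
```

Problems and models are strict JSON (`format_version: 1`); trajectories are
full-precision CSV.

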
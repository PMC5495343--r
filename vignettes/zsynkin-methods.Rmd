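---
title: "Methods: pathway deduction and kinetic solution verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway deduction and kinetic solution verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zsynkin)
```

# The deduction calculus

## Data model

A *molecule* is a case-sensitive token; an *interaction* is an ordered
character vector of molecules; an *aggregate* is an ordered list of
interactions. Order is meaningful at both levels: molecular interaction is
not associative, so `c("Kinase", "ATP")` and `c("ATP", "Kinase")` are
different interactions, and the engine compares interactions by exact
ordered equality — never by permutation or set semantics. EVF authors must
therefore write reactants in a consistent order; the TP53 fixture
illustrates this deliberately (its first EVF produces `[ATP, Kinase]` from
the pair `[Kinase, ATP]`, and only the reordered complex matches the second
EVF's reactant `[ATP, Kinase, TP53]`).

## One firing

Given an aggregate of length $n$ and $m$ EVFs, a scan (`zs_scan()`)
enumerates index pairs $(x, y)$ with $x = n-1, \dots, 0$ and, inside each
$x$, $y = n-1, \dots, 0$. For each pair the ordered concatenation of
members $x$ and $y$ is pushed onto the head of the aggregate
(`zs_introduce()`) and compared against EVF reactants at indices
$m-1, \dots, 0$ (`zs_match_evf()`). The first match fires: the head is
dropped, the matched EVF's products are appended at the end, and the two
consumed members are deleted — higher index first, so the lower index is
still valid (`zs_delete_pair()`). A firing therefore changes the aggregate
length by exactly $|\text{products}| - 2$, which the tests assert on every
recorded trace. This descending, first-match-wins enumeration makes the
engine fully deterministic; there is no randomness anywhere in deduction.

Two boundary behaviours are implemented literally rather than patched:

* **Self-pairs** ($x = y$) are allowed by the definitions. The pair
  deletion then takes its else-branch, which removes positions $y$ and
  $y+1$ of the working list. This is arguably surprising, so the engine
  performs it but signals a `self_pair_deletion` warning. The
  single-reaction law below explicitly excludes $x = y$.
* **Empty EVF products** are accepted by the engine (the firing simply
  removes the reactants) but rejected by the problem validator, since the
  behavioural laws assume non-empty products.

## Rounds and termination

A full deduction (`zs_deduce()`) repeats scans, one firing per round. The
default round bound equals the number of EVFs, matching the calculus'
definition of the final deduction function. That bound is not always
sufficient — an EVF may fire more than once — so a `"fixpoint"` mode
iterates until no scan matches, capped by a configurable hard limit
(default 10000). If the default bound runs out while a firing is still
possible the engine warns (`round_bound_exhausted`); if the hard limit runs
out in fixpoint mode it errors (`fixpoint_not_reached`) with the partial
aggregate attached. Both modes are exposed because neither dominates: the
default bound reproduces the calculus exactly, the fixpoint mode matches
the informal reading "repeat until nothing reacts".

## Behavioural laws and the enumeration oracle

Two laws characterise the engine on constrained inputs and are checked on
seeded random instances (1000 each in the acceptance suite):

* **No reaction**: if no EVF reactant equals any pair-concatenation of the
  aggregate (including self-pairs), deduction is the identity.
* **Single reaction**: if exactly one pair $(x', y')$, $x' \ne y'$, matches
  exactly one EVF $z$ — with all aggregate and product molecules distinct
  and EVF reactants pairwise distinct — the result is exactly
  `zs_delete_pair(aggregate ++ products(z), x', y')`.

Beyond the laws, `zs_fixpoints()` provides an independent oracle: an
exhaustive breadth-first enumeration of *every* firing order (all pair and
EVF choices at every step, with state deduplication) that returns the set
of reachable aggregates on which nothing can fire. On every test instance
the deterministic engine's result must be a member of that set. The oracle
is deliberately restricted to tiny instances (≤ 6 interactions, ≤ 4 EVFs,
depth ≤ 8) — it exists to catch semantic drift (wrong deletion order, wrong
enumeration direction), not to scale.

## The synthetic instance generator

`random_zsyntax_instance()` is seeded and deterministic. Its three modes
construct, by rejection sampling over a small molecule alphabet (≤ 8
tokens, ≤ 6 initial interactions, ≤ 4 EVFs):

* `no_reaction` — EVF reactants re-drawn until none equals any
  pair-concatenation of the initial aggregate;
* `single_reaction` — the initial aggregate is made of distinct singleton
  interactions; one EVF reactant is the concatenation of a chosen pair and
  its products are fresh molecules, so exactly one firing is possible and
  the post-firing aggregate is inert; the other EVFs get length-3 reactants,
  which can never equal a concatenation of two singletons;
* `free` — EVF reactants are biased (70%) toward pair-concatenations of the
  initial aggregate so that firing chains actually occur. Product sides are
  a single interaction, which keeps every firing strictly contracting: free
  instances then provably terminate within the oracle's enumeration depth,
  so the oracle-agreement property is exact rather than probabilistic.
  Aggregate-growing EVFs (more than two products) are exercised separately
  by the TP53 fixture, whose second firing grows the aggregate.

What the generated instances do **not** emulate: real EVF collections are
small, curated, and chemically meaningful; molecules are not interchangeable
tokens; and real deductions rarely involve self-pairs. Passing the laws on
random instances shows the *engine semantics* are right; it says nothing
about the biological validity of any particular EVF set.

# The kinetics engine

## Model and assembly

For $m$ species and $n$ reactions with reactant/product stoichiometries
$s_{ij}$, $s'_{ij}$, the flux of reaction $j$ under the law of mass action
is $v_j = k_j \prod_i [X_i]^{s_{ij}}$ for irreversible reactions and
$v_j = k_j^f \prod_i [X_i]^{s_{ij}} - k_j^r \prod_i [X_i]^{s'_{ij}}$ for
reversible ones. An irreversible reaction is encoded with $k_r = 0$ and the
constructor rejects anything else. The stoichiometric matrix has entries
$n_{ij} = s'_{ij} - s_{ij}$; it is *stored* reaction-major (rows are
reactions) and `ode_rhs()` applies the transpose, so the species balance
keeps the conventional shape $d[X]/dt = N v$. Rate constants are modelled
as non-negative reals (concentrations and rates are continuous quantities;
nothing in the machinery needs integrality). Concentrations are not stored
inside reactions: every flux function takes the current state vector, so
one model object serves all time points and the simulator.

## Closed-form solutions and the residual verifier

A `closed_form_solution` holds one entry per species: either a *value*
expression $X_i(t)$ (an R expression over the bound parameters and `t`) or
a *derivative-only* expression giving $dX_i/dt$ directly in terms of the
other species. Derivative-only entries model terminal compartments — in the
tumor models the dead-cell count M satisfies
$dM/dt = k_6\,\mathrm{CSC} + k_7 P + k_8 D$ and its absolute value never
feeds back into any flux, so no explicit $M(t)$ is needed (its
concentration is reported as 0 when a full state vector is required, which
is exact for every flux because M has zero reactant stoichiometry
everywhere).

`verify_solution()` checks a candidate solution in three steps, at every
grid time $t$:

1. reconstruct the state $X(t)$ from the value entries;
2. differentiate the value entries structurally with `stats::D` (and
   evaluate derivative-only entries at the reconstructed state);
3. assemble $N v$ at that state and form the per-species residual.

The residual is **scaled**: $|{\rm lhs} - {\rm rhs}| / \max(1, |{\rm lhs}|,
|{\rm rhs}|)$. The scaling matters because the tumor models grow
exponentially — with rates drawn up to 10 and a grid reaching $t = 10$, the
stem-cell compartment reaches $e^{100} \approx 10^{43}$, where any fixed
absolute tolerance is meaningless while the scaled residual stays at the
level of floating-point round-off ($\sim 10^{-16}$) whenever the identity
is algebraically true. The pass tolerance is $10^{-8}$: eight orders of
magnitude above round-off, yet a 1% corruption of any single species'
expression produces scaled residuals around $10^{-2}$–$10^{-4}$, so the
verifier separates true and corrupted solutions by many orders of magnitude
(the tests corrupt every species of every model and assert failure).

Assumption predicates are checked before any evaluation. Near-singular
parameters are rejected, not just exactly singular ones: each denominator
must exceed $10^{-6}$ times the local parameter scale, because close to a
singularity the closed forms lose accuracy through catastrophic
cancellation even though they are formally defined.

## The model catalog

Six models are cataloged with builders (`build_scheme()`) and solutions
(`scheme_solution()`):

| id | reactions | solution initial state |
|----|-----------|------------------------|
| `scheme_01` | A→B ($k_1$), B→C ($k_2$) | $A(0)=A_0$, $B(0)=C(0)=0$ |
| `scheme_02` | A→B ($k_1$); B⇌C ($k_2$, $k_3$) | same |
| `scheme_03` | A⇌B ($k_1$, $k_2$); B→C ($k_3$) | same |
| `scheme_04` | A⇌B ($k_1$, $k_2$); A→C ($k_3$) | same |
| `tumor_full` | CSC→2CSC ($k_1$), CSC→CSC+P ($k_2$), CSC→2P ($k_3$), P→2P ($k_4$), P→D ($k_5$), CSC→M ($k_6$), P→M ($k_7$), D→M ($k_8$) | $\mathrm{CSC}(0)=1$ |
| `tumor_reduced` | CSC→CSC+P ($k_1$), CSC→M ($k_2$), P→M ($k_3$) | $\mathrm{CSC}(0)=1$, $P(0)=1$ |

Schemes 2–4 use auxiliary exponents $r_1, r_2$: for scheme 2 they are
$r_1 = k_1$, $r_2 = k_2 + k_3$; for schemes 3 and 4 they are the roots of
$r^2 - (k_1+k_2+k_3) r + q = 0$ with $q = k_1 k_3$ (scheme 3) or $k_2 k_3$
(scheme 4), tie-broken $r_1 < r_2$. For positive rates the discriminant is
strictly positive, so the roots are always real and distinct. Users may
supply $r_1, r_2$ explicitly; they are then validated against these
defining constraints rather than silently recomputed.

Catalog conventions worth calling out:

* **Tumor normalisation.** The tumor solutions are dimensionless
  per-initial-stem-cell time courses: $\mathrm{CSC}(0) = 1$. The reduced
  model's progenitor solution has $P(0) = 1$ as well — that is what its
  published form $P(t) = ((k_3-k_2-k_1)e^{-k_3 t} + k_1 e^{-k_2 t})/(k_3-k_2)$
  evaluates to at $t = 0$, and the package keeps the expression verbatim
  (the verifier confirms it satisfies $dP/dt = k_1\,\mathrm{CSC} - k_3 P$
  regardless of the initial value). `total_cells()` therefore returns 2 at
  $t = 0$ for the reduced model and 1 for the full model.
* **Growth exponent.** The full tumor model's stem-cell course is
  $\mathrm{CSC}(t) = e^{(k_1-k_3-k_6)t}$: self-renewal minus symmetric
  differentiation minus death. Only this reading makes the rate-equation
  identity hold, which the verifier confirms at every parameter draw.
* **Tumor volume.** `tumor_volume()` multiplies a cell count by the
  effective volume of a spherically shaped cell in a spherical tumor,
  4.18×10⁻⁶ mm³/cell by default. The per-cell constant is an argument, not
  a hard-coded value, because reported values of this constant vary in
  sign-of-exponent between sources; the package treats the per-cell
  magnitude as authoritative.

## Numerical choices

* Verification grid: $t = 0$ plus 50 log-spaced points on
  $[10^{-3}, 10]$ — log spacing samples both the fast initial transient and
  the long-time behaviour of first-order networks.
* Parameter draws (`random_scheme_params()`): every rate (and $A_0$)
  log-uniform on $[10^{-2}, 10^{1}]$, the span typical of first-order rate
  constants in nondimensionalised models; draws violating a validity
  assumption are rejected and redrawn (up to 1000 times).
* Simulation: `deSolve::ode` (lsoda), defaults rtol $10^{-6}$ / atol
  $10^{-9}$; the closed forms serve as the oracle for the simulator, and
  agreement at rtol $10^{-6}$ is asserted for all six models.
* Differentiation is purely structural (`stats::D` on expression trees);
  there is no numeric fallback, so solution expressions must be built from
  the operators `stats::D` supports (`+ - * / ^ exp log sqrt` and friends) —
  every catalog entry is.
* Test problem sizes: the acceptance suite runs the deduction laws on 1000
  seeded instances per mode, oracle agreement on 200 free instances,
  verification on 100 parameter draws per model and simulation agreement on
  20 draws per model; together with the unit suite this completes in well
  under a minute on one core.

## Known limitations

* Strictly mass-action: no Michaelis–Menten or Hill kinetics, no stochastic
  (Gillespie) simulation, no SBML import, no parameter estimation.
* The deduction engine implements the calculus' executable fragment;
  it produces aggregates and traces, not formal proofs.
* Verification samples a finite grid. A residual of $10^{-16}$ at 51 points
  is overwhelming evidence for an algebraic identity of smooth
  exponential-polynomial expressions, but it is a numerical check, not a
  symbolic proof.
* The closed forms are valid away from parameter singularities only; the
  near-singular rejection band ($10^{-6}$ relative) is a pragmatic choice,
  and users working deliberately close to degeneracy (e.g. $k_2 \to k_1$ in
  scheme 1) should reformulate the solution in its confluent form instead.
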
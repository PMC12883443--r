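---
title: "Boolean network sketches: model, semantics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean network sketches: model, semantics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsketch)
```

## The modelling problem

Boolean networks model gene regulation with 0/1 variables, each updated by
a Boolean function of its regulators.  Building such a model from partial
knowledge — a plausible wiring diagram, signs for some interactions,
binarized steady states or trajectories — is an inference problem with, in
general, astronomically many consistent answers.  A *sketch* makes the
partial knowledge itself the model: an influence graph, update expressions
that may contain uninterpreted function symbols, first-order constraints on
the update functions, and HCTL constraints on the dynamics.  Inference then
means computing the *entire* set of concrete Boolean networks consistent
with the sketch, exactly and symbolically, rather than enumerating
candidates one by one.

## Parameter encoding

Every function symbol `g` of arity `k` is encoded by `2^k` Boolean
parameters, one per truth-table row, with rows in binary order and the
first argument as the most significant bit.  A *colour* is a full
assignment of all parameters — one interpretation of every symbol, hence
one concrete network.  An application `g(e1, ..., ek)` inside an update
expression compiles to the row multiplexer

```
OR over rows w of:  p_{g,w}  AND  AND_i (e_i <=> w_i)
```

realized as a Shannon cascade on the already-compiled argument functions,
so nested and shared applications (`g(h(A), B)`, the same `g` used by two
variables) work by construction.  With no constraints the candidate count
is `2^(total parameter bits)`: candidates are counted as *interpretations*,
without semantic deduplication — two colours that differ only in a
parameter of an unused table row count twice.  This is the only
well-defined count without quotienting, and it matches the
product-of-table-sizes scale on which such candidate spaces are usually
reported.

All symbolic objects — update functions `F_v(state, params)`, coloured
state sets, colour sets — are reduced ordered binary decision diagrams
(BDDs) built by a small hash-consed C++ kernel.  The global variable order
interleaves each state bit with its bound-state copies (used by HCTL) and
puts parameter bits last; state-to-copy renaming is then order-preserving,
which keeps the rename operation linear.  Nodes are never garbage
collected; a node cap (~2M) bounds memory and fails loudly instead of
thrashing.

## Asynchronous semantics

A transition updates exactly one variable whose update function disagrees
with its current value; consequently there are **no self-loops** and fixed
points are deadlock states.  Because the self-loop convention is not
universal across tools, all fixed-point reasoning uses the *structural*
predicate `AND_v (F_v(s) = s_v)` rather than `~EX true`, which makes the
results convention-independent.  `AX` is vacuously true at deadlocks (the
standard Kripke convention); this matters exactly at fixed points and is
therefore stated here.

Successor/predecessor images are per-variable BDD operations (`flip` of
one state bit conjoined with the transition-enabled predicate), and
reachability is plain chaotic iteration to a fixpoint — adequate at the
problem sizes this package targets (the kernel saturates small models in
milliseconds; no per-variable saturation ordering is implemented).

## Static constraints

Regulation-level essentiality and monotonicity are defined on the
**instantiated** update function of the target, `F_v`, not on the raw
symbol table: update expressions may be compound, and this is the only
definition well-formed for arbitrary expressions.  Symbol-level variants
constrain the raw table, quantifying over the remaining arguments.  The
two coincide when the update is exactly the symbol applied to the
regulators in order (a property the tests assert).

Free-form properties are closed first-order formulas over Booleans:

```
formula   := "forall" ID ":" formula | "exists" ID ":" formula | iff
iff       := imp ("<=>" imp)*
imp       := xor ("=>" imp)?          # right associative
xor       := or ("^" or)*
or        := and ("|" and)*
and       := unary ("&" unary)*
unary     := "!" unary | atom
atom      := "0" | "1" | "true" | "false" | ID | ID "(" args ")" | "(" formula ")"
```

Bound variables are Boolean scalars; network state variables may not
appear (state-dependent constraints are dynamic properties).  Quantifiers
are expanded over the two-element domain — bound variables are few in
practice and the expansion is trivially auditable, so no solver is
involved.  The concrete syntax is this package's own; it is part of the
sketch JSON document and versioned with it.

## HCTL and its templates

The dynamic logic is CTL plus state variables: binder `!{x}:` (bind the
current state), jump `@{x}:` (evaluate at the bound state), existential
quantification `3{x}:`.  Precedence, loosest to tightest: quantifier
prefixes; `<=>`; `=>`; `^`; `|`; `&`; infix `EU`/`AU`; unary
`~ ! EX AX EF AF EG AG`; atoms are variable names (`v` means `v = 1`),
`~v`, `0/1/true/false`, `{x}`, and the structural predicate
`fixed_point`.  `!` is a binder only when followed by `{`; otherwise it is
negation.

Checking is bottom-up over coloured state sets with one copy of the state
bits per bound state variable: `{x}` denotes the diagonal (current state
equals the `x`-copy), binder conjoins with the diagonal and projects the
copies out, jump substitutes the copies for the state bits (implemented as
`exists state. (result AND diagonal)`), and the temporal operators are the
standard mu/nu iterations over the predecessor image, with the `A`-forms
obtained by duality.

A colour satisfies a closed formula iff **every** state does (universal
convention).  The templates make this invisible — they wrap their content
in outer `3{x}: @{x}:` so results are state-independent — but a raw user
formula such as `AG EF v` can still depend on the current state, in which
case a warning states that the universal convention was applied.
Templates:

* *fixed points* over dataset `D`: for every observation `o`,
  `3{x}: @{x}: (obs(o) & fixed_point)`;
* *attractor count* in `[m, M]`: "at least m" uses `m` quantified states,
  each an attractor state (`@{x_i}: !{y}: AG EF {y}`) and pairwise
  unreachable (`@{x_i}: ~EF {x_j}`); "exactly" conjoins the negated
  "at least M+1".  Each bound adds a copy of the state bits, so bounds are
  capped at 8 with a clear error;
* *attractor coverage* of `D`: `~ 3{x}: @{x}: ((!{y}: AG EF {y}) & AND_o ~obs(o))`
  — no attractor state outside the observations.  Applied after the
  fixed-points template this is the classic refinement "only the observed
  steady states, no complex attractors";
* *time series* over `D = o1..ok`: `3{x}: @{x}: (obs(o1) & EF (obs(o2) & EF ...))`.

## Inference, counting, sampling

Inference intersects the full colour space with, in order: constraints
derived from regulation annotations (a declared sign is a monotonicity
constraint, a declared essentiality an essentiality constraint; `unknown`
generates nothing), the explicit static properties, and the dynamic
properties in declaration order, recording the exact count after each
stage.  Intersection commutes, so the final set is order-independent (a
tested invariant); the staging exists for the report and for early
emptiness detection.  Counts use exact arbitrary-precision integers — a
`bigint` class on base-1e9 digits — because candidate spaces beyond `2^53`
are routine.  Sampling descends the BDD weighting branches by per-node
model counts; branch probabilities are double-precision ratios of exact
counts (relative error ~1e-15, far below anything a goodness-of-fit test
at realistic sample sizes can resolve).  Per-variable variant counts
partition the candidate set recursively on the row functions
`F_v(row, ·)`; variables whose update touches more than 20 parameter bits
are reported `NA` rather than failing.

## The explicit oracle and the synthetic study conditions

Every symbolic operation is validated against an explicit-state reference:
enumeration of all interpretations (guard: ≤ 24 parameter bits), direct
recursive HCTL evaluation over the explicit transition graph (guard: ≤ 12
variables; binder/jump/quantifier via environments mapping state variables
to states, memoized per subformula and relevant environment slice), and
whole-sketch filtering.  Attractor-count properties are checked in the
oracle by direct bottom-SCC analysis — an algorithm disjoint from the HCTL
template they expand to, which strengthens the cross-validation.

The synthetic generator draws a ground-truth network (in-degree capped at
3; tables resampled until every declared regulator is essential, so the
influence graph never lies), hides a fraction of updates behind fresh
symbols, annotates signs only where the true table is monotone, and emits
observations from the ground truth's actual behaviour — genuine fixed
points, or states along a genuine asynchronous trajectory.  The emitted
sketch is therefore satisfiable by construction and the ground-truth
colour must survive inference; with nothing hidden the candidate set is
exactly the ground truth.  Default study conditions: density 0.45, hidden
fraction 0.6, sign probability 0.4, 1–2 observations; the equivalence
suites run at ≤ 5 variables and ≤ 10 parameter bits (200 sketches) and the
retention suite at ≤ 12 bits (100 sketches) so the brute-force oracle
remains enumerable in seconds.  What passing these suites shows is
agreement of the two engines and soundness of the generator under these
conditions; it does not certify behaviour on real transcriptomics data,
where binarization error and unsatisfiable sketches (empty candidate sets)
are the common failure modes — both are reported honestly (empty set, not
an error) but not modelled by the generator.

## Degenerate inputs and numerical corners

Empty sketches validate cleanly; a variable with no regulators gets a
nullary symbol (two interpretations: constants 0/1).  Contradictory
properties yield an empty candidate set, never an error.  Observation
atoms with no mapped variables denote `true`.  Duplicate quantifier names
shadow in FOL, and rebinding a state variable on one HCTL path is a parse
error.  Import of a candidate-set container verifies the recorded
parameter ordering against the PSBN it ships and refuses mismatches.

## Known limitations

Only the fully asynchronous semantics is implemented (no synchronous or
most-permissive update).  Multi-valued variables, SBML-qual import,
second-order quantification and cardinality constraints on update-function
clauses are out of scope.  The BDD kernel does no dynamic variable
reordering and no garbage collection; very large sketches will hit the
node cap.  Inference runs blocking; there is no cancellable session API.
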
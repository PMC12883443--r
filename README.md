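# bnsketch

Inference of Boolean network models from partial knowledge, for systems
biologists who know *some* of a regulatory network — its plausible wiring, a
few signs, a handful of binarized expression states — and want **all** models
consistent with that knowledge, not one arbitrary fit.

## The formalism

A **Boolean network sketch** is a partial specification with four parts:

* an **influence graph**: the possible regulations between variables, each
  optionally annotated as positive/negative (activation/inhibition) and as
  essential (must have an effect);
* a **partially specified Boolean network (PSBN)**: one update expression per
  variable, which may contain *uninterpreted function symbols* `g(...)` for
  unknown parts of the logic.  Substituting a concrete Boolean function for
  every symbol (an *interpretation*, or *colour*) yields an ordinary BN;
* **static properties**: first-order constraints over Booleans on the update
  functions — essentiality, monotonicity, or free-form formulas such as
  `forall a: g(a, 1)`;
* **dynamic properties**: constraints on the fully asynchronous dynamics,
  written in **HCTL** (CTL extended with state variables: binder `!{x}:`,
  jump `@{x}:`, existential quantifier `3{x}:`), or generated from
  observation datasets by templates (fixed points, time series, attractor
  count, attractor coverage).

Each symbol of arity *k* contributes one Boolean parameter per truth-table
row (2^k of them).  All operators run on binary decision diagrams over
state bits × parameter bits, so every colour is handled simultaneously: the
result of inference is the exact symbolic set of interpretations

&nbsp;&nbsp;&nbsp;&nbsp;`C = { c : BN(c) ⊨ every static and dynamic property }`

which the package counts exactly (arbitrary precision), samples uniformly,
summarizes per variable, and exports as a portable container.  An attractor
here is a terminal SCC of the asynchronous state-transition graph; in HCTL,
a state satisfying `!{x}: AG EF {x}`.

## Worked example

One self-regulating gene with fully unknown logic, `x := g(x)`, and a
steady-state observation `x = 1`:

```r
library(bnsketch)

g     <- influence_graph("x", data.frame(source = "x", target = "x"))
psbn  <- new_psbn(g, updates = list(x = "g(x)"))
obs   <- new_dataset("D", list(new_observation("o1", c(x = 1))), "steady_state")
sketch <- new_sketch(psbn,
  datasets           = list(obs),
  dynamic_properties = list(dyn_fixed_points("D")))

r <- run_inference(sketch)
r$report
#> Inference report
#>   consistent with PSBN: 4
#>   after static properties: 4
#>   after fixed_points_D: 2
#>   final: 2
#>   update-function variants per variable:
#>     x: 2
#>   elapsed: 0.01 s
```

Four interpretations of the unary symbol `g` exist (the four unary Boolean
functions); requiring a fixed point at `x = 1` forces `g(1) = 1`, leaving
the two tables `01` (identity) and `11` (constant one) — hence the count 2
and 2 update-function variants for `x`.  Refining with
`dyn_attractor_coverage("D")` ("no attractor outside the observations")
additionally discards the table that also stabilizes `x = 0`, leaving 1.

Sampled candidates are concrete networks:

```r
cat(write_bnet(sample_candidates(r$candidates, 1, seed = 1)[[1]]))
#> targets, factors
#> x, 1
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/bnsketch.R infer sketch.json --out out/
Rscript inst/cli/bnsketch.R sample out/candidates.json -n 3 --seed 7 --format bnet
```

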
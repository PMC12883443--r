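Package: bnsketch
Title: Boolean Network Sketches: Partial Specification and Symbolic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of Boolean network sketches: partially
    specified Boolean networks (influence graph plus update expressions that
    may contain uninterpreted function symbols), first-order static
    constraints on the update functions (essentiality, monotonicity, free-form
    formulas), and dynamic constraints written in HCTL, a hybrid extension of
    computation tree logic, evaluated over the coloured fully asynchronous
    state-transition graph.  A symbolic engine based on reduced ordered binary
    decision diagrams computes, counts, uniformly samples, and summarizes the
    complete set of Boolean networks consistent with a sketch.  Includes
    readers and writers for AEON model files, BoolNet .bnet output,
    observation CSV tables and a JSON sketch document, plus an explicit-state
    reference engine and a synthetic sketch generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
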
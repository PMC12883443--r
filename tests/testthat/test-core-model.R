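graph_abc <- function() {
  influence_graph(
    c("A", "B", "C"),
    data.frame(
      source = c("A", "B", "A"), target = c("C", "C", "B"),
      sign = c("positive", "unknown", "unknown"),
      essential = c("unknown", "unknown", "unknown")
    )
  )
}

test_that("default update expressions are deterministic symbol applications", {
  g <- graph_abc()
  d <- default_update_expr("C", g)
  expect_equal(d$symbol$arity, 2L)
  expect_equal(format_update_expr(d$expr), "g_C(A, B)")
  # regulator order is lexicographic regardless of declaration order
  g2 <- influence_graph(c("C", "Z", "A"), data.frame(
    source = c("Z", "A"), target = c("C", "C")
  ))
  expect_equal(format_update_expr(default_update_expr("C", g2)$expr), "g_C(A, Z)")
  # no regulators -> nullary symbol
  g3 <- influence_graph("A")
  expect_equal(format_update_expr(default_update_expr("A", g3)$expr), "g_A()")
  expect_equal(default_update_expr("A", g3)$symbol$arity, 0L)
  # collision -> deterministic suffix
  d2 <- default_update_expr("C", g, used_names = "g_C")
  expect_equal(d2$symbol$name, "g_C_1")
  # determinism
  expect_identical(default_update_expr("C", g), default_update_expr("C", g))
})

test_that("validate_sketch flags non-regulator references as errors", {
  g <- graph_abc()
  psbn <- new_psbn(g, updates = list(C = "A & B", B = "C")) # C does not regulate B
  iss <- validate_sketch(new_sketch(psbn))
  expect_true(any(iss$severity == "error" & grepl("C is not a regulator of B", iss$message)))
})

test_that("an empty sketch validates cleanly and unused regulators warn", {
  empty <- new_sketch(new_psbn(influence_graph()))
  expect_equal(nrow(validate_sketch(empty)), 0L)

  g <- graph_abc()
  psbn <- new_psbn(g, updates = list(C = "B")) # regulation (A, C) never read
  iss <- validate_sketch(new_sketch(psbn))
  unused <- iss[grepl("never reads A", iss$message), , drop = FALSE]
  expect_equal(unused$severity, "warning")
  # with an essentiality property the same situation is unsatisfiable
  sk <- new_sketch(psbn, static_properties = list(prop_regulation_essential("A", "C")))
  iss2 <- validate_sketch(sk)
  expect_true(any(grepl("no candidate can satisfy", iss2$message)))
})

test_that("property and dataset references must resolve", {
  g <- graph_abc()
  psbn <- new_psbn(g)
  sk <- new_sketch(
    psbn,
    static_properties = list(
      prop_regulation_monotone("C", "A", "positive"), # not declared
      prop_symbol_essential("g_C", 5L) # index out of range
    ),
    dynamic_properties = list(dyn_fixed_points("nope"))
  )
  iss <- validate_sketch(sk)
  expect_true(any(grepl("regulation \\(C, A\\) is not declared", iss$message)))
  expect_true(any(grepl("argument index 5 out of range", iss$message)))
  expect_true(any(grepl("unknown dataset 'nope'", iss$message)))
})

test_that("sketch JSON round-trips with identical document and issues", {
  g <- graph_abc()
  psbn <- new_psbn(g, updates = list(C = "g(A, B)"))
  d <- new_dataset(
    "D",
    list(
      new_observation("o1", c(A = 1, B = 0, C = 1)),
      new_observation("o2", c(A = 0)) # partial
    ),
    "steady_state"
  )
  sk <- new_sketch(
    psbn,
    static_properties = list(
      prop_regulation_monotone("B", "C", "negative"),
      prop_fol("forall a: g(a, 1) => g(a, 0)")
    ),
    datasets = list(d),
    dynamic_properties = list(
      dyn_fixed_points("D"),
      dyn_attractor_count(1, Inf),
      dyn_hctl("3{x}: @{x}: (AG (EF {x}))")
    ),
    annotations = list(A = "sepal identity gene", D = "binarized scRNA")
  )
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_sketch(sk, p1)
  sk2 <- read_sketch(p1)
  write_sketch(sk2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(validate_sketch(sk), validate_sketch(sk2))
  # counts agree too
  expect_true(count_candidates(run_inference(sk)$candidates) ==
    count_candidates(run_inference(sk2)$candidates))
})
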
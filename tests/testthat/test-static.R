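# Static-constraint compilation validated against exhaustive filters over
# all 2^(2^k) truth tables.

unary_ctx <- function() {
  psbn <- one_var_psbn("g(x)")
  bnsketch:::new_context(psbn)
}

test_that("essentiality of a regulation matches the brute-force filter", {
  ctx <- unary_ctx()
  set <- essentiality_of_regulation(ctx, "x", "x")
  expect_equal(count_colour_set(ctx, set), 2) # tables 01 and 10
  oracle <- sum(vapply(oracle_all_tables(1), function(t) oracle_essential(t, 1, 0), TRUE))
  expect_equal(count_colour_set(ctx, set), oracle)

  # fixed function with u essential: full colour space
  g <- influence_graph(c("u", "w", "v"), data.frame(
    source = c("u", "w"), target = c("v", "v")
  ))
  psbn <- new_psbn(g, updates = list(v = "u | w", u = "u", w = "w"))
  ctx2 <- bnsketch:::new_context(psbn)
  expect_equal(essentiality_of_regulation(ctx2, "u", "v"), bnsketch:::bdd_true)
  # u never read: empty set
  psbn3 <- new_psbn(g, updates = list(v = "w", u = "u", w = "w"))
  ctx3 <- bnsketch:::new_context(psbn3)
  expect_equal(essentiality_of_regulation(ctx3, "u", "v"), bnsketch:::bdd_false)
  expect_error(essentiality_of_regulation(ctx3, "w", "u"), "not declared")
})

test_that("monotone colour counts equal the exhaustive enumeration for k = 1..4", {
  # 3, 6, 20, 168 monotone-in-every-argument functions
  expected <- c(3, 6, 20, 168)
  for (k in 1:4) {
    vars <- letters[seq_len(k)]
    g <- influence_graph(c(vars, "v"), data.frame(source = vars, target = "v"))
    ups <- c(
      stats::setNames(as.list(vars), vars),
      list(v = sprintf("g(%s)", paste(vars, collapse = ", ")))
    )
    psbn <- new_psbn(g, updates = ups)
    ctx <- bnsketch:::new_context(psbn)
    set <- bnsketch:::bdd_true
    for (i in seq_len(k) - 1L) {
      set <- bnsketch:::bdd_and(
        ctx$mgr, set,
        compile_symbol_property(ctx, "g", i, "monotone", "positive")
      )
    }
    expect_equal(count_colour_set(ctx, set), expected[k], label = sprintf("k=%d", k))
    oracle <- sum(vapply(oracle_all_tables(k), function(t) {
      all(vapply(seq_len(k) - 1, function(a) oracle_monotone(t, k, a), TRUE))
    }, TRUE))
    expect_equal(oracle, expected[k])
  }
})

test_that("binary-symbol essentiality and combined constraints count correctly", {
  g <- influence_graph(c("u", "w", "v"), data.frame(
    source = c("u", "w"), target = c("v", "v")
  ))
  psbn <- new_psbn(g, updates = list(v = "g(u, w)", u = "u", w = "w"))
  ctx <- bnsketch:::new_context(psbn)
  m <- ctx$mgr
  ess <- bnsketch:::bdd_and(
    m,
    compile_symbol_property(ctx, "g", 0L, "essential"),
    compile_symbol_property(ctx, "g", 1L, "essential")
  )
  expect_equal(count_colour_set(ctx, ess), 10) # 16 minus tables ignoring an argument
  mono <- bnsketch:::bdd_and(
    m,
    compile_symbol_property(ctx, "g", 0L, "monotone", "positive"),
    compile_symbol_property(ctx, "g", 1L, "monotone", "positive")
  )
  both <- bnsketch:::bdd_and(m, ess, mono)
  expect_equal(count_colour_set(ctx, both), 2) # AND and OR only
  # regulation-level and symbol-level coincide when update is g(regulators)
  reg <- bnsketch:::bdd_and(
    m,
    essentiality_of_regulation(ctx, "u", "v"),
    essentiality_of_regulation(ctx, "w", "v")
  )
  expect_equal(reg, ess)
  reg_mono <- bnsketch:::bdd_and(
    m,
    monotonicity_of_regulation(ctx, "u", "v", "positive"),
    monotonicity_of_regulation(ctx, "w", "v", "positive")
  )
  expect_equal(reg_mono, mono)
})

test_that("first-order formulas compile to the right colour sets", {
  g <- influence_graph(c("u", "w", "v"), data.frame(
    source = c("u", "w"), target = c("v", "v")
  ))
  psbn <- new_psbn(g, updates = list(v = "g(u, w)", u = "u", w = "w"))
  ctx <- bnsketch:::new_context(psbn)
  # forall a: g(a, 1)  ->  p_g[01] & p_g[11]: 4 of 16
  s1 <- compile_fol(parse_fol("forall a: g(a, 1)"), ctx)
  expect_equal(count_colour_set(ctx, s1), 4)
  # symmetric tables: 8 of 16
  s2 <- compile_fol(parse_fol("forall a: forall b: (g(a, b) <=> g(b, a))"), ctx)
  expect_equal(count_colour_set(ctx, s2), 8)
  # conjunction of compiled properties == compilation of the conjoined formula
  s3 <- compile_fol(parse_fol("(forall a: g(a, 1)) & (forall a: forall b: (g(a, b) <=> g(b, a)))"), ctx)
  expect_equal(bnsketch:::bdd_and(ctx$mgr, s1, s2), s3)

  ctx1 <- unary_ctx()
  s4 <- compile_fol(parse_fol("exists a: g(a)"), ctx1)
  expect_equal(count_colour_set(ctx1, s4), 3)

  expect_error(parse_fol("g(a)"), "unbound")
  expect_error(parse_fol("forall a: g(a,"), "parse error")
})
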
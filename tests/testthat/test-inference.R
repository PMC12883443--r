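fp_sketch <- function() {
  psbn <- one_var_psbn("g(x)")
  d <- new_dataset("D", list(new_observation("o1", c(x = 1))), "steady_state")
  new_sketch(psbn,
    datasets = list(d),
    dynamic_properties = list(dyn_fixed_points("D"))
  )
}

test_that("inference counts shrink monotonically and match hand counts", {
  r <- run_inference(fp_sketch())
  expect_true(r$report$counts$initial == 4)
  expect_true(r$report$counts$final == 2) # colours with p_g[1] = 1
  expect_true(count_candidates(r$candidates) == 2)

  # contradictory properties give an empty set, not an error
  psbn <- one_var_psbn("g(x)")
  d <- new_dataset("D", list(new_observation("o1", c(x = 1))), "steady_state")
  sk <- new_sketch(psbn,
    static_properties = list(prop_fol("forall a: !g(a)")),
    datasets = list(d),
    dynamic_properties = list(dyn_fixed_points("D"))
  )
  r2 <- run_inference(sk)
  expect_true(r2$report$counts$final == 0)
  expect_error(sample_candidates(r2$candidates, 1), "no candidates")
})

test_that("candidate counts are exact beyond double precision", {
  # 60 nullary symbols: 2^60 interpretations, not representable exactly
  # as consecutive doubles
  vars <- sprintf("n%02d", 1:60)
  g <- influence_graph(vars)
  ups <- stats::setNames(lapply(vars, function(v) sprintf("c_%s()", v)), vars)
  psbn <- new_psbn(g, updates = ups)
  r <- run_inference(new_sketch(psbn), summarize = FALSE)
  expect_equal(as.character(r$report$counts$final), "1152921504606846976")
})

test_that("sampled candidates are members and seeds reproduce them", {
  r <- run_inference(fp_sketch())
  s1 <- sample_candidates(r$candidates, 5, seed = 42)
  s2 <- sample_candidates(r$candidates, 5, seed = 42)
  expect_identical(s1, s2)
  for (bn in s1) {
    expect_equal(unname(bn$colour["g[1]"]), 1L) # the defining constraint
    expect_equal(bn$functions$x$table[2], 1L)
  }
})

test_that("sampling is uniform over an enumerable constrained set", {
  # x := g(x, y), y := y with g essential in both arguments: 10 of 16
  g <- influence_graph(c("x", "y"), data.frame(
    source = c("x", "y", "y"), target = c("x", "x", "y")
  ))
  psbn <- new_psbn(g, updates = list(x = "g(x, y)", y = "y"))
  sk <- new_sketch(psbn, static_properties = list(
    prop_symbol_essential("g", 0L),
    prop_symbol_essential("g", 1L)
  ))
  r <- run_inference(sk)
  expect_true(r$report$counts$final == 10)
  draws <- sample_candidates(r$candidates, 3000, seed = 7)
  keys <- vapply(draws, function(bn) paste(bn$colour, collapse = ""), "")
  tab <- table(keys)
  expect_equal(length(tab), 10) # every model hit
  p <- stats::chisq.test(as.vector(tab))$p.value
  expect_gt(p, 0.001)
})

test_that("variant summaries count distinct instantiated tables", {
  r <- run_inference(fp_sketch())
  v <- summarize_variants(r$candidates)
  expect_equal(unname(v["x"]), 2) # tables 01 and 11
  # fully specified variable: always 1; unconstrained unary symbol: 4
  g <- influence_graph(c("a", "b"), data.frame(
    source = c("a", "a"), target = c("a", "b")
  ))
  psbn <- new_psbn(g, updates = list(a = "!a", b = "g(a)"))
  r2 <- run_inference(new_sketch(psbn))
  v2 <- summarize_variants(r2$candidates)
  expect_equal(unname(v2[c("a", "b")]), c(1, 4))
  # empty set: zero variants everywhere
  sk0 <- new_sketch(psbn, static_properties = list(prop_fol("false")))
  v0 <- summarize_variants(run_inference(sk0)$candidates)
  expect_equal(unname(v0[c("a", "b")]), c(0, 0))
})

test_that("the candidate-set container round-trips losslessly", {
  r <- run_inference(fp_sketch())
  path <- withr::local_tempfile(fileext = ".json")
  export_candidate_set(r$candidates, path)
  back <- import_candidate_set(path)
  expect_true(count_candidates(back) == count_candidates(r$candidates))
  expect_identical(candidate_colours(back), candidate_colours(r$candidates))
  # empty sets round-trip
  sk0 <- new_sketch(one_var_psbn("g(x)"),
    static_properties = list(prop_fol("false"))
  )
  r0 <- run_inference(sk0)
  p0 <- withr::local_tempfile(fileext = ".json")
  export_candidate_set(r0$candidates, p0)
  expect_true(count_candidates(import_candidate_set(p0)) == 0)
  # tampering with the parameter ordering is rejected
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$param_names <- rev(doc$param_names)
  p_bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, p_bad, auto_unbox = TRUE)
  expect_error(import_candidate_set(p_bad), "does not match")
  doc$format <- "something/else"
  jsonlite::write_json(doc, p_bad, auto_unbox = TRUE)
  expect_error(import_candidate_set(p_bad), "unsupported")
})

test_that("the candidate set is order-invariant and monotone in properties", {
  gen <- random_small_sketch(7)
  sk <- gen$sketch
  # append a mild static property to have several to permute
  regs <- sk$psbn$graph$regulations
  extra <- prop_regulation_essential(regs$source[1], regs$target[1])
  sk$static_properties <- c(sk$static_properties, list(extra))
  base <- run_inference(sk, summarize = FALSE)
  perm <- sk
  perm$dynamic_properties <- rev(perm$dynamic_properties)
  alt <- run_inference(perm, summarize = FALSE)
  expect_identical(candidate_colours(base$candidates), candidate_colours(alt$candidates))
  # dropping the extra property can only grow the set
  sk_less <- sk
  sk_less$static_properties <- list()
  more <- run_inference(sk_less, summarize = FALSE)
  expect_true(count_candidates(more$candidates) >= count_candidates(base$candidates))
})
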
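test_that("AEON regulation lines map to signs and essentiality", {
  r <- read_aeon("A -> B\nB -| A\n")
  expect_setequal(r$graph$variables, c("A", "B"))
  regs <- r$graph$regulations
  expect_equal(regs$sign[regs$source == "A"], "positive")
  expect_equal(regs$sign[regs$source == "B"], "negative")
  expect_equal(unique(regs$essential), "true")
  # '?' suffix marks non-essential; '-?' is unknown sign
  r2 <- read_aeon("A ->? B\nA -?? C\nC -? A\n")
  regs2 <- r2$graph$regulations
  expect_equal(regs2[regs2$target == "B", "essential"], "unknown")
  expect_equal(regs2[regs2$target == "B", "sign"], "positive")
  expect_equal(regs2[regs2$target == "C", "sign"], "unknown")
  expect_equal(regs2[regs2$target == "C", "essential"], "unknown")
  expect_equal(regs2[regs2$source == "C", "essential"], "true")
  expect_error(read_aeon("A --> B\n"), "malformed AEON line 1")
  expect_warning(read_aeon("# name: model\nA -> B\n"), "metadata")
})

test_that("AEON update lines parse and the write/read cycle is stable", {
  txt <- "A -> B\nB -| A\n$A: !B\n$B: g(A)\n"
  r <- read_aeon(txt)
  expect_equal(sort(names(r$updates)), c("A", "B"))
  psbn <- new_psbn(r$graph, updates = as.list(r$updates))
  out <- write_aeon(psbn)
  r2 <- read_aeon(out)
  psbn2 <- new_psbn(r2$graph, updates = as.list(r2$updates))
  expect_identical(write_aeon(psbn2), out)
  # a variable declared only via '$' with no update for others defaults
  r3 <- read_aeon("$C: 1\n")
  expect_equal(r3$graph$variables, "C")
})

test_that("observation CSV parses blanks as unconstrained and rejects junk", {
  csv <- "id,A,B\no1,1,\no2,0,1\n"
  d <- read_observations_csv(csv, id = "D", category = "steady_state")
  expect_equal(length(d$observations), 2L)
  expect_equal(d$observations[[1]]$values, c(A = 1L))
  expect_equal(d$observations[[2]]$values, c(A = 0L, B = 1L))
  expect_error(
    read_observations_csv("id,A\no1,2\n"),
    "non-binary cell '2' at row 1"
  )
  expect_error(
    read_observations_csv("id,A\no1,1\no1,0\n"),
    "duplicate observation id"
  )
  # round trip
  out <- write_observations_csv(d, variables = c("A", "B"))
  expect_equal(out, csv)
  # row order is preserved
  expect_equal(vapply(d$observations, function(o) o$id, ""), c("o1", "o2"))
})

test_that("the shipped example files load into a working sketch", {
  aeon <- system.file("extdata", "example.aeon", package = "bnsketch")
  csv <- system.file("extdata", "example_observations.csv", package = "bnsketch")
  expect_warning(r <- read_aeon(aeon), "metadata")
  psbn <- new_psbn(r$graph, updates = as.list(r$updates))
  d <- read_observations_csv(csv, id = "expr", category = "steady_state")
  sk <- new_sketch(psbn,
    datasets = list(d),
    dynamic_properties = list(dyn_fixed_points("expr"))
  )
  expect_false(any(validate_sketch(sk)$severity == "error"))
  res <- run_inference(sk, summarize = FALSE)
  # g_A arity 1, g_C arity 1 (defaulted): 16 interpretations before data
  expect_true(res$report$counts$initial == 16)
  expect_true(res$report$counts$final <= 16)
})

test_that("bnet output is a canonical DNF that re-evaluates to the table", {
  psbn <- one_var_psbn("!x")
  bn <- instantiate_bn(psbn, integer(0))
  expect_equal(write_bnet(bn), "targets, factors\nx, !x\n")
  # constant variable
  g <- influence_graph(c("u", "v"), data.frame(source = "u", target = "v"))
  p2 <- new_psbn(g, updates = list(u = "0", v = "g(u)"))
  bn2 <- instantiate_bn(p2, c("g[0]" = 0L, "g[1]" = 0L))
  lines <- strsplit(write_bnet(bn2), "\n")[[1]]
  expect_true("u, 0" %in% lines)
  expect_true("v, 0" %in% lines)
  # random tables: parse the emitted DNF and re-evaluate every row
  set.seed(99)
  for (rep in 1:10) {
    regs <- c("a", "b", "c")
    tab <- as.integer(stats::runif(8) < 0.5)
    fake <- structure(
      list(
        variables = "z",
        functions = list(z = list(regulators = regs, table = tab))
      ),
      class = "concrete_bn"
    )
    line <- strsplit(write_bnet(fake), "\n")[[1]][2]
    expr <- parse_update_expr(sub("^z, ", "", line))
    for (r in 0:7) {
      w <- bnsketch:::row_word(r, 3)
      env <- stats::setNames(w, regs)
      evaluate <- function(e) {
        switch(e$op,
          const = e$value == 1L,
          var = env[[e$name]] == 1L,
          not = !evaluate(e$arg),
          and = evaluate(e$lhs) && evaluate(e$rhs),
          or = evaluate(e$lhs) || evaluate(e$rhs)
        )
      }
      expect_equal(as.integer(evaluate(expr)), tab[r + 1])
    }
  }
})
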
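# Coloured asynchronous transition operators against tiny hand-checked
# networks and a brute-force explicit STG on random instances.

state_set <- function(ctx, ...) {
  # conjunction of variable literals, e.g. state_set(ctx, x = 1)
  vals <- c(...)
  f <- bnsketch:::bdd_true
  for (v in names(vals)) {
    lit <- bnsketch:::bdd_v(ctx$mgr, ctx$state_pos[[v]])
    if (vals[[v]] == 0) lit <- bnsketch:::bdd_not(ctx$mgr, lit)
    f <- bnsketch:::bdd_and(ctx$mgr, f, lit)
  }
  f
}

test_that("post and pre images follow the single-flip semantics", {
  ctx <- bnsketch:::new_context(one_var_psbn("!x"))
  s0 <- state_set(ctx, x = 0)
  s1 <- state_set(ctx, x = 1)
  expect_equal(post_image(ctx, s0), s1)
  expect_equal(pre_image(ctx, s1), s0)
  expect_equal(reach_fwd(ctx, s0), bnsketch:::bdd_true)

  # x := x has no transitions anywhere
  ctx2 <- bnsketch:::new_context(one_var_psbn("x"))
  expect_equal(post_image(ctx2, bnsketch:::bdd_true), bnsketch:::bdd_false)
  expect_equal(reach_fwd(ctx2, state_set(ctx2, x = 1)), state_set(ctx2, x = 1))

  # a := b, b := a from (1, 0): either variable may fire
  g <- influence_graph(c("a", "b"), data.frame(
    source = c("b", "a"), target = c("a", "b")
  ))
  ctx3 <- bnsketch:::new_context(new_psbn(g, updates = list(a = "b", b = "a")))
  from <- state_set(ctx3, a = 1, b = 0)
  img <- post_image(ctx3, from)
  expected <- bnsketch:::bdd_or(
    ctx3$mgr, state_set(ctx3, a = 0, b = 0), state_set(ctx3, a = 1, b = 1)
  )
  expect_equal(img, expected)
})

test_that("fixed points are deadlocks and match the case analysis", {
  ctx <- bnsketch:::new_context(one_var_psbn("x"))
  expect_equal(fixed_points(ctx), bnsketch:::bdd_true)
  ctx2 <- bnsketch:::new_context(one_var_psbn("!x"))
  expect_equal(fixed_points(ctx2), bnsketch:::bdd_false)
  # PSBN x := g(x): fixed iff g(s) = s
  ctx3 <- bnsketch:::new_context(one_var_psbn("g(x)"))
  fp <- fixed_points(ctx3)
  # enumerate (state, colour) pairs: p_g[0]=0 fixes x=0; p_g[1]=1 fixes x=1
  for (s in 0:1) {
    for (p0 in 0:1) {
      for (p1 in 0:1) {
        a <- integer(ctx3$nbits)
        a[ctx3$state_pos[["x"]] + 1L] <- s
        a[bnsketch:::ctx_param_bits(ctx3) + 1L] <- c(p0, p1)
        want <- (s == 0 && p0 == 0) || (s == 1 && p1 == 1)
        expect_equal(bnsketch:::bdd_eval(ctx3$mgr, fp, a), want)
      }
    }
  }
  # structural and operational definitions agree: fixed points have an
  # empty post image, and every non-fixed (state, colour) pair has one
  expect_equal(post_image(ctx3, fp), bnsketch:::bdd_false)
  live <- bnsketch:::bdd_not(ctx3$mgr, fp)
  expect_equal(post_image(ctx3, live) == bnsketch:::bdd_false, FALSE)
})

test_that("symbolic operators equal the explicit STG on random instances", {
  for (case in 1:12) {
    gen <- random_small_sketch(case, max_bits = 6)
    psbn <- gen$sketch$psbn
    ctx <- bnsketch:::new_context(psbn)
    pn <- param_names(ctx$space)
    vars <- ctx$vars
    n <- length(vars)
    for (item in enumerate_interpretations(psbn)) {
      stg <- bnsketch:::explicit_stg(item$bn)
      # choose a pseudo-random seed set of states
      set.seed(case)
      seed_states <- which(stats::runif(stg$ns) < 0.4) - 1L
      seed_bdd <- bnsketch:::bdd_false
      for (s in seed_states) {
        seed_bdd <- bnsketch:::bdd_or(ctx$mgr, seed_bdd, state_set(
          ctx, stats::setNames(as.integer(bitwAnd(bitwShiftR(s, (n - 1):0), 1)), vars)
        ))
      }
      colour_assign <- function(extra) {
        a <- integer(ctx$nbits)
        a[bnsketch:::ctx_param_bits(ctx) + 1L] <- item$colour
        a[ctx$state_pos[vars] + 1L] <- extra
        a
      }
      in_set <- function(bdd, s) {
        bnsketch:::bdd_eval(ctx$mgr, bdd, colour_assign(
          as.integer(bitwAnd(bitwShiftR(s, (n - 1):0), 1))
        ))
      }
      seed_logical <- (seq_len(stg$ns) - 1L) %in% seed_states
      post_explicit <- logical(stg$ns)
      for (s in which(seed_logical)) {
        nxt <- stats::na.omit(stg$succ[s, ])
        post_explicit[nxt + 1L] <- TRUE
      }
      pre_explicit <- bnsketch:::stg_ex(stg, seed_logical)
      post_sym <- post_image(ctx, seed_bdd)
      pre_sym <- pre_image(ctx, seed_bdd)
      slice <- function(bdd) {
        vapply(seq_len(stg$ns) - 1L, function(s) in_set(bdd, s), TRUE)
      }
      expect_equal(slice(post_sym), post_explicit)
      expect_equal(slice(pre_sym), unname(pre_explicit))
      # reachability against per-colour BFS
      reach_explicit <- seed_logical
      repeat {
        nxt <- reach_explicit
        for (s in which(reach_explicit)) {
          nn <- stats::na.omit(stg$succ[s, ])
          nxt[nn + 1L] <- TRUE
        }
        if (all(nxt == reach_explicit)) break
        reach_explicit <- nxt
      }
      expect_equal(slice(reach_fwd(ctx, seed_bdd)), reach_explicit)
    }
  }
})
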
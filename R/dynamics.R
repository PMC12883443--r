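# Coloured fully asynchronous state-transition graph.
#
# A coloured state set is a BDD over state bits x parameter bits (x copy
# bits during HCTL checking).  A transition updates exactly one variable v
# whose update disagrees with its current value — so fixed points are
# deadlocks, and there are no self-loops.  All operators act on every
# colour simultaneously; slicing at one colour gives the explicit STG of
# the instantiated BN.

# Transition-enabled predicate for v: F_v(s, c) != s_v.
trans_enabled <- function(ctx, v) {
  key <- paste0("enabled_", v)
  cached <- ctx$cache[[key]]
  if (!is.null(cached)) return(cached)
  r <- bdd_xor(ctx$mgr, ctx$fun[[v]], bdd_v(ctx$mgr, ctx$state_pos[[v]]))
  ctx$cache[[key]] <- r
  r
}

#' Symbolic successor image under asynchronous semantics
#'
#' All pairs `(s', c)` such that some `(s, c)` in `set` has an
#' asynchronous transition `s -> s'` under colour `c` (exactly one
#' variable flips, and only when its update disagrees with its value).
#'
#' @param ctx symbolic context.
#' @param set coloured state set (BDD handle).
#' @return coloured state set.
#' @export
post_image <- function(ctx, set) {
  m <- ctx$mgr
  out <- bdd_false
  for (v in ctx$vars) {
    fired <- bdd_and(m, set, trans_enabled(ctx, v))
    out <- bdd_or(m, out, bdd_flip(m, fired, ctx$state_pos[[v]]))
  }
  out
}

#' Symbolic predecessor image under asynchronous semantics
#'
#' Exact dual of [post_image()]: all `(s, c)` with at least one
#' single-variable transition into `set`.
#'
#' @inheritParams post_image
#' @return coloured state set.
#' @export
pre_image <- function(ctx, set) {
  m <- ctx$mgr
  out <- bdd_false
  for (v in ctx$vars) {
    hit <- bdd_flip(m, set, ctx$state_pos[[v]])
    out <- bdd_or(m, out, bdd_and(m, hit, trans_enabled(ctx, v)))
  }
  out
}

#' Symbolic fixed points across all colours
#'
#' All `(s, c)` with `F_v(s, c) = s_v` for every variable: the structural
#' fixed-point predicate, which coincides with the deadlock states of the
#' self-loop-free transition graph.
#'
#' @inheritParams post_image
#' @return coloured state set.
#' @export
fixed_points <- function(ctx) {
  cached <- ctx$cache[["fixed_points"]]
  if (!is.null(cached)) return(cached)
  m <- ctx$mgr
  out <- bdd_true
  for (v in ctx$vars) {
    out <- bdd_and(m, out, bdd_iff(m, ctx$fun[[v]], bdd_v(m, ctx$state_pos[[v]])))
  }
  ctx$cache[["fixed_points"]] <- out
  out
}

#' Forward / backward reachability
#'
#' Transitive closure of [post_image()] (resp. [pre_image()]) union the
#' seed set, by chaotic iteration to the least fixed point; the lattice is
#' finite so this terminates.
#'
#' @inheritParams post_image
#' @return coloured state set.
#' @export
reach_fwd <- function(ctx, set) {
  repeat {
    nxt <- bdd_or(ctx$mgr, set, post_image(ctx, set))
    if (nxt == set) return(set)
    set <- nxt
  }
}

#' @rdname reach_fwd
#' @export
reach_bwd <- function(ctx, set) {
  repeat {
    nxt <- bdd_or(ctx$mgr, set, pre_image(ctx, set))
    if (nxt == set) return(set)
    set <- nxt
  }
}
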
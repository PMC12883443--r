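# Explicit-state reference engine: enumerate interpretations, evaluate
# HCTL by direct recursion over the explicit asynchronous STG, and run
# whole-sketch inference by filtering.  Deliberately independent of the
# BDD path — this is the oracle the symbolic engine is validated against.

#' Enumerate all interpretations of a PSBN
#'
#' Walks every parameter valuation (in parameter binary order) and
#' instantiates the concrete network.
#'
#' @param psbn a [new_psbn()] object.
#' @param max_bits refuse parameter spaces beyond `2^max_bits`
#'   interpretations (explicit enumeration only makes sense desk-scale).
#' @return list of `list(colour, bn)` pairs, `2^total_bits` of them.
#' @export
enumerate_interpretations <- function(psbn, max_bits = 24L) {
  ctx <- new_context(psbn)
  b <- ctx$space$total_bits
  if (b > max_bits) {
    stop(sprintf("parameter space has %d bits, above the enumeration guard (%d)", b, max_bits))
  }
  pn <- param_names(ctx$space)
  lapply(seq_len(2^b) - 1, function(r) {
    colour <- stats::setNames(as.integer(bitwAnd(bitwShiftR(r, (b - 1):0), 1)), pn)
    if (b == 0) colour <- stats::setNames(integer(0), character(0))
    list(colour = colour, bn = instantiate_in_ctx(ctx, colour))
  })
}

## ---- explicit STG ---------------------------------------------------------

# Explicit asynchronous state-transition graph of a concrete BN.
# States are indexed 0..2^n-1, first variable (sorted) most significant.
explicit_stg <- function(bn) {
  n <- length(bn$variables)
  if (n > 12L) stop("explicit state space guard: at most 12 variables")
  ns <- 2L^n
  states <- matrix(0L, nrow = ns, ncol = n, dimnames = list(NULL, bn$variables))
  for (j in seq_len(n)) {
    states[, j] <- bitwAnd((seq_len(ns) - 1L) %/% (2L^(n - j)), 1L)
  }
  next_val <- matrix(0L, nrow = ns, ncol = n, dimnames = list(NULL, bn$variables))
  for (j in seq_len(n)) {
    v <- bn$variables[j]
    f <- bn$functions[[v]]
    k <- length(f$regulators)
    idx <- if (k == 0L) rep(0L, ns) else {
      cols <- match(f$regulators, bn$variables)
      as.integer(states[, cols, drop = FALSE] %*% 2L^((k - 1L):0L))
    }
    next_val[, j] <- f$table[idx + 1L]
  }
  succ <- matrix(NA_integer_, nrow = ns, ncol = n)
  for (j in seq_len(n)) {
    enabled <- next_val[, j] != states[, j]
    flip <- (seq_len(ns) - 1L) + ifelse(states[, j] == 1L, -1L, 1L) * 2L^(n - j)
    succ[enabled, j] <- flip[enabled]
  }
  list(n = n, ns = ns, vars = bn$variables, states = states, next_val = next_val, succ = succ)
}

stg_ex <- function(stg, set) {
  # states with at least one successor in `set`
  hit <- matrix(FALSE, nrow = stg$ns, ncol = stg$n)
  for (j in seq_len(stg$n)) {
    ok <- !is.na(stg$succ[, j])
    hit[ok, j] <- set[stg$succ[ok, j] + 1L]
  }
  rowSums(hit) > 0
}

stg_fixed <- function(stg) rowSums(stg$next_val != stg$states) == 0

#' Explicit HCTL evaluation over one concrete network
#'
#' Direct recursive semantics over the explicit asynchronous STG, with
#' binder/jump/quantifier handled through an environment mapping state
#' variables to concrete states.  The reference implementation for
#' [hctl_check()].
#'
#' @param formula HCTL AST or formula string.
#' @param bn a `concrete_bn` with at most 12 variables.
#' @param env named integer vector: bound state variables (0-based state
#'   indices); usually empty for closed formulas.
#' @return logical vector over the `2^n` states.
#' @export
explicit_check_hctl <- function(formula, bn, env = integer(0)) {
  if (is.character(formula)) formula <- parse_hctl(formula)
  explicit_eval_indexed(hctl_index_nodes(formula), explicit_stg(bn), env)
}

# Core evaluator over a prebuilt STG and a node-indexed formula, so batch
# callers (brute_force_inference) pay the preprocessing once.
explicit_eval_indexed <- function(info, stg, env = integer(0)) {
  memo <- new.env(parent = emptyenv())
  ev <- function(a, env) {
    free <- info$free[[as.character(a$nid)]]
    key <- paste(a$nid, paste(env[free], collapse = ","), sep = "|")
    hitm <- memo[[key]]
    if (!is.null(hitm)) return(hitm)
    res <- switch(a$op,
      const = rep(a$value == 1L, stg$ns),
      prop = {
        j <- match(a$name, stg$vars)
        if (is.na(j)) stop(sprintf("unknown variable '%s'", a$name))
        stg$states[, j] == 1L
      },
      svar = (seq_len(stg$ns) - 1L) == env[[a$name]],
      fp = stg_fixed(stg),
      obs = {
        keep <- rep(TRUE, stg$ns)
        for (v in names(a$values)) {
          j <- match(v, stg$vars)
          keep <- keep & (stg$states[, j] == a$values[[v]])
        }
        keep
      },
      not = !ev(a$arg, env),
      and = ev(a$lhs, env) & ev(a$rhs, env),
      or = ev(a$lhs, env) | ev(a$rhs, env),
      xor = xor(ev(a$lhs, env), ev(a$rhs, env)),
      imp = !ev(a$lhs, env) | ev(a$rhs, env),
      iff = ev(a$lhs, env) == ev(a$rhs, env),
      EX = stg_ex(stg, ev(a$arg, env)),
      AX = !stg_ex(stg, !ev(a$arg, env)),
      EF = {
        z <- ev(a$arg, env)
        repeat {
          nz <- z | stg_ex(stg, z)
          if (all(nz == z)) break
          z <- nz
        }
        z
      },
      AG = {
        z <- !ev(a$arg, env)
        repeat {
          nz <- z | stg_ex(stg, z)
          if (all(nz == z)) break
          z <- nz
        }
        !z
      },
      EG = {
        z <- ev(a$arg, env)
        repeat {
          nz <- z & stg_ex(stg, z)
          if (all(nz == z)) break
          z <- nz
        }
        z
      },
      AF = {
        z <- !ev(a$arg, env)
        repeat {
          nz <- z & stg_ex(stg, z)
          if (all(nz == z)) break
          z <- nz
        }
        !z
      },
      EU = {
        phi <- ev(a$lhs, env)
        z <- ev(a$rhs, env)
        repeat {
          nz <- z | (phi & stg_ex(stg, z))
          if (all(nz == z)) break
          z <- nz
        }
        z
      },
      AU = {
        phi <- ev(a$lhs, env)
        psi <- ev(a$rhs, env)
        z1 <- !psi & !phi
        repeat {
          nz <- z1 | (!psi & stg_ex(stg, z1))
          if (all(nz == z1)) break
          z1 <- nz
        }
        z2 <- !psi
        repeat {
          nz <- z2 & stg_ex(stg, z2)
          if (all(nz == z2)) break
          z2 <- nz
        }
        !(z1 | z2)
      },
      bind = {
        out <- logical(stg$ns)
        for (s in seq_len(stg$ns) - 1L) {
          e2 <- env
          e2[a$var] <- s
          out[s + 1L] <- ev(a$body, e2)[s + 1L]
        }
        out
      },
      jump = rep(ev(a$body, env)[env[[a$var]] + 1L], stg$ns),
      exists_state = {
        out <- logical(stg$ns)
        for (s in seq_len(stg$ns) - 1L) {
          e2 <- env
          e2[a$var] <- s
          out <- out | ev(a$body, e2)
        }
        out
      },
      stop(sprintf("unknown HCTL operator '%s'", a$op))
    )
    memo[[key]] <- res
    res
  }
  ev(info$ast, env)
}

# Assign node ids and compute free state variables per node, enabling
# memoization keyed on (node, relevant environment slice).
hctl_index_nodes <- function(ast) {
  counter <- 0L
  free <- list()
  walk <- function(a) {
    counter <<- counter + 1L
    a$nid <- counter
    fr <- switch(a$op,
      svar = a$name,
      jump = {
        a$body <- walk(a$body)
        unique(c(a$var, free[[as.character(a$body$nid)]]))
      },
      bind = ,
      exists_state = {
        a$body <- walk(a$body)
        setdiff(free[[as.character(a$body$nid)]], a$var)
      },
      not = ,
      EX = ,
      AX = ,
      EF = ,
      AF = ,
      EG = ,
      AG = {
        a$arg <- walk(a$arg)
        free[[as.character(a$arg$nid)]]
      },
      const = ,
      prop = ,
      fp = ,
      obs = character(0),
      {
        a$lhs <- walk(a$lhs)
        a$rhs <- walk(a$rhs)
        unique(c(
          free[[as.character(a$lhs$nid)]],
          free[[as.character(a$rhs$nid)]]
        ))
      }
    )
    free[[as.character(a$nid)]] <<- fr
    a
  }
  ast <- walk(ast)
  list(ast = ast, free = free)
}

## ---- explicit static checks ------------------------------------------------

# Does regulation (u, v) have an effect in this concrete network?
explicit_regulation_essential <- function(bn, u, v) {
  f <- bn$functions[[v]]
  pos <- match(u, f$regulators)
  if (is.na(pos)) return(FALSE)
  k <- length(f$regulators)
  weight <- 2L^(k - pos)
  rows0 <- (seq_len(2L^k) - 1L)
  rows0 <- rows0[bitwAnd(rows0 %/% weight, 1L) == 0L]
  any(f$table[rows0 + 1L] != f$table[rows0 + weight + 1L])
}

explicit_regulation_monotone <- function(bn, u, v, direction) {
  f <- bn$functions[[v]]
  pos <- match(u, f$regulators)
  if (is.na(pos)) return(TRUE) # constant in u: monotone both ways
  k <- length(f$regulators)
  weight <- 2L^(k - pos)
  rows0 <- (seq_len(2L^k) - 1L)
  rows0 <- rows0[bitwAnd(rows0 %/% weight, 1L) == 0L]
  lo <- f$table[rows0 + 1L]
  hi <- f$table[rows0 + weight + 1L]
  if (direction == "positive") all(lo <= hi) else all(lo >= hi)
}

# Raw symbol table (0/1 vector in row order) from a colour.
colour_symbol_table <- function(space, colour, symbol) {
  i <- match(symbol, space$symbols$name)
  unname(colour[space$symbols$offset[i] + seq_len(space$symbols$bits[i])])
}

explicit_symbol_property <- function(space, colour, symbol, arg_index, kind,
                                     direction = "positive") {
  tab <- colour_symbol_table(space, colour, symbol)
  i <- match(symbol, space$symbols$name)
  k <- space$symbols$arity[i]
  weight <- 2L^(k - 1L - arg_index)
  rows0 <- (seq_len(2L^k) - 1L)
  rows0 <- rows0[bitwAnd(rows0 %/% weight, 1L) == 0L]
  lo <- tab[rows0 + 1L]
  hi <- tab[rows0 + weight + 1L]
  switch(kind,
    essential = any(lo != hi),
    monotone = if (direction == "positive") all(lo <= hi) else all(lo >= hi)
  )
}

explicit_fol <- function(ast, space, colour) {
  rec <- function(a, env) {
    switch(a$op,
      forall = rec(a$body, bind_env(env, a$var, 0L)) &&
        rec(a$body, bind_env(env, a$var, 1L)),
      exists = rec(a$body, bind_env(env, a$var, 0L)) ||
        rec(a$body, bind_env(env, a$var, 1L)),
      const = a$value == 1L,
      var = env[[a$name]] == 1L,
      not = !rec(a$arg, env),
      app = {
        args <- vapply(a$args, function(x) as.integer(rec(x, env)), 0L)
        tab <- colour_symbol_table(space, colour, a$fn)
        k <- length(args)
        idx <- if (k == 0L) 0L else sum(args * 2L^((k - 1L):0L))
        tab[idx + 1L] == 1L
      },
      and = rec(a$lhs, env) && rec(a$rhs, env),
      or = rec(a$lhs, env) || rec(a$rhs, env),
      xor = xor(rec(a$lhs, env), rec(a$rhs, env)),
      imp = !rec(a$lhs, env) || rec(a$rhs, env),
      iff = rec(a$lhs, env) == rec(a$rhs, env)
    )
  }
  bind_env <- function(env, v, b) {
    env[v] <- b
    env
  }
  rec(ast, stats::setNames(integer(0), character(0)))
}

## ---- explicit whole-sketch inference ---------------------------------------

#' Brute-force sketch inference (reference semantics)
#'
#' Enumerates every interpretation and keeps those whose instantiated
#' network passes every static property (checked on the truth tables) and
#' every dynamic property (explicit HCTL, universal over states).  The
#' independent oracle for [run_inference()].
#'
#' @param sketch a [new_sketch()] object.
#' @param max_bits enumeration guard, see [enumerate_interpretations()].
#' @return list with `count` and `colours` (list of named 0/1 vectors).
#' @export
brute_force_inference <- function(sketch, max_bits = 24L) {
  psbn <- sketch$psbn
  space <- build_parameter_space(psbn)
  regs <- psbn$graph$regulations
  # Attractor-count properties are checked by direct bottom-SCC analysis
  # (an algorithm fully disjoint from the HCTL template they expand to);
  # everything else goes through explicit HCTL evaluation.
  attr_bounds <- list()
  formula_infos <- list()
  for (p in sketch$dynamic_properties) {
    if (p$kind == "attractor_count") {
      attr_bounds[[length(attr_bounds) + 1L]] <- c(p$min, p$max)
    } else {
      formula_infos[[length(formula_infos) + 1L]] <-
        hctl_index_nodes(build_template(p, sketch$datasets))
    }
  }
  fol_asts <- list()
  for (p in sketch$static_properties) {
    if (p$kind == "fol") fol_asts[[p$id]] <- parse_fol(p$text)
  }
  keep <- list()
  for (item in enumerate_interpretations(psbn, max_bits)) {
    bn <- item$bn
    colour <- item$colour
    ok <- TRUE
    for (i in seq_len(nrow(regs))) {
      if (regs$sign[i] != "unknown" &&
        !explicit_regulation_monotone(bn, regs$source[i], regs$target[i], regs$sign[i])) {
        ok <- FALSE
        break
      }
      if (regs$essential[i] == "true" &&
        !explicit_regulation_essential(bn, regs$source[i], regs$target[i])) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      for (p in sketch$static_properties) {
        pass <- switch(p$kind,
          regulation_essential = explicit_regulation_essential(bn, p$source, p$target),
          regulation_monotone = explicit_regulation_monotone(bn, p$source, p$target, p$direction),
          symbol_essential = explicit_symbol_property(space, colour, p$symbol, p$arg_index, "essential"),
          symbol_monotone = explicit_symbol_property(space, colour, p$symbol, p$arg_index, "monotone", p$direction),
          fol = explicit_fol(fol_asts[[p$id]], space, colour)
        )
        if (!pass) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok && length(attr_bounds)) {
      n_attr <- length(explicit_attractors(bn))
      for (b in attr_bounds) {
        if (n_attr < b[1] || n_attr > b[2]) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok && length(formula_infos)) {
      stg <- explicit_stg(bn)
      for (info in formula_infos) {
        if (!all(explicit_eval_indexed(info, stg))) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) keep[[length(keep) + 1L]] <- colour
  }
  list(count = length(keep), colours = keep)
}
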
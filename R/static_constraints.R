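# Static (update-function) properties compiled to symbolic colour sets.
#
# Regulation-level properties are defined on the *instantiated* update
# function F_v of the target — the only definition that is well formed for
# compound expressions.  Symbol-level properties constrain the raw truth
# table of one symbol.  Free-form properties are closed first-order
# formulas over Booleans with quantifiers expanded over the finite domain.

# Colours under which regulation (u, v) is essential:
# exists state s with F_v(s[u:=0], c) != F_v(s[u:=1], c).
#' Essentiality of a regulation as a colour set
#'
#' @param ctx symbolic context.
#' @param u,v source and target variable of a declared regulation.
#' @return BDD handle over parameter bits: the colours in which flipping
#'   `u` changes the update of `v` at some state.
#' @export
essentiality_of_regulation <- function(ctx, u, v) {
  check_regulation(ctx, u, v)
  m <- ctx$mgr
  pos <- ctx$state_pos[[u]]
  g0 <- bdd_restrict(m, ctx$fun[[v]], pos, 0L)
  g1 <- bdd_restrict(m, ctx$fun[[v]], pos, 1L)
  bdd_exists(m, bdd_xor(m, g0, g1), ctx_state_bits(ctx))
}

#' Monotonicity of a regulation as a colour set
#'
#' Positive: for all states, `F_v(s[u:=0]) => F_v(s[u:=1])`; negative is
#' the reversed implication.
#'
#' @inheritParams essentiality_of_regulation
#' @param direction `"positive"` or `"negative"`.
#' @return BDD handle over parameter bits.
#' @export
monotonicity_of_regulation <- function(ctx, u, v, direction) {
  check_regulation(ctx, u, v)
  stopifnot(direction %in% c("positive", "negative"))
  m <- ctx$mgr
  pos <- ctx$state_pos[[u]]
  g0 <- bdd_restrict(m, ctx$fun[[v]], pos, 0L)
  g1 <- bdd_restrict(m, ctx$fun[[v]], pos, 1L)
  body <- if (direction == "positive") bdd_imp(m, g0, g1) else bdd_imp(m, g1, g0)
  bdd_forall(m, body, ctx_state_bits(ctx))
}

check_regulation <- function(ctx, u, v) {
  regs <- ctx$psbn$graph$regulations
  if (!any(regs$source == u & regs$target == v)) {
    stop(sprintf("regulation (%s, %s) is not declared", u, v))
  }
}

#' Symbol-level essentiality / monotonicity as a colour set
#'
#' Constrains the raw truth table of one function symbol in one argument
#' position, quantifying over all values of the other arguments.
#'
#' @param ctx symbolic context.
#' @param symbol function symbol name.
#' @param arg_index 0-based argument position.
#' @param kind `"essential"` or `"monotone"`.
#' @param direction for `kind = "monotone"`: `"positive"` or `"negative"`.
#' @return BDD handle over parameter bits.
#' @export
compile_symbol_property <- function(ctx, symbol, arg_index, kind,
                                    direction = "positive") {
  m <- ctx$mgr
  i <- match(symbol, ctx$space$symbols$name)
  if (is.na(i)) stop(sprintf("unknown function symbol '%s'", symbol))
  k <- ctx$space$symbols$arity[i]
  if (arg_index < 0 || arg_index >= k) {
    stop(sprintf("argument index %d out of range for '%s' (arity %d)", arg_index, symbol, k))
  }
  weight <- 2L^(k - 1L - arg_index) # first argument is the most significant bit
  rows0 <- (seq_len(2L^k) - 1L)
  rows0 <- rows0[bitwAnd(rows0 %/% weight, 1L) == 0L]
  pieces <- lapply(rows0, function(r0) {
    p0 <- bdd_v(m, param_pos(ctx, symbol, r0))
    p1 <- bdd_v(m, param_pos(ctx, symbol, r0 + weight))
    switch(kind,
      essential = bdd_xor(m, p0, p1),
      monotone = if (direction == "positive") {
        bdd_imp(m, p0, p1)
      } else {
        bdd_imp(m, p1, p0)
      },
      stop(sprintf("unknown symbol property kind '%s'", kind))
    )
  })
  if (kind == "essential") bdd_or_all(m, pieces) else bdd_and_all(m, pieces)
}

## ---- first-order formulas over Booleans ------------------------------------

# AST nodes: quantifiers list(op = "forall"/"exists", var, body) over the
# shared propositional core of expr.R, where `var` references denote
# bound Boolean variables.

#' Parse a first-order property over Booleans
#'
#' Grammar (ASCII): `forall a: <body>` and `exists a: <body>` bind a
#' Boolean scalar; bodies use `!`, `&`, `|`, `^`, `=>`, `<=>`, constants
#' `0`/`1`/`true`/`false` and applications of function symbols to terms
#' (terms may nest applications).  The formula must be closed, and may
#' mention only bound variables and function symbols — never network
#' state variables (state-dependent constraints are dynamic properties).
#'
#' @param text formula string, e.g. `"forall a: forall b: g(a,b) <=> g(b,a)"`.
#' @return a FOL AST.
#' @export
parse_fol <- function(text) {
  cur <- new_cursor(tokenize(text))
  ast <- fol_parse_quant(cur)
  t <- cur_peek(cur)
  if (t$type != "eof") {
    stop(sprintf("parse error at position %d: unexpected '%s'", t$pos, t$text))
  }
  fol_check_scope(ast, character(0))
  ast
}

fol_parse_quant <- function(cur) {
  if (cur_at(cur, "ident", "forall") || cur_at(cur, "ident", "exists")) {
    q <- cur_next(cur)$text
    v <- cur_expect(cur, "ident")$text
    cur_expect(cur, "op", ":")
    return(list(op = q, var = v, body = fol_parse_quant(cur)))
  }
  fol_iff(cur)
}

fol_iff <- function(cur) {
  lhs <- fol_imp(cur)
  while (cur_at(cur, "op", "<=>")) {
    cur_next(cur)
    lhs <- ex_bin("iff", lhs, fol_imp(cur))
  }
  lhs
}
fol_imp <- function(cur) {
  lhs <- fol_xor(cur)
  if (cur_at(cur, "op", "=>")) {
    cur_next(cur)
    return(ex_bin("imp", lhs, fol_imp(cur)))
  }
  lhs
}
fol_xor <- function(cur) {
  lhs <- fol_or(cur)
  while (cur_at(cur, "op", "^")) {
    cur_next(cur)
    lhs <- ex_bin("xor", lhs, fol_or(cur))
  }
  lhs
}
fol_or <- function(cur) {
  lhs <- fol_and(cur)
  while (cur_at(cur, "op", "|")) {
    cur_next(cur)
    lhs <- ex_bin("or", lhs, fol_and(cur))
  }
  lhs
}
fol_and <- function(cur) {
  lhs <- fol_unary(cur)
  while (cur_at(cur, "op", "&")) {
    cur_next(cur)
    lhs <- ex_bin("and", lhs, fol_unary(cur))
  }
  lhs
}
fol_unary <- function(cur) {
  if (cur_at(cur, "op", "!") || cur_at(cur, "op", "~")) {
    cur_next(cur)
    return(ex_not(fol_unary(cur)))
  }
  if (cur_at(cur, "ident", "forall") || cur_at(cur, "ident", "exists")) {
    return(fol_parse_quant(cur))
  }
  fol_atom(cur)
}
fol_atom <- function(cur) {
  t <- cur_peek(cur)
  if (t$type == "num") {
    cur_next(cur)
    if (!t$text %in% c("0", "1")) {
      stop(sprintf("parse error at position %d: constants must be 0 or 1", t$pos))
    }
    return(ex_const(as.integer(t$text)))
  }
  if (t$type == "ident") {
    cur_next(cur)
    if (t$text %in% c("true", "false")) {
      return(ex_const(as.integer(t$text == "true")))
    }
    if (cur_at(cur, "op", "(")) {
      cur_next(cur)
      args <- list()
      if (!cur_at(cur, "op", ")")) {
        repeat {
          args[[length(args) + 1L]] <- fol_iff(cur)
          if (!cur_at(cur, "op", ",")) break
          cur_next(cur)
        }
      }
      cur_expect(cur, "op", ")")
      return(ex_app(t$text, args))
    }
    return(ex_var(t$text))
  }
  if (cur_at(cur, "op", "(")) {
    cur_next(cur)
    e <- fol_parse_quant(cur)
    cur_expect(cur, "op", ")")
    return(e)
  }
  stop(sprintf("parse error at position %d: unexpected '%s'", t$pos, t$text))
}

fol_check_scope <- function(ast, bound) {
  switch(ast$op,
    forall = ,
    exists = fol_check_scope(ast$body, c(bound, ast$var)),
    const = invisible(NULL),
    var = {
      if (!ast$name %in% bound) {
        stop(sprintf("unbound variable '%s' in first-order formula", ast$name))
      }
    },
    not = fol_check_scope(ast$arg, bound),
    app = for (a in ast$args) fol_check_scope(a, bound),
    {
      fol_check_scope(ast$lhs, bound)
      fol_check_scope(ast$rhs, bound)
    }
  )
  invisible(NULL)
}

# Used by validate_sketch: symbol references must resolve with the right
# arity.
fol_check_refs <- function(ast, symbols, vars) {
  walk <- function(a) {
    switch(a$op,
      forall = ,
      exists = walk(a$body),
      const = ,
      var = invisible(NULL),
      not = walk(a$arg),
      app = {
        i <- match(a$fn, symbols$name)
        if (is.na(i)) {
          stop(sprintf("unknown function symbol '%s' in first-order formula", a$fn))
        }
        if (length(a$args) != symbols$arity[i]) {
          stop(sprintf(
            "symbol '%s' applied to %d arguments but has arity %d",
            a$fn, length(a$args), symbols$arity[i]
          ))
        }
        for (x in a$args) walk(x)
      },
      {
        walk(a$lhs)
        walk(a$rhs)
      }
    )
    invisible(NULL)
  }
  walk(ast)
  invisible(NULL)
}

#' Compile a first-order property to a colour set
#'
#' Expands quantifiers over the two-element Boolean domain and evaluates
#' applications through the truth-table parameters, yielding the set of
#' colours under which the closed formula holds.
#'
#' @param ast a [parse_fol()] AST.
#' @param ctx symbolic context.
#' @return BDD handle over parameter bits.
#' @export
compile_fol <- function(ast, ctx) {
  m <- ctx$mgr
  bind <- function(env, v, b) {
    env[v] <- b # overwrite: inner quantifiers shadow outer ones
    env
  }
  rec <- function(a, env) {
    switch(a$op,
      forall = bdd_and(
        m, rec(a$body, bind(env, a$var, 0L)),
        rec(a$body, bind(env, a$var, 1L))
      ),
      exists = bdd_or(
        m, rec(a$body, bind(env, a$var, 0L)),
        rec(a$body, bind(env, a$var, 1L))
      ),
      const = if (a$value == 1L) bdd_true else bdd_false,
      var = {
        if (!a$name %in% names(env)) {
          stop(sprintf("unbound variable '%s' in first-order formula", a$name))
        }
        if (env[[a$name]] == 1L) bdd_true else bdd_false
      },
      not = bdd_not(m, rec(a$arg, env)),
      app = compile_app_bdd(ctx, a$fn, lapply(a$args, rec, env = env)),
      bdd_apply(m, a$op, rec(a$lhs, env), rec(a$rhs, env))
    )
  }
  rec(ast, stats::setNames(integer(0), character(0)))
}

# Dispatch one static property object to its colour set.
compile_static_property <- function(ctx, p) {
  switch(p$kind,
    regulation_essential = essentiality_of_regulation(ctx, p$source, p$target),
    regulation_monotone = monotonicity_of_regulation(ctx, p$source, p$target, p$direction),
    symbol_essential = compile_symbol_property(ctx, p$symbol, p$arg_index, "essential"),
    symbol_monotone = compile_symbol_property(ctx, p$symbol, p$arg_index, "monotone", p$direction),
    fol = compile_fol(parse_fol(p$text), ctx),
    stop(sprintf("unknown static property kind '%s'", p$kind))
  )
}
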
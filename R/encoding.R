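# Parameter-space construction and symbolic instantiation.
#
# Every function symbol g of arity k contributes one Boolean parameter per
# truth-table row, 2^k in total; a full assignment of all parameters (a
# "colour") is one interpretation and yields one concrete BN.  Update
# expressions compile to BDDs over (state bits, parameter bits) by turning
# each application g(e1,...,ek) into the row multiplexer
#   OR_w [ p_{g,w} & AND_i (ei <=> w_i) ],
# realized as a Shannon cascade over the argument functions.
#
# Global BDD variable order: for each network variable (sorted by name)
# its state bit followed by its bound-state-copy bits (one per HCTL state
# variable slot), then all parameter bits (symbols sorted by name, rows in
# binary order, first argument most significant).  Keeping each state bit
# adjacent to its copies makes state<->copy renaming order-preserving.

#' Build the parameter space of a PSBN
#'
#' @param psbn a [new_psbn()] object.
#' @param arity_cap reject symbols whose truth table would exceed
#'   `2^arity_cap` rows (such tables signal an intractable encoding).
#' @return a `parameter_space`: symbol table with bit offsets plus
#'   `total_bits`.
#' @examples
#' g <- influence_graph(c("A", "B"), data.frame(source = "A", target = "B"))
#' ps <- build_parameter_space(new_psbn(g))
#' ps$total_bits # g_A has arity 0 (1 bit), g_B arity 1 (2 bits)
#' @export
build_parameter_space <- function(psbn, arity_cap = 16L) {
  syms <- psbn$symbols[order(psbn$symbols$name), , drop = FALSE]
  if (nrow(syms) && any(syms$arity > arity_cap)) {
    bad <- syms$name[syms$arity > arity_cap][1]
    stop(sprintf(
      "symbol '%s' has arity above the cap (%d); its truth table is intractably large",
      bad, arity_cap
    ))
  }
  bits <- if (nrow(syms)) 2L^syms$arity else integer(0)
  offset <- if (nrow(syms)) cumsum(c(0L, bits))[seq_len(nrow(syms))] else integer(0)
  symbols <- data.frame(
    name = syms$name, arity = syms$arity, bits = bits, offset = offset,
    stringsAsFactors = FALSE
  )
  rownames(symbols) <- NULL
  structure(
    list(symbols = symbols, total_bits = sum(bits)),
    class = "parameter_space"
  )
}

# Row bit-word of row index r for arity k: first argument most significant.
row_word <- function(r, k) {
  if (k == 0L) return(integer(0))
  as.integer(bitwAnd(bitwShiftR(r, (k - 1L):0L), 1L))
}

#' Parameter names of a parameter space
#'
#' One name per truth-table row, `"g[w]"` with `w` the input word (first
#' argument leftmost); in parameter-space order.
#'
#' @param space a [build_parameter_space()] object.
#' @return character vector of length `space$total_bits`.
#' @export
param_names <- function(space) {
  out <- character(space$total_bits)
  for (i in seq_len(nrow(space$symbols))) {
    k <- space$symbols$arity[i]
    for (r in seq_len(2L^k) - 1L) {
      out[space$symbols$offset[i] + r + 1L] <-
        sprintf("%s[%s]", space$symbols$name[i], paste(row_word(r, k), collapse = ""))
    }
  }
  out
}

## ---- symbolic context ------------------------------------------------------

# The context owns the BDD manager plus the bit layout and the compiled
# update functions F_v(state, params).  Environments give cheap caching.
new_context <- function(psbn, n_state_vars = 0L, arity_cap = 16L) {
  space <- build_parameter_space(psbn, arity_cap)
  vars <- sort(psbn$graph$variables)
  n <- length(vars)
  m <- as.integer(n_state_vars)
  ctx <- new.env(parent = emptyenv())
  ctx$psbn <- psbn
  ctx$space <- space
  ctx$vars <- vars
  ctx$n_copies <- m
  ctx$param_base <- n * (1L + m)
  ctx$nbits <- ctx$param_base + space$total_bits
  ctx$mgr <- bdd_mgr_new(ctx$nbits)
  ctx$state_pos <- stats::setNames((seq_len(n) - 1L) * (1L + m), vars)
  ctx$fun <- list()
  for (v in vars) {
    ctx$fun[[v]] <- compile_expr_bdd(ctx, psbn$update[[v]])
  }
  ctx$cache <- new.env(parent = emptyenv())
  class(ctx) <- "bn_context"
  ctx
}

#' @export
print.bn_context <- function(x, ...) {
  cat(sprintf(
    "Symbolic context: %d variables, %d parameter bits, %d HCTL state-variable slots\n",
    length(x$vars), x$space$total_bits, x$n_copies
  ))
  invisible(x)
}

ctx_state_bits <- function(ctx) unname(ctx$state_pos)
ctx_copy_bits <- function(ctx, slot) unname(ctx$state_pos) + slot
ctx_param_bits <- function(ctx) {
  if (ctx$space$total_bits == 0L) integer(0) else ctx$param_base + seq_len(ctx$space$total_bits) - 1L
}

param_pos <- function(ctx, symbol, row) {
  i <- match(symbol, ctx$space$symbols$name)
  if (is.na(i)) stop(sprintf("unknown function symbol '%s'", symbol))
  ctx$param_base + ctx$space$symbols$offset[i] + row
}

# Compile an update-expression AST to a BDD over state + parameter bits.
compile_expr_bdd <- function(ctx, e) {
  m <- ctx$mgr
  switch(e$op,
    const = if (e$value == 1L) bdd_true else bdd_false,
    var = {
      pos <- ctx$state_pos[[e$name]]
      if (is.null(pos)) stop(sprintf("unknown variable '%s' in expression", e$name))
      bdd_v(m, pos)
    },
    not = bdd_not(m, compile_expr_bdd(ctx, e$arg)),
    app = compile_app_bdd(ctx, e$fn, lapply(e$args, function(a) compile_expr_bdd(ctx, a))),
    {
      l <- compile_expr_bdd(ctx, e$lhs)
      r <- compile_expr_bdd(ctx, e$rhs)
      bdd_apply(m, e$op, l, r)
    }
  )
}

# Row multiplexer for an application of symbol `fn` to already-compiled
# argument functions: a Shannon cascade selecting the truth-table
# parameter indexed by the argument values.
compile_app_bdd <- function(ctx, fn, arg_handles) {
  m <- ctx$mgr
  i <- match(fn, ctx$space$symbols$name)
  if (is.na(i)) stop(sprintf("unknown function symbol '%s'", fn))
  k <- ctx$space$symbols$arity[i]
  if (length(arg_handles) != k) {
    stop(sprintf("symbol '%s' applied with wrong arity", fn))
  }
  mux <- function(depth, row) {
    if (depth == k) {
      return(bdd_v(m, param_pos(ctx, fn, row)))
    }
    bdd_ite(
      m, arg_handles[[depth + 1L]],
      mux(depth + 1L, row * 2L + 1L),
      mux(depth + 1L, row * 2L)
    )
  }
  mux(0L, 0L)
}

#' Symbolic update function of a variable
#'
#' Returns the compiled `F_v(state, parameters)` as a symbolic function
#' handle within the context; fixed (symbol-free) expressions are
#' parameter independent.
#'
#' @param ctx a symbolic context created by `new_context()` (internal) or
#'   obtained from [run_inference()].
#' @param v variable name.
#' @return a BDD handle (integer) valid in `ctx$mgr`.
#' @keywords internal
symbolic_update <- function(ctx, v) {
  f <- ctx$fun[[v]]
  if (is.null(f)) stop(sprintf("unknown variable '%s'", v))
  f
}

## ---- colours and instantiation --------------------------------------------

# Normalize a colour to a named 0/1 integer vector in parameter order.
as_colour <- function(space, colour) {
  pn <- param_names(space)
  if (is.null(names(colour))) {
    if (length(colour) != length(pn)) stop("colour length must equal total parameter bits")
    colour <- stats::setNames(as.integer(colour), pn)
  } else {
    if (!setequal(names(colour), pn)) stop("colour names must match the parameter space")
    colour <- stats::setNames(as.integer(colour[pn]), pn)
  }
  if (length(colour) && !all(colour %in% c(0L, 1L))) stop("colour values must be 0/1")
  colour
}

#' Instantiate a concrete Boolean network from a colour
#'
#' Substitutes one full parameter valuation (an interpretation of every
#' function symbol) into the PSBN, producing a standard BN given as one
#' truth table per variable over its regulators (sorted by name, first
#' regulator most significant row bit).
#'
#' @param psbn a [new_psbn()] object.
#' @param colour named 0/1 vector over [param_names()] (or unnamed, in
#'   parameter order).
#' @return a `concrete_bn` object.
#' @export
instantiate_bn <- function(psbn, colour) {
  ctx <- new_context(psbn)
  instantiate_in_ctx(ctx, colour)
}

instantiate_in_ctx <- function(ctx, colour) {
  colour <- as_colour(ctx$space, colour)
  m <- ctx$mgr
  pbits <- ctx_param_bits(ctx)
  functions <- list()
  for (v in ctx$vars) {
    f <- ctx$fun[[v]]
    for (j in seq_along(pbits)) f <- bdd_restrict(m, f, pbits[j], colour[[j]])
    regs <- regulators_of(ctx$psbn$graph, v)
    k <- length(regs)
    rows <- 2L^k
    assign_mat <- matrix(0L, nrow = rows, ncol = ctx$nbits)
    for (r in seq_len(rows) - 1L) {
      w <- row_word(r, k)
      for (j in seq_len(k)) assign_mat[r + 1L, ctx$state_pos[[regs[j]]] + 1L] <- w[j]
    }
    tab <- as.integer(bdd_eval_many(m, f, assign_mat))
    functions[[v]] <- list(regulators = regs, table = tab)
  }
  structure(
    list(variables = ctx$vars, functions = functions, colour = colour),
    class = "concrete_bn"
  )
}

#' @export
print.concrete_bn <- function(x, ...) {
  cat(sprintf("Boolean network with %d variables\n", length(x$variables)))
  for (v in x$variables) {
    f <- x$functions[[v]]
    cat(sprintf(
      "  %s(%s): %s\n", v, paste(f$regulators, collapse = ","),
      paste(f$table, collapse = "")
    ))
  }
  invisible(x)
}

# Apply the update function of `v` in a concrete BN to a full state
# (named 0/1 vector).
bn_apply <- function(bn, v, state) {
  f <- bn$functions[[v]]
  k <- length(f$regulators)
  if (k == 0L) return(f$table[1L])
  idx <- sum(state[f$regulators] * 2L^((k - 1L):0L))
  f$table[idx + 1L]
}
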
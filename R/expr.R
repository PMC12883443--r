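# Boolean expression ASTs and the shared tokenizer.
#
# Update expressions, first-order static properties and HCTL formulas all
# share the propositional core: constants 0/1, negation `!` (HCTL also
# accepts `~`), `&`, `|`, `^` (xor), `=>` (right associative), `<=>`, and
# applications `g(e1, ..., ek)` of declared function symbols.
# Precedence, loosest to tightest: <=>, =>, ^, |, &, negation.

IDENT_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

ex_const <- function(value) list(op = "const", value = as.integer(value))
ex_var <- function(name) list(op = "var", name = name)
ex_not <- function(arg) list(op = "not", arg = arg)
ex_bin <- function(op, lhs, rhs) list(op = op, lhs = lhs, rhs = rhs)
ex_app <- function(fn, args) list(op = "app", fn = fn, args = args)

## ---- tokenizer -----------------------------------------------------------

# Tokens: list(type, text, pos).  Types: ident, num, op, punct, eof.
tokenize <- function(text) {
  ops <- c("<=>", "=>", "&", "|", "^", "!", "~", "(", ")", ",", ":", "@",
    "{", "}", "[", "]")
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, txt, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, text = txt, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) {
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j + 1L, j + 1L))) j <- j + 1L
      push("ident", substr(text, i, j), i)
      i <- j + 1L
      next
    }
    if (grepl("^[0-9]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9]$", substr(text, j + 1L, j + 1L))) j <- j + 1L
      push("num", substr(text, i, j), i)
      i <- j + 1L
      next
    }
    matched <- FALSE
    for (op in ops) {
      if (substr(text, i, i + nchar(op) - 1L) == op) {
        push("op", op, i)
        i <- i + nchar(op)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("parse error at position %d: unexpected character '%s'", i, ch))
    }
  }
  push("eof", "", n + 1L)
  tokens
}

# Small cursor object over a token list.
new_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$k <- 1L
  env
}
cur_peek <- function(cur) cur$tokens[[cur$k]]
cur_next <- function(cur) {
  t <- cur$tokens[[cur$k]]
  cur$k <- cur$k + 1L
  t
}
cur_expect <- function(cur, type, text = NULL) {
  t <- cur_next(cur)
  ok <- t$type == type && (is.null(text) || t$text == text)
  if (!ok) {
    want <- if (is.null(text)) type else sprintf("'%s'", text)
    stop(sprintf(
      "parse error at position %d: expected %s, found '%s'",
      t$pos, want, t$text
    ))
  }
  t
}
cur_at <- function(cur, type, text = NULL) {
  t <- cur_peek(cur)
  t$type == type && (is.null(text) || t$text == text)
}

## ---- update-expression parser --------------------------------------------

#' Parse a Boolean update expression
#'
#' Parses the textual form of an update expression into an AST.  The
#' grammar supports constants `0`/`1`/`true`/`false`, variable references,
#' negation `!`, the binary connectives `&`, `|`, `^`, `=>`, `<=>`, and
#' applications of uninterpreted function symbols `g(e1, ..., ek)`,
#' arbitrarily nested.
#'
#' @param text expression string.
#' @return an update-expression AST (a nested list).
#' @examples
#' parse_update_expr("g(A, !B) | (A & C)")
#' @export
parse_update_expr <- function(text) {
  cur <- new_cursor(tokenize(text))
  e <- parse_iff(cur)
  t <- cur_peek(cur)
  if (t$type != "eof") {
    stop(sprintf("parse error at position %d: unexpected '%s'", t$pos, t$text))
  }
  e
}

parse_iff <- function(cur) {
  lhs <- parse_imp(cur)
  while (cur_at(cur, "op", "<=>")) {
    cur_next(cur)
    lhs <- ex_bin("iff", lhs, parse_imp(cur))
  }
  lhs
}
parse_imp <- function(cur) {
  lhs <- parse_xor(cur)
  if (cur_at(cur, "op", "=>")) {
    cur_next(cur)
    return(ex_bin("imp", lhs, parse_imp(cur))) # right associative
  }
  lhs
}
parse_xor <- function(cur) {
  lhs <- parse_or(cur)
  while (cur_at(cur, "op", "^")) {
    cur_next(cur)
    lhs <- ex_bin("xor", lhs, parse_or(cur))
  }
  lhs
}
parse_or <- function(cur) {
  lhs <- parse_and(cur)
  while (cur_at(cur, "op", "|")) {
    cur_next(cur)
    lhs <- ex_bin("or", lhs, parse_and(cur))
  }
  lhs
}
parse_and <- function(cur) {
  lhs <- parse_unary(cur)
  while (cur_at(cur, "op", "&")) {
    cur_next(cur)
    lhs <- ex_bin("and", lhs, parse_unary(cur))
  }
  lhs
}
parse_unary <- function(cur) {
  if (cur_at(cur, "op", "!") || cur_at(cur, "op", "~")) {
    cur_next(cur)
    return(ex_not(parse_unary(cur)))
  }
  parse_atom(cur)
}
parse_atom <- function(cur) {
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
          args[[length(args) + 1L]] <- parse_iff(cur)
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
    e <- parse_iff(cur)
    cur_expect(cur, "op", ")")
    return(e)
  }
  stop(sprintf("parse error at position %d: unexpected '%s'", t$pos, t$text))
}

## ---- printer and traversal ------------------------------------------------

BIN_OPS <- c(and = "&", or = "|", xor = "^", imp = "=>", iff = "<=>")

#' Deparse an update expression AST back to text
#'
#' The printed form re-parses to an identical AST.
#'
#' @param e expression AST.
#' @return a string.
#' @export
format_update_expr <- function(e) {
  fmt <- function(e) {
    switch(e$op,
      const = as.character(e$value),
      var = e$name,
      not = paste0("!", wrap(e$arg)),
      app = paste0(e$fn, "(", paste(vapply(e$args, fmt, ""), collapse = ", "), ")"),
      paste(wrap(e$lhs), BIN_OPS[[e$op]], wrap(e$rhs))
    )
  }
  wrap <- function(e) {
    if (e$op %in% names(BIN_OPS)) paste0("(", fmt(e), ")") else fmt(e)
  }
  fmt(e)
}

# Variable names referenced anywhere in an expression.
expr_variables <- function(e) {
  switch(e$op,
    const = character(0),
    var = e$name,
    not = expr_variables(e$arg),
    app = unique(unlist(c(list(character(0)), lapply(e$args, expr_variables)))),
    unique(c(expr_variables(e$lhs), expr_variables(e$rhs)))
  )
}

# Function-symbol names used anywhere in an expression.
expr_symbols <- function(e) {
  switch(e$op,
    const = ,
    var = character(0),
    not = expr_symbols(e$arg),
    app = unique(c(e$fn, unlist(lapply(e$args, expr_symbols)))),
    unique(c(expr_symbols(e$lhs), expr_symbols(e$rhs)))
  )
}

# Arities used per symbol: named integer vector (first occurrence wins;
# conflicts are reported by validate_sketch).
expr_symbol_arities <- function(e) {
  acc <- integer(0)
  walk <- function(e) {
    if (e$op == "app") {
      if (!e$fn %in% names(acc)) {
        a <- length(e$args)
        names(a) <- e$fn
        acc <<- c(acc, a)
      }
      lapply(e$args, walk)
    } else if (e$op == "not") {
      walk(e$arg)
    } else if (e$op %in% names(BIN_OPS)) {
      walk(e$lhs)
      walk(e$rhs)
    }
    invisible(NULL)
  }
  walk(e)
  acc
}
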
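# HCTL: hybrid CTL with state variables (binder `!{x}:`, jump `@{x}:`,
# existential state quantifier `3{x}:`) interpreted over the coloured
# fully asynchronous state-transition graph.
#
# Concrete syntax, loosest to tightest:
#   quantifier prefixes  3{x}: ...   @{x}: ...   !{x}: ...
#   <=>   =>   ^   |   &   EU/AU (binary, infix)   unary (~ ! EX AX EF AF EG AG)
# Atoms: network variable `v` (meaning v = 1), `~v`, constants
# `true`/`false`/`1`/`0`, state variable `{x}` (current state equals x),
# and the structural fixed-point predicate `fixed_point`.

hctl_svar <- function(name) list(op = "svar", name = name)
hctl_prop <- function(name) list(op = "prop", name = name)
hctl_fp <- function() list(op = "fp")
hctl_obs <- function(values, label = "") {
  list(op = "obs", values = values, label = label)
}
hctl_un <- function(op, arg) list(op = op, arg = arg)
hctl_quant <- function(op, var, body) list(op = op, var = var, body = body)

HCTL_UNARY <- c("EX", "AX", "EF", "AF", "EG", "AG")
HCTL_UNTIL <- c("EU", "AU")
HCTL_QUANT <- c("bind", "jump", "exists_state")

#' Parse an HCTL formula
#'
#' @param text formula string, e.g. `"3{x}: @{x}: (AG (EF {x}))"` — there
#'   exists a universally reachable state.
#' @return an HCTL AST; scoping of state variables is checked (unbound
#'   occurrences and rebinding on one path are errors).
#' @export
parse_hctl <- function(text) {
  cur <- new_cursor(tokenize(text))
  ast <- hctl_parse_quant(cur)
  t <- cur_peek(cur)
  if (t$type != "eof") {
    stop(sprintf("parse error at position %d: unexpected '%s'", t$pos, t$text))
  }
  hctl_check_scope(ast, character(0))
  ast
}

hctl_parse_svar_head <- function(cur) {
  cur_expect(cur, "op", "{")
  v <- cur_expect(cur, "ident")$text
  cur_expect(cur, "op", "}")
  cur_expect(cur, "op", ":")
  v
}

hctl_parse_quant <- function(cur) {
  if (cur_at(cur, "num", "3")) {
    cur_next(cur)
    return(hctl_quant("exists_state", hctl_parse_svar_head(cur), hctl_parse_quant(cur)))
  }
  if (cur_at(cur, "op", "@")) {
    cur_next(cur)
    return(hctl_quant("jump", hctl_parse_svar_head(cur), hctl_parse_quant(cur)))
  }
  if (cur_at(cur, "op", "!")) {
    # binder only when followed by '{'; plain '!' is negation
    save <- cur$k
    cur_next(cur)
    if (cur_at(cur, "op", "{")) {
      return(hctl_quant("bind", hctl_parse_svar_head(cur), hctl_parse_quant(cur)))
    }
    cur$k <- save
  }
  hctl_iff(cur)
}

hctl_iff <- function(cur) {
  lhs <- hctl_imp(cur)
  while (cur_at(cur, "op", "<=>")) {
    cur_next(cur)
    lhs <- ex_bin("iff", lhs, hctl_imp(cur))
  }
  lhs
}
hctl_imp <- function(cur) {
  lhs <- hctl_xor(cur)
  if (cur_at(cur, "op", "=>")) {
    cur_next(cur)
    return(ex_bin("imp", lhs, hctl_imp(cur)))
  }
  lhs
}
hctl_xor <- function(cur) {
  lhs <- hctl_or(cur)
  while (cur_at(cur, "op", "^")) {
    cur_next(cur)
    lhs <- ex_bin("xor", lhs, hctl_or(cur))
  }
  lhs
}
hctl_or <- function(cur) {
  lhs <- hctl_and(cur)
  while (cur_at(cur, "op", "|")) {
    cur_next(cur)
    lhs <- ex_bin("or", lhs, hctl_and(cur))
  }
  lhs
}
hctl_and <- function(cur) {
  lhs <- hctl_until(cur)
  while (cur_at(cur, "op", "&")) {
    cur_next(cur)
    lhs <- ex_bin("and", lhs, hctl_until(cur))
  }
  lhs
}
hctl_until <- function(cur) {
  lhs <- hctl_unary(cur)
  while (cur_at(cur, "ident") && cur_peek(cur)$text %in% HCTL_UNTIL) {
    op <- cur_next(cur)$text
    lhs <- ex_bin(op, lhs, hctl_unary(cur))
  }
  lhs
}
hctl_unary <- function(cur) {
  if (cur_at(cur, "op", "~")) {
    cur_next(cur)
    return(ex_not(hctl_unary(cur)))
  }
  if (cur_at(cur, "op", "!")) {
    save <- cur$k
    cur_next(cur)
    if (cur_at(cur, "op", "{")) { # nested binder
      return(hctl_quant("bind", hctl_parse_svar_head(cur), hctl_parse_quant(cur)))
    }
    cur$k <- save
    cur_next(cur)
    return(ex_not(hctl_unary(cur)))
  }
  if (cur_at(cur, "num", "3")) {
    cur_next(cur)
    return(hctl_quant("exists_state", hctl_parse_svar_head(cur), hctl_parse_quant(cur)))
  }
  if (cur_at(cur, "op", "@")) {
    cur_next(cur)
    return(hctl_quant("jump", hctl_parse_svar_head(cur), hctl_parse_quant(cur)))
  }
  if (cur_at(cur, "ident") && cur_peek(cur)$text %in% HCTL_UNARY) {
    op <- cur_next(cur)$text
    return(hctl_un(op, hctl_unary(cur)))
  }
  hctl_atom(cur)
}
hctl_atom <- function(cur) {
  t <- cur_peek(cur)
  if (t$type == "num") {
    cur_next(cur)
    if (!t$text %in% c("0", "1")) {
      stop(sprintf("parse error at position %d: constants must be 0 or 1", t$pos))
    }
    return(ex_const(as.integer(t$text)))
  }
  if (cur_at(cur, "op", "{")) {
    cur_next(cur)
    v <- cur_expect(cur, "ident")$text
    cur_expect(cur, "op", "}")
    return(hctl_svar(v))
  }
  if (t$type == "ident") {
    cur_next(cur)
    if (t$text %in% c("true", "false")) {
      return(ex_const(as.integer(t$text == "true")))
    }
    if (t$text == "fixed_point") {
      return(hctl_fp())
    }
    return(hctl_prop(t$text))
  }
  if (cur_at(cur, "op", "(")) {
    cur_next(cur)
    e <- hctl_parse_quant(cur)
    cur_expect(cur, "op", ")")
    return(e)
  }
  stop(sprintf("parse error at position %d: unexpected '%s'", t$pos, t$text))
}

hctl_check_scope <- function(ast, bound) {
  switch(ast$op,
    svar = {
      if (!ast$name %in% bound) {
        stop(sprintf("state variable '{%s}' used outside the scope of its binder", ast$name))
      }
    },
    bind = ,
    exists_state = {
      if (ast$var %in% bound) {
        stop(sprintf("state variable '{%s}' bound twice on one path", ast$var))
      }
      hctl_check_scope(ast$body, c(bound, ast$var))
    },
    jump = {
      if (!ast$var %in% bound) {
        stop(sprintf("jump to unbound state variable '{%s}'", ast$var))
      }
      hctl_check_scope(ast$body, bound)
    },
    prop = ,
    const = ,
    fp = ,
    obs = invisible(NULL),
    not = hctl_check_scope(ast$arg, bound),
    EX = ,
    AX = ,
    EF = ,
    AF = ,
    EG = ,
    AG = hctl_check_scope(ast$arg, bound),
    {
      hctl_check_scope(ast$lhs, bound)
      hctl_check_scope(ast$rhs, bound)
    }
  )
  invisible(NULL)
}

# Network variables mentioned as atomic propositions or inside
# observation atoms.
hctl_propositions <- function(ast) {
  switch(ast$op,
    prop = ast$name,
    obs = names(ast$values),
    const = ,
    svar = ,
    fp = character(0),
    not = ,
    EX = ,
    AX = ,
    EF = ,
    AF = ,
    EG = ,
    AG = hctl_propositions(ast$arg),
    bind = ,
    jump = ,
    exists_state = hctl_propositions(ast$body),
    unique(c(hctl_propositions(ast$lhs), hctl_propositions(ast$rhs)))
  )
}

# Distinct state-variable names, in order of first binding occurrence.
hctl_state_vars <- function(ast) {
  switch(ast$op,
    bind = ,
    exists_state = unique(c(ast$var, hctl_state_vars(ast$body))),
    jump = unique(c(ast$var, hctl_state_vars(ast$body))),
    svar = ast$name,
    prop = ,
    const = ,
    fp = ,
    obs = character(0),
    not = ,
    EX = ,
    AX = ,
    EF = ,
    AF = ,
    EG = ,
    AG = hctl_state_vars(ast$arg),
    unique(c(hctl_state_vars(ast$lhs), hctl_state_vars(ast$rhs)))
  )
}

#' Deparse an HCTL formula
#'
#' The printed form re-parses to an identical AST (observation atoms are
#' rendered as conjunctions of literals).
#'
#' @param ast an HCTL AST.
#' @return a string.
#' @export
format_hctl <- function(ast) {
  fmt <- function(a) {
    switch(a$op,
      svar = sprintf("{%s}", a$name),
      prop = a$name,
      const = as.character(a$value),
      fp = "fixed_point",
      obs = {
        if (length(a$values) == 0) {
          "true"
        } else {
          lits <- sprintf("%s%s", ifelse(a$values == 1L, "", "~"), names(a$values))
          paste0("(", paste(lits, collapse = " & "), ")")
        }
      },
      not = paste0("~", sub(a$arg)),
      bind = sprintf("!{%s}: %s", a$var, fmt(a$body)),
      jump = sprintf("@{%s}: %s", a$var, fmt(a$body)),
      exists_state = sprintf("3{%s}: %s", a$var, fmt(a$body)),
      EX = ,
      AX = ,
      EF = ,
      AF = ,
      EG = ,
      AG = paste0(a$op, " ", sub(a$arg)),
      EU = ,
      AU = paste0("(", sub(a$lhs), " ", a$op, " ", sub(a$rhs), ")"),
      paste0("(", fmt(a$lhs), " ", BIN_OPS[[a$op]], " ", fmt(a$rhs), ")")
    )
  }
  sub <- function(a) {
    if (a$op %in% c("svar", "prop", "const", "fp", "obs")) fmt(a) else paste0("(", fmt(a), ")")
  }
  fmt(ast)
}

## ---- symbolic model checking ----------------------------------------------

# Diagonal for state variable slot j: AND_i (state_i <=> copy^j_i).
hctl_diag <- function(ctx, slot) {
  key <- paste0("diag_", slot)
  cached <- ctx$cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- ctx$mgr
  out <- bdd_true
  for (pos in ctx_state_bits(ctx)) {
    out <- bdd_and(m, out, bdd_iff(m, bdd_v(m, pos), bdd_v(m, pos + slot)))
  }
  ctx$cache[[key]] <- out
  out
}

obs_to_bdd <- function(ctx, values) {
  m <- ctx$mgr
  out <- bdd_true
  for (v in names(values)) {
    pos <- ctx$state_pos[[v]]
    if (is.null(pos)) stop(sprintf("observation mentions unknown variable '%s'", v))
    lit <- bdd_v(m, pos)
    if (values[[v]] == 0L) lit <- bdd_not(m, lit)
    out <- bdd_and(m, out, lit)
  }
  out
}

#' Symbolic HCTL model checking
#'
#' Evaluates a formula over the coloured asynchronous state-transition
#' graph of the context's PSBN, for all colours at once.  Returns the
#' coloured state set of satisfying `(state, colour)` pairs; for formulas
#' with free state variables the result additionally ranges over the
#' bound-state copies.
#'
#' @param ctx symbolic context with enough state-variable slots
#'   (contexts created by [run_inference()] and [satisfying_colours()] are
#'   sized automatically).
#' @param formula an HCTL AST from [parse_hctl()] or [build_template()],
#'   or a formula string.
#' @return BDD handle: the satisfying coloured state set.
#' @export
hctl_check <- function(ctx, formula) {
  if (is.character(formula)) formula <- parse_hctl(formula)
  svars <- hctl_state_vars(formula)
  if (length(svars) > ctx$n_copies) {
    stop(sprintf(
      "formula uses %d state variables but the context has %d slots",
      length(svars), ctx$n_copies
    ))
  }
  slots <- stats::setNames(seq_along(svars), svars)
  m <- ctx$mgr
  rec <- function(a) {
    switch(a$op,
      const = if (a$value == 1L) bdd_true else bdd_false,
      prop = {
        pos <- ctx$state_pos[[a$name]]
        if (is.null(pos)) stop(sprintf("unknown variable '%s' in HCTL formula", a$name))
        bdd_v(m, pos)
      },
      svar = hctl_diag(ctx, slots[[a$name]]),
      fp = fixed_points(ctx),
      obs = obs_to_bdd(ctx, a$values),
      not = bdd_not(m, rec(a$arg)),
      and = ,
      or = ,
      xor = ,
      imp = ,
      iff = bdd_apply(m, a$op, rec(a$lhs), rec(a$rhs)),
      EX = pre_image(ctx, rec(a$arg)),
      AX = bdd_not(m, pre_image(ctx, bdd_not(m, rec(a$arg)))),
      EF = lfp_pre(ctx, rec(a$arg)),
      AG = bdd_not(m, lfp_pre(ctx, bdd_not(m, rec(a$arg)))),
      EG = gfp_pre(ctx, rec(a$arg)),
      AF = bdd_not(m, gfp_pre(ctx, bdd_not(m, rec(a$arg)))),
      EU = eu_fix(ctx, rec(a$lhs), rec(a$rhs)),
      AU = {
        phi <- rec(a$lhs)
        psi <- rec(a$rhs)
        npsi <- bdd_not(m, psi)
        bad <- bdd_or(
          m, eu_fix(ctx, npsi, bdd_and(m, bdd_not(m, phi), npsi)),
          gfp_pre(ctx, npsi)
        )
        bdd_not(m, bad)
      },
      bind = {
        slot <- slots[[a$var]]
        r <- bdd_and(m, rec(a$body), hctl_diag(ctx, slot))
        bdd_exists(m, r, ctx_copy_bits(ctx, slot))
      },
      jump = {
        slot <- slots[[a$var]]
        r <- bdd_and(m, rec(a$body), hctl_diag(ctx, slot))
        bdd_exists(m, r, ctx_state_bits(ctx))
      },
      exists_state = {
        slot <- slots[[a$var]]
        bdd_exists(m, rec(a$body), ctx_copy_bits(ctx, slot))
      },
      stop(sprintf("unknown HCTL operator '%s'", a$op))
    )
  }
  rec(formula)
}

# mu Z. seed | pre(Z)
lfp_pre <- function(ctx, seed) {
  z <- seed
  repeat {
    nxt <- bdd_or(ctx$mgr, z, pre_image(ctx, z))
    if (nxt == z) return(z)
    z <- nxt
  }
}

# nu Z. seed & pre(Z)
gfp_pre <- function(ctx, seed) {
  z <- seed
  repeat {
    nxt <- bdd_and(ctx$mgr, z, pre_image(ctx, z))
    if (nxt == z) return(z)
    z <- nxt
  }
}

# mu Z. psi | (phi & pre(Z))
eu_fix <- function(ctx, phi, psi) {
  z <- psi
  repeat {
    nxt <- bdd_or(ctx$mgr, psi, bdd_and(ctx$mgr, phi, pre_image(ctx, z)))
    if (nxt == z) return(z)
    z <- nxt
  }
}

#' Colours under which a closed HCTL formula holds
#'
#' Universal-over-states convention: a colour satisfies the formula iff
#' every state does.  All property templates wrap their content in outer
#' state quantifiers and jumps, making the result state independent; for
#' raw user formulas whose result still depends on the current state a
#' warning explains that the universal convention is applied.
#'
#' @param psbn a [new_psbn()] object (or an existing context).
#' @param formula HCTL AST or formula string (must be closed: no free
#'   state variables).
#' @return list with `colours` (BDD handle over parameter bits) and `ctx`
#'   (the context the handle lives in).
#' @export
satisfying_colours <- function(psbn, formula) {
  if (is.character(formula)) formula <- parse_hctl(formula)
  ctx <- if (inherits(psbn, "bn_context")) psbn else {
    new_context(psbn, n_state_vars = length(hctl_state_vars(formula)))
  }
  res <- hctl_check(ctx, formula)
  sup <- bdd_support(ctx$mgr, res)
  copies <- unlist(lapply(seq_len(ctx$n_copies), function(j) ctx_copy_bits(ctx, j)))
  if (length(intersect(sup, copies))) {
    stop("formula has free state variables; colour satisfaction is undefined")
  }
  if (length(intersect(sup, ctx_state_bits(ctx)))) {
    warning(paste(
      "HCTL result still depends on the current state;",
      "applying the universal-over-states convention"
    ))
  }
  list(colours = bdd_forall(ctx$mgr, res, ctx_state_bits(ctx)), ctx = ctx)
}

## ---- templates -------------------------------------------------------------

MAX_ATTRACTOR_BOUND <- 8L

#' Expand a dynamic-property template to HCTL
#'
#' Templates translate observation datasets and attractor requirements to
#' HCTL:
#' * **fixed points**: every observation is matched by some fixed point —
#'   `AND_o 3{x}: @{x}: (obs(o) & fixed_point)`;
#' * **attractor count**: at least `m` pairwise unreachable attractor
#'   states exist (each `@{x_i}: !{y}: AG EF {y}` with mutual
#'   `~EF` separation); "exactly" combines at-least-`min` with the negated
#'   at-least-`max + 1`;
#' * **attractor coverage**: no attractor state lies outside the
#'   observations;
#' * **time series**: some path visits the observations in order
#'   (nested `EF` reachability).
#'
#' @param prop a dynamic property object (see [dyn_fixed_points()] etc.).
#' @param datasets list of datasets the property may reference.
#' @return an HCTL AST.
#' @export
build_template <- function(prop, datasets = list()) {
  find_dataset <- function(id) {
    for (d in datasets) {
      if (d$id == id) return(d)
    }
    stop(sprintf("unknown dataset '%s'", id))
  }
  obs_atoms <- function(d) {
    lapply(d$observations, function(o) hctl_obs(o$values, o$id))
  }
  and_all <- function(xs) Reduce(function(a, b) ex_bin("and", a, b), xs)
  switch(prop$kind,
    hctl = parse_hctl(prop$text),
    fixed_points = {
      d <- find_dataset(prop$dataset_id)
      if (length(d$observations) == 0) {
        stop(sprintf("dataset '%s' has no observations", prop$dataset_id))
      }
      and_all(lapply(obs_atoms(d), function(o) {
        hctl_quant(
          "exists_state", "x",
          hctl_quant("jump", "x", ex_bin("and", o, hctl_fp()))
        )
      }))
    },
    attractor_count = {
      if (prop$min > MAX_ATTRACTOR_BOUND ||
        (is.finite(prop$max) && prop$max + 1L > MAX_ATTRACTOR_BOUND)) {
        stop(sprintf(
          "attractor-count bounds above %d are not supported (each bound adds a bound-state copy)",
          MAX_ATTRACTOR_BOUND
        ))
      }
      f <- attractor_at_least(prop$min)
      if (is.finite(prop$max)) {
        f <- ex_bin("and", f, ex_not(attractor_at_least(prop$max + 1L)))
      }
      f
    },
    attractor_coverage = {
      d <- find_dataset(prop$dataset_id)
      outside <- lapply(obs_atoms(d), ex_not)
      body <- hctl_quant("bind", "y", hctl_un("AG", hctl_un("EF", hctl_svar("y"))))
      if (length(outside)) body <- ex_bin("and", body, and_all(outside))
      ex_not(hctl_quant("exists_state", "x", hctl_quant("jump", "x", body)))
    },
    time_series = {
      d <- find_dataset(prop$dataset_id)
      if (length(d$observations) == 0) {
        stop(sprintf("dataset '%s' has no observations", prop$dataset_id))
      }
      atoms <- obs_atoms(d)
      chain <- atoms[[length(atoms)]]
      for (i in rev(seq_len(length(atoms) - 1L))) {
        chain <- ex_bin("and", atoms[[i]], hctl_un("EF", chain))
      }
      hctl_quant("exists_state", "x", hctl_quant("jump", "x", chain))
    },
    stop(sprintf("unknown dynamic property kind '%s'", prop$kind))
  )
}

# At least m pairwise-unreachable attractor states exist.
attractor_at_least <- function(m) {
  xs <- paste0("x", seq_len(m))
  is_attr <- function(x) {
    hctl_quant(
      "jump", x,
      hctl_quant("bind", "y", hctl_un("AG", hctl_un("EF", hctl_svar("y"))))
    )
  }
  sep <- function(xi, xj) {
    hctl_quant("jump", xi, ex_not(hctl_un("EF", hctl_svar(xj))))
  }
  parts <- lapply(xs, is_attr)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        parts[[length(parts) + 1L]] <- sep(xs[i], xs[j])
      }
    }
  }
  body <- Reduce(function(a, b) ex_bin("and", a, b), parts)
  for (x in rev(xs)) body <- hctl_quant("exists_state", x, body)
  body
}
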
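# Sketch data model: influence graph, partially specified Boolean network,
# observation datasets, static/dynamic properties, annotations — plus the
# structural validation and defaulting rules.

REG_SIGNS <- c("positive", "negative", "unknown")
REG_ESSENTIAL <- c("true", "unknown")

#' Build an influence graph
#'
#' The influence graph lists the network variables and all the *possible*
#' regulations between them.  A regulation carries a sign
#' (`"positive"`/`"negative"`/`"unknown"`) and an essentiality flag
#' (`"true"`/`"unknown"`).  Sign and essentiality generate static
#' constraints during inference when they are not `"unknown"`.
#'
#' @param variables character vector of variable names.
#' @param regulations data frame with columns `source`, `target` and
#'   optionally `sign` and `essential` (missing columns default to
#'   `"unknown"`).
#' @return an `influence_graph` object.
#' @examples
#' influence_graph(c("A", "B"), data.frame(
#'   source = "A", target = "B",
#'   sign = "positive", essential = "true"
#' ))
#' @export
influence_graph <- function(variables = character(0), regulations = NULL) {
  variables <- as.character(variables)
  if (is.null(regulations) || nrow(regulations) == 0) {
    regulations <- data.frame(
      source = character(0), target = character(0),
      sign = character(0), essential = character(0),
      stringsAsFactors = FALSE
    )
  } else {
    regulations <- as.data.frame(regulations, stringsAsFactors = FALSE)
    if (is.null(regulations$sign)) regulations$sign <- "unknown"
    if (is.null(regulations$essential)) regulations$essential <- "unknown"
    regulations <- regulations[, c("source", "target", "sign", "essential")]
  }
  structure(list(variables = variables, regulations = regulations),
    class = "influence_graph"
  )
}

# Regulators of `v`, in the canonical (lexicographic) order used for
# truth-table rows and default symbol applications.
regulators_of <- function(graph, v) {
  sort(graph$regulations$source[graph$regulations$target == v])
}

#' Default update expression for a variable
#'
#' When no update expression is given for a variable, a fresh function
#' symbol is created and applied to all the variable's regulators (in
#' lexicographic order), leaving the update mechanism fully unspecified.
#'
#' @param v variable name.
#' @param graph an [influence_graph()].
#' @param used_names character vector of symbol names already taken.
#' @return list with `symbol` (list with `name`, `arity`) and `expr` (AST).
#' @examples
#' g <- influence_graph(c("A", "B", "C"), data.frame(
#'   source = c("A", "B"), target = c("C", "C")
#' ))
#' default_update_expr("C", g)
#' @export
default_update_expr <- function(v, graph, used_names = character(0)) {
  stopifnot(v %in% graph$variables)
  regs <- regulators_of(graph, v)
  name <- paste0("g_", v)
  if (name %in% used_names) {
    i <- 1L
    while (paste0(name, "_", i) %in% used_names) i <- i + 1L
    name <- paste0(name, "_", i)
  }
  list(
    symbol = list(name = name, arity = length(regs)),
    expr = ex_app(name, lapply(regs, ex_var))
  )
}

#' Build a partially specified Boolean network (PSBN)
#'
#' A PSBN assigns one update expression to every variable of the influence
#' graph.  Expressions may apply uninterpreted function symbols; variables
#' without an explicit expression get a fresh symbol applied to all their
#' regulators (see [default_update_expr()]).  Symbols are collected from
#' the expressions automatically; `symbols` may declare extra ones or fix
#' arities explicitly.
#'
#' @param graph an [influence_graph()].
#' @param updates named list/character vector mapping variable names to
#'   update expressions (strings or ASTs).  Missing variables are
#'   defaulted.
#' @param symbols optional data frame with columns `name`, `arity`.
#' @return a `psbn` object.
#' @examples
#' g <- influence_graph(c("A", "B"), data.frame(
#'   source = c("A", "B"), target = c("B", "A")
#' ))
#' new_psbn(g, updates = list(A = "!B")) # B's update is defaulted to g_B(A)
#' @export
new_psbn <- function(graph, updates = list(), symbols = NULL) {
  update <- list()
  for (v in names(updates)) {
    e <- updates[[v]]
    update[[v]] <- if (is.character(e)) parse_update_expr(e) else e
  }
  declared <- if (is.null(symbols)) {
    data.frame(name = character(0), arity = integer(0), stringsAsFactors = FALSE)
  } else {
    as.data.frame(symbols, stringsAsFactors = FALSE)[, c("name", "arity")]
  }
  # collect symbols used in explicit expressions
  for (v in names(update)) {
    ar <- expr_symbol_arities(update[[v]])
    for (s in names(ar)) {
      if (!s %in% declared$name) {
        declared <- rbind(declared, data.frame(
          name = s, arity = unname(ar[[s]]),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  # default the rest, deterministically in variable order
  for (v in graph$variables) {
    if (is.null(update[[v]])) {
      d <- default_update_expr(v, graph, c(declared$name, graph$variables))
      update[[v]] <- d$expr
      declared <- rbind(declared, data.frame(
        name = d$symbol$name, arity = d$symbol$arity,
        stringsAsFactors = FALSE
      ))
    }
  }
  declared <- declared[order(declared$name), , drop = FALSE]
  rownames(declared) <- NULL
  structure(
    list(graph = graph, symbols = declared, update = update),
    class = "psbn"
  )
}

#' @export
print.psbn <- function(x, ...) {
  cat(sprintf(
    "Partially specified Boolean network: %d variables, %d regulations, %d function symbols\n",
    length(x$graph$variables), nrow(x$graph$regulations), nrow(x$symbols)
  ))
  for (v in sort(x$graph$variables)) {
    cat(sprintf("  %s := %s\n", v, format_update_expr(x$update[[v]])))
  }
  invisible(x)
}

## ---- observations ---------------------------------------------------------

#' Create an observation
#'
#' A (possibly partial) binarized measurement: variables absent from
#' `values` are unconstrained.
#'
#' @param id observation identifier.
#' @param values named vector of 0/1 values.
#' @return an `observation` object.
#' @export
new_observation <- function(id, values) {
  values <- unlist(values)
  storage.mode(values) <- "integer"
  structure(list(id = as.character(id), values = values), class = "observation")
}

#' Create a dataset of observations
#'
#' @param id dataset identifier.
#' @param observations list of [new_observation()] objects; order is
#'   meaningful for time series.
#' @param category `"unspecified"`, `"steady_state"` or `"time_series"`.
#' @return a `dataset` object.
#' @export
new_dataset <- function(id, observations, category = c("unspecified", "steady_state", "time_series")) {
  category <- match.arg(category)
  structure(
    list(id = as.character(id), observations = observations, category = category),
    class = "dataset"
  )
}

## ---- properties -----------------------------------------------------------

new_static_property <- function(kind, id, fields) {
  structure(c(list(kind = kind, id = id), fields), class = "static_property")
}

#' Static (update-function) properties
#'
#' Constructors for the supported static constraints, which restrict the
#' admissible interpretations of function symbols: regulation essentiality
#' and monotonicity (defined on the instantiated update function of the
#' target), symbol-level essentiality and monotonicity of one argument
#' (defined on the raw truth table), and free-form first-order formulas
#' over Booleans (see [parse_fol()]).
#'
#' @param source,target regulation endpoints.
#' @param symbol function symbol name.
#' @param arg_index 0-based argument position.
#' @param direction `"positive"` or `"negative"`.
#' @param text first-order formula, e.g. `"\\forall a: g(a, 1)"` written
#'   as `"forall a: g(a, 1)"`.
#' @param id optional property identifier (defaulted deterministically).
#' @return a `static_property` object.
#' @name static-properties
NULL

#' @rdname static-properties
#' @export
prop_regulation_essential <- function(source, target, id = NULL) {
  new_static_property(
    "regulation_essential",
    id %||% sprintf("essential_%s_%s", source, target),
    list(source = source, target = target)
  )
}

#' @rdname static-properties
#' @export
prop_regulation_monotone <- function(source, target, direction, id = NULL) {
  stopifnot(direction %in% c("positive", "negative"))
  new_static_property(
    "regulation_monotone",
    id %||% sprintf("monotone_%s_%s", source, target),
    list(source = source, target = target, direction = direction)
  )
}

#' @rdname static-properties
#' @export
prop_symbol_essential <- function(symbol, arg_index, id = NULL) {
  new_static_property(
    "symbol_essential",
    id %||% sprintf("essential_%s_%d", symbol, arg_index),
    list(symbol = symbol, arg_index = as.integer(arg_index))
  )
}

#' @rdname static-properties
#' @export
prop_symbol_monotone <- function(symbol, arg_index, direction, id = NULL) {
  stopifnot(direction %in% c("positive", "negative"))
  new_static_property(
    "symbol_monotone",
    id %||% sprintf("monotone_%s_%d", symbol, arg_index),
    list(symbol = symbol, arg_index = as.integer(arg_index), direction = direction)
  )
}

#' @rdname static-properties
#' @export
prop_fol <- function(text, id = NULL) {
  new_static_property("fol", id %||% paste0("fol_", substr(text, 1, 24)), list(text = text))
}

new_dynamic_property <- function(kind, id, fields) {
  structure(c(list(kind = kind, id = id), fields), class = "dynamic_property")
}

#' Dynamic (HCTL) properties
#'
#' Constructors for dynamic constraints on the fully asynchronous dynamics
#' of the candidate networks.  Raw HCTL formulas use the grammar of
#' [parse_hctl()]; the template constructors expand to HCTL during
#' inference (see [build_template()]).
#'
#' @param text raw HCTL formula text.
#' @param dataset_id id of a dataset in the sketch.
#' @param min,max attractor count bounds (`max = Inf` for "at least min").
#' @param id optional property identifier.
#' @return a `dynamic_property` object.
#' @name dynamic-properties
NULL

#' @rdname dynamic-properties
#' @export
dyn_hctl <- function(text, id = NULL) {
  new_dynamic_property("hctl", id %||% paste0("hctl_", substr(text, 1, 24)), list(text = text))
}

#' @rdname dynamic-properties
#' @export
dyn_fixed_points <- function(dataset_id, id = NULL) {
  new_dynamic_property(
    "fixed_points", id %||% paste0("fixed_points_", dataset_id),
    list(dataset_id = dataset_id)
  )
}

#' @rdname dynamic-properties
#' @export
dyn_attractor_count <- function(min, max = min, id = NULL) {
  new_dynamic_property(
    "attractor_count", id %||% sprintf("attractor_count_%s_%s", min, max),
    list(min = as.integer(min), max = if (is.finite(max)) as.integer(max) else Inf)
  )
}

#' @rdname dynamic-properties
#' @export
dyn_attractor_coverage <- function(dataset_id, id = NULL) {
  new_dynamic_property(
    "attractor_coverage", id %||% paste0("attractor_coverage_", dataset_id),
    list(dataset_id = dataset_id)
  )
}

#' @rdname dynamic-properties
#' @export
dyn_time_series <- function(dataset_id, id = NULL) {
  new_dynamic_property(
    "time_series", id %||% paste0("time_series_", dataset_id),
    list(dataset_id = dataset_id)
  )
}

## ---- sketch ----------------------------------------------------------------

#' Assemble a Boolean network sketch
#'
#' A sketch bundles a PSBN with static properties, observation datasets,
#' dynamic properties, and free-text annotations.  It is the full partial
#' specification from which the set of consistent Boolean networks is
#' inferred.
#'
#' @param psbn a [new_psbn()] object.
#' @param static_properties list of static property objects.
#' @param datasets list of [new_dataset()] objects.
#' @param dynamic_properties list of dynamic property objects.
#' @param annotations named list mapping element ids to free text; inert
#'   metadata, stored and round-tripped but never interpreted.
#' @return a `sketch` object.
#' @export
new_sketch <- function(psbn, static_properties = list(), datasets = list(),
                       dynamic_properties = list(), annotations = list()) {
  structure(
    list(
      psbn = psbn, static_properties = static_properties,
      datasets = datasets, dynamic_properties = dynamic_properties,
      annotations = annotations
    ),
    class = "sketch"
  )
}

#' @export
print.sketch <- function(x, ...) {
  cat(sprintf(
    "Boolean network sketch: %d variables, %d regulations, %d symbols, %d static + %d dynamic properties, %d datasets\n",
    length(x$psbn$graph$variables), nrow(x$psbn$graph$regulations),
    nrow(x$psbn$symbols), length(x$static_properties),
    length(x$dynamic_properties), length(x$datasets)
  ))
  invisible(x)
}

dataset_by_id <- function(sketch, id) {
  for (d in sketch$datasets) {
    if (d$id == id) return(d)
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- validation ------------------------------------------------------------

issue_frame <- function() {
  data.frame(
    severity = character(0), element = character(0), message = character(0),
    stringsAsFactors = FALSE
  )
}

#' Validate a sketch
#'
#' Checks every structural invariant of the sketch and returns the list of
#' problems found rather than raising: unknown names, arity mismatches,
#' duplicate identifiers, unresolvable property references are errors;
#' benign oddities (a declared regulation that no expression reads and no
#' property forces to be essential) are warnings.
#'
#' @param sketch a [new_sketch()] object (a bare `psbn` is also accepted).
#' @return data frame with columns `severity` (`"error"`/`"warning"`),
#'   `element`, `message`; zero rows iff the sketch is clean.
#' @export
validate_sketch <- function(sketch) {
  if (inherits(sketch, "psbn")) sketch <- new_sketch(sketch)
  iss <- issue_frame()
  add <- function(severity, element, message) {
    iss[nrow(iss) + 1L, ] <<- list(severity, element, message)
  }
  g <- sketch$psbn$graph
  vars <- g$variables

  for (v in vars) {
    if (!grepl(IDENT_RE, v)) add("error", v, sprintf("invalid variable name '%s'", v))
  }
  if (anyDuplicated(vars)) {
    add("error", "variables", sprintf(
      "duplicate variable names: %s",
      paste(unique(vars[duplicated(vars)]), collapse = ", ")
    ))
  }

  regs <- g$regulations
  for (i in seq_len(nrow(regs))) {
    for (endp in c(regs$source[i], regs$target[i])) {
      if (!endp %in% vars) {
        add("error", sprintf("%s -> %s", regs$source[i], regs$target[i]),
          sprintf("regulation endpoint '%s' is not a declared variable", endp))
      }
    }
    if (!regs$sign[i] %in% REG_SIGNS) {
      add("error", sprintf("%s -> %s", regs$source[i], regs$target[i]),
        sprintf("invalid sign '%s'", regs$sign[i]))
    }
    if (!regs$essential[i] %in% REG_ESSENTIAL) {
      add("error", sprintf("%s -> %s", regs$source[i], regs$target[i]),
        sprintf("invalid essentiality '%s'", regs$essential[i]))
    }
  }
  if (nrow(regs) && anyDuplicated(regs[, c("source", "target")])) {
    add("error", "regulations", "duplicate (source, target) regulation pairs")
  }

  syms <- sketch$psbn$symbols
  for (i in seq_len(nrow(syms))) {
    if (!grepl(IDENT_RE, syms$name[i])) {
      add("error", syms$name[i], sprintf("invalid symbol name '%s'", syms$name[i]))
    }
    if (syms$name[i] %in% vars) {
      add("error", syms$name[i],
        sprintf("symbol name '%s' collides with a variable name", syms$name[i]))
    }
    if (syms$arity[i] < 0) add("error", syms$name[i], "negative arity")
  }
  if (nrow(syms) && anyDuplicated(syms$name)) {
    add("error", "symbols", "duplicate symbol names")
  }

  # update expressions
  for (v in vars) {
    e <- sketch$psbn$update[[v]]
    if (is.null(e)) {
      add("error", v, sprintf("variable '%s' has no update expression", v))
      next
    }
    regs_v <- regulators_of(g, v)
    for (u in expr_variables(e)) {
      if (!u %in% vars) {
        add("error", v, sprintf("'%s' in the update of '%s' is not a declared variable", u, v))
      } else if (!u %in% regs_v) {
        add("error", v, sprintf("%s is not a regulator of %s", u, v))
      }
    }
    ar <- expr_symbol_arities(e)
    check_apps <- function(e) {
      if (e$op == "app") {
        i <- match(e$fn, syms$name)
        if (is.na(i)) {
          add("error", v, sprintf("unknown function symbol '%s' in the update of '%s'", e$fn, v))
        } else if (length(e$args) != syms$arity[i]) {
          add("error", v, sprintf(
            "symbol '%s' applied to %d arguments but has arity %d",
            e$fn, length(e$args), syms$arity[i]
          ))
        }
        lapply(e$args, check_apps)
      } else if (e$op == "not") {
        check_apps(e$arg)
      } else if (e$op %in% names(BIN_OPS)) {
        check_apps(e$lhs)
        check_apps(e$rhs)
      }
      invisible(NULL)
    }
    check_apps(e)
  }

  # unused-regulator warnings
  forced_essential <- vapply(sketch$static_properties, function(p) {
    if (p$kind == "regulation_essential") paste(p$source, p$target) else ""
  }, "")
  for (i in seq_len(nrow(regs))) {
    u <- regs$source[i]
    v <- regs$target[i]
    if (!u %in% vars || !v %in% vars) next
    e <- sketch$psbn$update[[v]]
    if (is.null(e)) next
    mentioned <- u %in% expr_variables(e)
    forced <- regs$essential[i] == "true" || paste(u, v) %in% forced_essential
    if (!mentioned && !forced) {
      add("warning", sprintf("%s -> %s", u, v),
        sprintf("regulation (%s, %s) is declared but the update of %s never reads %s", u, v, v, u))
    }
    if (!mentioned && forced) {
      add("warning", sprintf("%s -> %s", u, v),
        sprintf(
          "regulation (%s, %s) is required essential but the update of %s never reads %s; no candidate can satisfy it",
          u, v, v, u
        ))
    }
  }

  # datasets
  ids <- vapply(sketch$datasets, function(d) d$id, "")
  if (anyDuplicated(ids)) add("error", "datasets", "duplicate dataset ids")
  for (d in sketch$datasets) {
    oids <- vapply(d$observations, function(o) o$id, "")
    if (anyDuplicated(oids)) {
      add("error", d$id, sprintf("duplicate observation ids in dataset '%s'", d$id))
    }
    if (d$category == "time_series" && length(d$observations) < 2) {
      add("error", d$id, "time-series dataset needs at least 2 observations")
    }
    for (o in d$observations) {
      bad <- setdiff(names(o$values), vars)
      if (length(bad)) {
        add("error", paste(d$id, o$id, sep = "/"),
          sprintf("observation maps unknown variables: %s", paste(bad, collapse = ", ")))
      }
      if (length(o$values) && !all(o$values %in% c(0L, 1L))) {
        add("error", paste(d$id, o$id, sep = "/"), "observation values must be 0 or 1")
      }
    }
  }

  # static properties
  for (p in sketch$static_properties) {
    if (p$kind %in% c("regulation_essential", "regulation_monotone")) {
      found <- any(regs$source == p$source & regs$target == p$target)
      if (!found) {
        add("error", p$id, sprintf("regulation (%s, %s) is not declared", p$source, p$target))
      }
    } else if (p$kind %in% c("symbol_essential", "symbol_monotone")) {
      i <- match(p$symbol, syms$name)
      if (is.na(i)) {
        add("error", p$id, sprintf("unknown function symbol '%s'", p$symbol))
      } else if (p$arg_index < 0 || p$arg_index >= syms$arity[i]) {
        add("error", p$id, sprintf(
          "argument index %d out of range for '%s' (arity %d)",
          p$arg_index, p$symbol, syms$arity[i]
        ))
      }
    } else if (p$kind == "fol") {
      res <- tryCatch(parse_fol(p$text), error = function(e) e)
      if (inherits(res, "error")) {
        add("error", p$id, conditionMessage(res))
      } else {
        msg <- tryCatch(
          {
            fol_check_refs(res, syms, vars)
            NULL
          },
          error = function(e) conditionMessage(e)
        )
        if (!is.null(msg)) add("error", p$id, msg)
      }
    }
  }

  # dynamic properties
  for (p in sketch$dynamic_properties) {
    if (p$kind == "hctl") {
      res <- tryCatch(parse_hctl(p$text), error = function(e) e)
      if (inherits(res, "error")) {
        add("error", p$id, conditionMessage(res))
      } else {
        bad <- setdiff(hctl_propositions(res), vars)
        if (length(bad)) {
          add("error", p$id, sprintf(
            "HCTL formula mentions unknown variables: %s",
            paste(bad, collapse = ", ")
          ))
        }
      }
    } else if (p$kind %in% c("fixed_points", "attractor_coverage", "time_series")) {
      d <- dataset_by_id(sketch, p$dataset_id)
      if (is.null(d)) {
        add("error", p$id, sprintf("unknown dataset '%s'", p$dataset_id))
      } else if (p$kind != "attractor_coverage" && length(d$observations) == 0) {
        add("error", p$id, sprintf("dataset '%s' has no observations", p$dataset_id))
      }
    } else if (p$kind == "attractor_count") {
      if (p$min < 1 || (is.finite(p$max) && p$max < p$min)) {
        add("error", p$id, "attractor count bounds must satisfy 1 <= min <= max")
      }
    }
  }

  iss
}
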
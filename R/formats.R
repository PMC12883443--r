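# On-disk formats: AEON model text, observation CSV tables, BoolNet
# .bnet output for sampled candidates, and the JSON sketch document (the
# single source of truth; AEON import covers graph + expressions only).

## ---- AEON -----------------------------------------------------------------

AEON_ARROWS <- c(
  "->?" = "positive.unknown", "->" = "positive.true",
  "-|?" = "negative.unknown", "-|" = "negative.true",
  "-??" = "unknown.unknown", "-?" = "unknown.true"
)

#' Read / write AEON model text
#'
#' The AEON dialect: one regulation per line — `A -> B` (activation),
#' `A -| B` (inhibition), `A -? B` (unknown sign), with a `?` suffix
#' marking a non-essential (not necessarily observable) regulation, e.g.
#' `A ->? B`; update expressions as `$V: <expression>`; `#`-prefixed
#' metadata lines are ignored (with a warning).  Variables are the union
#' of regulation endpoints and `$`-declared names; variables without an
#' update line are left unset and defaulted by [new_psbn()].
#'
#' @param path file path, or a literal string containing newlines.
#' @return `read_aeon()`: list with `graph` (an [influence_graph()]) and
#'   `updates` (named character of expression texts).
#' @export
read_aeon <- function(path) {
  lines <- if (grepl("\n", path, fixed = TRUE)) {
    strsplit(path, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(path, warn = FALSE)
  }
  regs <- data.frame(
    source = character(0), target = character(0),
    sign = character(0), essential = character(0), stringsAsFactors = FALSE
  )
  updates <- character(0)
  declared <- character(0)
  n_meta <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (startsWith(line, "#")) {
      n_meta <- n_meta + 1L
      next
    }
    if (startsWith(line, "$")) {
      m <- regmatches(line, regexec("^\\$([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", line))[[1]]
      if (length(m) != 3) {
        stop(sprintf("malformed AEON update line %d: '%s'", i, line))
      }
      updates[m[2]] <- m[3]
      declared <- c(declared, m[2], expr_variables(parse_update_expr(m[3])))
      next
    }
    m <- regmatches(line, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)\\s*(->\\?|->|-\\|\\?|-\\||-\\?\\?|-\\?)\\s*([A-Za-z_][A-Za-z0-9_]*)$",
      line
    ))[[1]]
    if (length(m) != 4) {
      stop(sprintf("malformed AEON line %d: '%s'", i, line))
    }
    se <- strsplit(AEON_ARROWS[[m[3]]], ".", fixed = TRUE)[[1]]
    regs[nrow(regs) + 1L, ] <- list(m[2], m[4], se[1], se[2])
    declared <- c(declared, m[2], m[4])
  }
  if (n_meta > 0L) {
    warning(sprintf("ignored %d '#'-prefixed metadata line(s)", n_meta))
  }
  graph <- influence_graph(sort(unique(declared)), regs)
  list(graph = graph, updates = updates)
}

#' @rdname read_aeon
#' @param psbn a [new_psbn()] object.
#' @param path_out optional output path; omitted returns the text.
#' @export
write_aeon <- function(psbn, path_out = NULL) {
  arrows <- stats::setNames(names(AEON_ARROWS), AEON_ARROWS)
  regs <- psbn$graph$regulations
  lines <- character(0)
  for (i in seq_len(nrow(regs))) {
    a <- arrows[[paste(regs$sign[i], regs$essential[i], sep = ".")]]
    lines <- c(lines, sprintf("%s %s %s", regs$source[i], a, regs$target[i]))
  }
  for (v in sort(psbn$graph$variables)) {
    lines <- c(lines, sprintf("$%s: %s", v, format_update_expr(psbn$update[[v]])))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path_out)) {
    return(text)
  }
  writeLines(text, path_out, sep = "")
  invisible(path_out)
}

## ---- observation CSV ------------------------------------------------------

#' Read / write observation datasets as CSV
#'
#' Comma-separated UTF-8 table: header row is `id` followed by variable
#' names; one observation per row; cells are `0`, `1` or blank
#' (unconstrained).  Row order is preserved (meaningful for time series).
#'
#' @param path file path, or a literal string containing newlines.
#' @param id dataset id (defaults to the file base name).
#' @param category dataset category, see [new_dataset()].
#' @return `read_observations_csv()`: a `dataset` object.
#' @export
read_observations_csv <- function(path, id = NULL,
                                  category = c("unspecified", "steady_state", "time_series")) {
  category <- match.arg(category)
  literal <- grepl("\n", path, fixed = TRUE)
  con <- if (literal) textConnection(path) else path
  df <- utils::read.csv(con, colClasses = "character", check.names = FALSE)
  if (is.null(id)) {
    id <- if (literal) "dataset" else sub("\\.[^.]*$", "", basename(path))
  }
  if (ncol(df) < 1) stop("observation CSV needs an id column")
  vars <- colnames(df)[-1]
  obs <- list()
  for (r in seq_len(nrow(df))) {
    vals <- integer(0)
    for (j in seq_along(vars)) {
      cell <- trimws(df[r, j + 1])
      if (cell == "") next
      if (!cell %in% c("0", "1")) {
        stop(sprintf(
          "non-binary cell '%s' at row %d, column '%s'", cell, r, vars[j]
        ))
      }
      vals[vars[j]] <- as.integer(cell)
    }
    obs[[r]] <- new_observation(df[r, 1], vals)
  }
  oids <- vapply(obs, function(o) o$id, "")
  if (anyDuplicated(oids)) {
    stop(sprintf(
      "duplicate observation id(s): %s",
      paste(unique(oids[duplicated(oids)]), collapse = ", ")
    ))
  }
  new_dataset(id, obs, category)
}

#' @rdname read_observations_csv
#' @param dataset a `dataset` object.
#' @param path_out optional output path; omitted returns the text.
#' @param variables column order (defaults to the union of mapped
#'   variables, sorted).
#' @export
write_observations_csv <- function(dataset, path_out = NULL, variables = NULL) {
  if (is.null(variables)) {
    variables <- sort(unique(unlist(lapply(dataset$observations, function(o) names(o$values)))))
  }
  rows <- c(paste(c("id", variables), collapse = ","))
  for (o in dataset$observations) {
    cells <- vapply(variables, function(v) {
      if (v %in% names(o$values)) as.character(o$values[[v]]) else ""
    }, "")
    rows <- c(rows, paste(c(o$id, cells), collapse = ","))
  }
  text <- paste0(paste(rows, collapse = "\n"), "\n")
  if (is.null(path_out)) {
    return(text)
  }
  writeLines(text, path_out, sep = "")
  invisible(path_out)
}

## ---- BoolNet output -------------------------------------------------------

#' Write a concrete Boolean network in BoolNet .bnet format
#'
#' `targets, factors` header, one line per variable with the canonical
#' DNF of its truth table over its regulators (`0`/`1` for constants).
#'
#' @param bn a `concrete_bn` object.
#' @param path_out optional output path; omitted returns the text.
#' @export
write_bnet <- function(bn, path_out = NULL) {
  lines <- "targets, factors"
  for (v in bn$variables) {
    f <- bn$functions[[v]]
    k <- length(f$regulators)
    expr <- if (all(f$table == 0L)) {
      "0"
    } else if (all(f$table == 1L)) {
      "1"
    } else {
      terms <- vapply(which(f$table == 1L) - 1L, function(r) {
        w <- row_word(r, k)
        lits <- sprintf("%s%s", ifelse(w == 1L, "", "!"), f$regulators)
        if (k > 1) paste0("(", paste(lits, collapse = " & "), ")") else lits
      }, "")
      paste(terms, collapse = " | ")
    }
    lines <- c(lines, sprintf("%s, %s", v, expr))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path_out)) {
    return(text)
  }
  writeLines(text, path_out, sep = "")
  invisible(path_out)
}

## ---- sketch JSON ----------------------------------------------------------

SKETCH_FORMAT <- "bnsketch/1"

psbn_to_list <- function(psbn) {
  g <- psbn$graph
  list(
    variables = as.list(sort(g$variables)),
    regulations = lapply(seq_len(nrow(g$regulations)), function(i) {
      as.list(g$regulations[i, c("source", "target", "sign", "essential")])
    }),
    symbols = lapply(seq_len(nrow(psbn$symbols)), function(i) {
      list(name = psbn$symbols$name[i], arity = psbn$symbols$arity[i])
    }),
    update_expressions = stats::setNames(
      lapply(sort(g$variables), function(v) format_update_expr(psbn$update[[v]])),
      sort(g$variables)
    )
  )
}

psbn_from_list <- function(x) {
  regs <- if (length(x$regulations)) {
    do.call(rbind, lapply(x$regulations, function(r) {
      data.frame(
        source = r$source, target = r$target,
        sign = r$sign, essential = r$essential, stringsAsFactors = FALSE
      )
    }))
  } else {
    NULL
  }
  graph <- influence_graph(unlist(x$variables), regs)
  symbols <- if (length(x$symbols)) {
    do.call(rbind, lapply(x$symbols, function(s) {
      data.frame(name = s$name, arity = as.integer(s$arity), stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  updates <- lapply(x$update_expressions, function(t) parse_update_expr(t))
  new_psbn(graph, updates = updates, symbols = symbols)
}

static_to_list <- function(p) {
  p <- unclass(p)
  p[c("kind", "id", setdiff(names(p), c("kind", "id")))]
}

dynamic_to_list <- function(p) {
  p <- unclass(p)
  out <- p[c("kind", "id", setdiff(names(p), c("kind", "id")))]
  if (identical(p$kind, "attractor_count") && is.infinite(p$max)) {
    out$max <- "inf"
  }
  out
}

#' Read / write the sketch JSON document
#'
#' The JSON document is the canonical on-disk form of a sketch: sections
#' `variables`, `regulations`, `symbols`, `update_expressions`,
#' `static_properties`, `datasets`, `dynamic_properties`, `annotations`
#' and `format_version`.  Reading validates referential integrity via
#' [validate_sketch()] and fails on errors.
#'
#' @param path file path.
#' @return `read_sketch()`: a `sketch` object.
#' @export
read_sketch <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format_version, SKETCH_FORMAT)) {
    stop(sprintf(
      "unsupported sketch format '%s'", doc$format_version %||% "<missing>"
    ))
  }
  psbn <- psbn_from_list(doc)
  statics <- lapply(doc$static_properties, function(p) {
    fields <- p[setdiff(names(p), c("kind", "id"))]
    if (!is.null(fields$arg_index)) fields$arg_index <- as.integer(fields$arg_index)
    new_static_property(p$kind, p$id, fields)
  })
  dynamics <- lapply(doc$dynamic_properties, function(p) {
    fields <- p[setdiff(names(p), c("kind", "id"))]
    if (identical(p$kind, "attractor_count")) {
      fields$min <- as.integer(fields$min)
      fields$max <- if (identical(fields$max, "inf")) Inf else as.integer(fields$max)
    }
    new_dynamic_property(p$kind, p$id, fields)
  })
  datasets <- lapply(doc$datasets, function(d) {
    obs <- lapply(d$observations, function(o) {
      new_observation(o$id, unlist(o$values) %||% integer(0))
    })
    new_dataset(d$id, obs, d$category)
  })
  sketch <- new_sketch(
    psbn,
    static_properties = statics, datasets = datasets,
    dynamic_properties = dynamics,
    annotations = lapply(doc$annotations, as.character) %||% list()
  )
  issues <- validate_sketch(sketch)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop(
      "sketch document has validation errors:\n",
      paste(sprintf("  [%s] %s", errs$element, errs$message), collapse = "\n")
    )
  }
  sketch
}

#' @rdname read_sketch
#' @param sketch a `sketch` object.
#' @export
write_sketch <- function(sketch, path) {
  doc <- c(
    list(format_version = SKETCH_FORMAT),
    psbn_to_list(sketch$psbn),
    list(
      static_properties = lapply(sketch$static_properties, static_to_list),
      datasets = lapply(sketch$datasets, function(d) {
        list(
          id = d$id, category = d$category,
          observations = lapply(d$observations, function(o) {
            list(id = o$id, values = as.list(o$values))
          })
        )
      }),
      dynamic_properties = lapply(sketch$dynamic_properties, dynamic_to_list),
      annotations = sketch$annotations
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
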
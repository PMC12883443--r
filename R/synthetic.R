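# Synthetic sketch generator: draw a ground-truth Boolean network, hide a
# fraction of its update logic behind fresh function symbols, and emit
# properties/observations that the ground truth is guaranteed to satisfy.
# The generator is the test bedrock for ground-truth retention: the true
# colour must always survive inference.

#' Specification for the synthetic sketch generator
#'
#' @param n_vars number of network variables (>= 1).
#' @param density probability that any ordered pair becomes a regulation
#'   (in-degrees are capped at 3 to keep the hidden truth tables small).
#' @param hidden_fraction fraction of variables whose update expression is
#'   replaced by a fresh uninterpreted symbol over their regulators.
#' @param sign_prob probability that a (genuinely monotone) regulation is
#'   annotated with its sign, and that a regulation carries an explicit
#'   essentiality flag.
#' @param n_observations number of observations to emit.
#' @param seed RNG seed; a fixed seed reproduces the sketch byte for byte.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_vars, density = 0.4, hidden_fraction = 0.5,
                           sign_prob = 0.5, n_observations = 2L, seed = 1L) {
  stopifnot(
    n_vars >= 1, density >= 0, density <= 1,
    hidden_fraction >= 0, hidden_fraction <= 1,
    sign_prob >= 0, sign_prob <= 1, n_observations >= 0
  )
  structure(
    list(
      n_vars = as.integer(n_vars), density = density,
      hidden_fraction = hidden_fraction, sign_prob = sign_prob,
      n_observations = as.integer(n_observations), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Truth table (row order: first regulator most significant) rendered as a
# parseable expression: canonical DNF.
table_to_expr_text <- function(regulators, table) {
  k <- length(regulators)
  if (all(table == 0L)) return("0")
  if (all(table == 1L)) return("1")
  terms <- vapply(which(table == 1L) - 1L, function(r) {
    w <- row_word(r, k)
    lits <- sprintf("%s%s", ifelse(w == 1L, "", "!"), regulators)
    paste0("(", paste(lits, collapse = " & "), ")")
  }, "")
  paste(terms, collapse = " | ")
}

# Monotone direction of argument `pos` (1-based) in a table, or NA.
table_monotone_dir <- function(table, k, pos) {
  weight <- 2L^(k - pos)
  rows0 <- (seq_len(2L^k) - 1L)
  rows0 <- rows0[bitwAnd(rows0 %/% weight, 1L) == 0L]
  lo <- table[rows0 + 1L]
  hi <- table[rows0 + weight + 1L]
  if (all(lo <= hi)) return("positive")
  if (all(lo >= hi)) return("negative")
  NA_character_
}

table_essential_arg <- function(table, k, pos) {
  weight <- 2L^(k - pos)
  rows0 <- (seq_len(2L^k) - 1L)
  rows0 <- rows0[bitwAnd(rows0 %/% weight, 1L) == 0L]
  any(table[rows0 + 1L] != table[rows0 + weight + 1L])
}

# Bottom strongly connected components of the explicit asynchronous STG,
# as a list of state-index vectors.
explicit_attractors <- function(bn) {
  stg <- explicit_stg(bn)
  fwd <- vector("list", stg$ns)
  for (s in seq_len(stg$ns)) {
    reach <- logical(stg$ns)
    reach[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(stats::na.omit(as.vector(stg$succ[frontier, , drop = FALSE]))) + 1L
      nxt <- nxt[!reach[nxt]]
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    fwd[[s]] <- which(reach)
  }
  in_attr <- vapply(seq_len(stg$ns), function(s) {
    all(vapply(fwd[[s]], function(t) s %in% fwd[[t]], TRUE))
  }, TRUE)
  comps <- unique(lapply(which(in_attr), function(s) sort(fwd[[s]])))
  comps
}

#' Generate a synthetic sketch with a known ground truth
#'
#' Draws a random concrete Boolean network (random regulators; random
#' truth tables resampled until every declared regulator is essential, so
#' the influence graph is truthful), then builds a sketch: sign
#' annotations only where the true table is monotone, essentiality flags
#' only on genuinely essential regulations, observations taken from the
#' ground truth's actual behaviour (fixed points, or states along an
#' asynchronous trajectory for time series), and the requested dynamic
#' properties.  By construction the ground-truth colour satisfies every
#' emitted constraint.
#'
#' @param spec a [synthetic_spec()].
#' @param dynamic_kinds subset of `c("fixed_points", "time_series",
#'   "attractor_count")`: which dynamic properties to emit.
#' @param max_retries how many ground-truth draws to attempt when the
#'   requested observations cannot be produced (e.g. no fixed point
#'   exists).
#' @return list with `sketch`, `bn` (ground-truth network) and `colour`
#'   (the ground-truth parameter valuation over the sketch's symbols).
#' @export
generate_sketch <- function(spec, dynamic_kinds = "fixed_points",
                            max_retries = 60L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stopifnot(all(dynamic_kinds %in% c("fixed_points", "time_series", "attractor_count")))
  set.seed(spec$seed)
  vars <- sprintf("v%d", seq_len(spec$n_vars))
  for (attempt in seq_len(max_retries)) {
    drawn <- draw_ground_truth(vars, spec)
    bn <- drawn$bn
    need_fp <- "fixed_points" %in% dynamic_kinds && spec$n_observations > 0
    fps <- which(stg_fixed(explicit_stg(bn))) - 1L
    if (need_fp && length(fps) == 0L) next # resample: no steady state exists

    graph <- drawn$graph
    n <- spec$n_vars
    hidden <- sort(sample(vars, round(spec$hidden_fraction * n)))
    updates <- list()
    for (v in setdiff(vars, hidden)) {
      f <- bn$functions[[v]]
      updates[[v]] <- table_to_expr_text(f$regulators, f$table)
    }
    psbn <- new_psbn(graph, updates = updates)
    space <- build_parameter_space(psbn)

    # ground-truth colour: the hidden tables themselves
    colour <- stats::setNames(integer(space$total_bits), param_names(space))
    for (i in seq_len(nrow(space$symbols))) {
      v <- sub("^g_", "", space$symbols$name[i])
      tab <- bn$functions[[v]]$table
      colour[space$symbols$offset[i] + seq_along(tab)] <- tab
    }

    datasets <- list()
    dyn <- list()
    if ("fixed_points" %in% dynamic_kinds && spec$n_observations > 0) {
      take <- fps[sample.int(length(fps), min(spec$n_observations, length(fps)))]
      obs <- lapply(seq_along(take), function(i) {
        new_observation(sprintf("ss%d", i), state_to_values(take[i], vars))
      })
      datasets <- c(datasets, list(new_dataset("steady_states", obs, "steady_state")))
      dyn <- c(dyn, list(dyn_fixed_points("steady_states")))
    }
    if ("time_series" %in% dynamic_kinds && spec$n_observations >= 2) {
      walk <- async_walk(bn, spec$n_observations)
      if (length(walk) >= 2) {
        obs <- lapply(seq_along(walk), function(i) {
          new_observation(sprintf("t%d", i), state_to_values(walk[i], vars))
        })
        datasets <- c(datasets, list(new_dataset("trajectory", obs, "time_series")))
        dyn <- c(dyn, list(dyn_time_series("trajectory")))
      }
    }
    if ("attractor_count" %in% dynamic_kinds) {
      n_attr <- length(explicit_attractors(bn))
      if (n_attr <= 2L) { # larger bounds multiply the bound-state copies
        dyn <- c(dyn, list(dyn_attractor_count(1L, n_attr)))
      }
    }
    sketch <- new_sketch(psbn, datasets = datasets, dynamic_properties = dyn)
    return(list(sketch = sketch, bn = bn, colour = colour))
  }
  stop("could not draw a ground truth matching the requested observations")
}

state_to_values <- function(state, vars) {
  n <- length(vars)
  stats::setNames(as.integer(bitwAnd(bitwShiftR(state, (n - 1L):0L), 1L)), vars)
}

# One concrete random BN whose declared regulators are all essential.
draw_ground_truth <- function(vars, spec) {
  n <- length(vars)
  functions <- list()
  regs <- data.frame(
    source = character(0), target = character(0),
    sign = character(0), essential = character(0), stringsAsFactors = FALSE
  )
  for (v in vars) {
    cand <- vars[stats::runif(n) < spec$density]
    if (length(cand) > 3L) cand <- sort(sample(cand, 3L)) # cap in-degree
    cand <- sort(cand)
    k <- length(cand)
    repeat {
      tab <- as.integer(stats::runif(2L^k) < 0.5)
      if (k == 0L || all(vapply(seq_len(k), function(p) table_essential_arg(tab, k, p), TRUE))) break
    }
    functions[[v]] <- list(regulators = cand, table = tab)
    for (p in seq_along(cand)) {
      dir <- table_monotone_dir(tab, k, p)
      sign <- if (!is.na(dir) && stats::runif(1) < spec$sign_prob) dir else "unknown"
      essential <- if (stats::runif(1) < spec$sign_prob) "true" else "unknown"
      regs[nrow(regs) + 1L, ] <- list(cand[p], v, sign, essential)
    }
  }
  bn <- structure(
    list(variables = vars, functions = functions, colour = NULL),
    class = "concrete_bn"
  )
  list(bn = bn, graph = influence_graph(vars, regs))
}

# Random asynchronous trajectory: successive states (each a genuine
# single-variable transition of the ground truth).
async_walk <- function(bn, len) {
  stg <- explicit_stg(bn)
  s <- sample.int(stg$ns, 1L) - 1L
  out <- s
  while (length(out) < len) {
    nxt <- stats::na.omit(stg$succ[s + 1L, ])
    if (length(nxt) == 0L) break
    s <- if (length(nxt) == 1L) nxt[1L] else sample(nxt, 1L)
    out <- c(out, s)
  }
  out
}
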
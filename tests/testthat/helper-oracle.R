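# Test-side oracles, written independently of the package internals:
# exhaustive filters over raw truth tables and small hand-rolled helpers.

# All 2^(2^k) truth tables of arity k, rows in binary order (first
# argument most significant).
oracle_all_tables <- function(k) {
  rows <- 2^k
  lapply(0:(2^rows - 1), function(i) {
    as.integer(bitwAnd(bitwShiftR(i, (rows - 1):0), 1))
  })
}

# Row pairs differing only in argument `arg` (0-based).
oracle_row_pairs <- function(k, arg) {
  weight <- 2^(k - 1 - arg)
  rows0 <- (0:(2^k - 1))
  rows0 <- rows0[bitwAnd(rows0 %/% weight, 1) == 0]
  cbind(lo = rows0, hi = rows0 + weight)
}

oracle_monotone <- function(tab, k, arg, dir = "positive") {
  p <- oracle_row_pairs(k, arg)
  lo <- tab[p[, "lo"] + 1]
  hi <- tab[p[, "hi"] + 1]
  if (dir == "positive") all(lo <= hi) else all(lo >= hi)
}

oracle_essential <- function(tab, k, arg) {
  p <- oracle_row_pairs(k, arg)
  any(tab[p[, "lo"] + 1] != tab[p[, "hi"] + 1])
}

# Colour count of a colour-set BDD handle in a context (via internals).
count_colour_set <- function(ctx, set) {
  as.numeric(bnsketch:::bdd_count(ctx$mgr, set, bnsketch:::ctx_param_bits(ctx)))
}

# Convenience: a tiny fully specified one-variable network x := <expr>.
one_var_psbn <- function(expr) {
  g <- influence_graph("x", data.frame(source = "x", target = "x"))
  new_psbn(g, updates = list(x = expr))
}

# The matrix of colours of a candidate set, one row per model (sorted
# rows for order-independent comparison).
candidate_colours <- function(cand) {
  ctx <- cand$ctx
  m <- bnsketch:::bdd_all_models(ctx$mgr, cand$colours, bnsketch:::ctx_param_bits(ctx))
  if (nrow(m) == 0) {
    return(m)
  }
  colnames(m) <- param_names(ctx$space)
  m[order(apply(m, 1, paste, collapse = "")), , drop = FALSE]
}

colour_list_matrix <- function(colours, pn) {
  if (length(colours) == 0) {
    return(matrix(0L, nrow = 0, ncol = length(pn)))
  }
  m <- do.call(rbind, lapply(colours, function(cl) as.integer(cl[pn])))
  colnames(m) <- pn
  m[order(apply(m, 1, paste, collapse = "")), , drop = FALSE]
}

# Mixed synthetic instance used by equivalence suites: rotates dynamic
# property kinds and keeps the parameter space enumerable.
random_small_sketch <- function(case, max_bits = 10) {
  kinds_pool <- list(
    "fixed_points", "time_series", c("fixed_points", "attractor_count"),
    c("fixed_points", "time_series"), "attractor_count"
  )
  kinds <- kinds_pool[[(case %% length(kinds_pool)) + 1]]
  for (attempt in 1:50) {
    spec <- synthetic_spec(
      n_vars = 2 + (case + attempt) %% 4,
      density = 0.45, hidden_fraction = 0.6, sign_prob = 0.4,
      n_observations = 1 + case %% 2,
      seed = case * 1000 + attempt
    )
    gen <- try(generate_sketch(spec, dynamic_kinds = kinds), silent = TRUE)
    if (inherits(gen, "try-error")) next
    bits <- build_parameter_space(gen$sketch$psbn)$total_bits
    if (bits <= max_bits) {
      return(gen)
    }
  }
  stop("could not draw a small enough synthetic sketch")
}
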
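# Thin R layer over the C++ decision-diagram kernel.  A "bdd" is an
# integer handle valid within one manager; handles are canonical, so
# identical handles <=> identical Boolean functions.

bdd_true <- 1L
bdd_false <- 0L

bdd_and <- function(m, f, g) bdd_apply(m, "and", f, g)
bdd_or <- function(m, f, g) bdd_apply(m, "or", f, g)
bdd_xor <- function(m, f, g) bdd_apply(m, "xor", f, g)
bdd_imp <- function(m, f, g) bdd_apply(m, "imp", f, g)
bdd_iff <- function(m, f, g) bdd_apply(m, "iff", f, g)

bdd_and_all <- function(m, fs) Reduce(function(a, b) bdd_and(m, a, b), fs, accumulate = FALSE, init = bdd_true)
bdd_or_all <- function(m, fs) Reduce(function(a, b) bdd_or(m, a, b), fs, accumulate = FALSE, init = bdd_false)

bdd_exists <- function(m, f, vars) bdd_quantify(m, f, as.integer(vars), TRUE)
bdd_forall <- function(m, f, vars) bdd_quantify(m, f, as.integer(vars), FALSE)

# Exact model count of `f` over the ordered variable set `vars` (0-based
# manager indices, strictly increasing).  Support of f must lie inside
# `vars`.  Returns a bigint (see bignum.R): candidate spaces routinely
# exceed 2^53.
bdd_count <- function(m, f, vars) {
  vars <- as.integer(vars)
  if (length(vars) && is.unsorted(vars, strictly = TRUE)) {
    stop("count variables must be strictly increasing")
  }
  sup <- bdd_support(m, f)
  if (!all(sup %in% vars)) {
    stop("BDD support is not contained in the counting variable set")
  }
  if (f == bdd_false) return(big_from_num(0))
  if (f == bdd_true) return(big_shift(big_from_num(1), length(vars)))
  nodes <- bdd_nodes(m, f)
  level <- match(nodes[, "var"], vars) - 1L # 0-based level of each node
  nlev <- length(vars)
  # models(node) counted over variables below the node's level; terminals
  # are handled inline with the level gap to the child.
  counts <- vector("list", nrow(nodes))
  child_count <- function(child, parent_level) {
    if (child == 0L) return(big_from_num(0))
    gap_from <- parent_level + 1L
    if (child == 1L) {
      return(big_shift(big_from_num(1), nlev - gap_from))
    }
    i <- match(child, nodes[, "id"])
    big_shift(counts[[i]], level[i] - gap_from)
  }
  for (i in seq_len(nrow(nodes))) {
    counts[[i]] <- big_add(
      child_count(nodes[i, "lo"], level[i]),
      child_count(nodes[i, "hi"], level[i])
    )
  }
  r <- match(f, nodes[, "id"])
  big_shift(counts[[r]], level[r])
}

# Draw `n` satisfying assignments of `f` over `vars`, i.i.d. uniform over
# the models.  Branch probabilities use double-precision ratios of the
# exact per-node counts, which is accurate to ~1e-15.  Returns a 0/1
# matrix with one column per variable in `vars`.
bdd_sample_models <- function(m, f, vars, n) {
  vars <- as.integer(vars)
  if (f == bdd_false) stop("cannot sample from an empty set")
  nlev <- length(vars)
  out <- matrix(0L, nrow = n, ncol = nlev)
  if (f == bdd_true || nlev == 0L) {
    if (nlev > 0L) out[] <- as.integer(stats::runif(n * nlev) < 0.5)
    return(out)
  }
  nodes <- bdd_nodes(m, f)
  level <- match(nodes[, "var"], vars) - 1L
  counts <- numeric(nrow(nodes)) # double approximations of model counts
  child_weight <- function(child, parent_level) {
    if (child == 0L) return(0)
    gap <- if (child == 1L) nlev - parent_level - 1L else {
      i <- match(child, nodes[, "id"])
      level[i] - parent_level - 1L
    }
    base <- if (child == 1L) 1 else counts[match(child, nodes[, "id"])]
    base * 2^gap
  }
  for (i in seq_len(nrow(nodes))) {
    counts[i] <- child_weight(nodes[i, "lo"], level[i]) +
      child_weight(nodes[i, "hi"], level[i])
  }
  for (s in seq_len(n)) {
    node <- f
    lev <- 0L
    row <- integer(nlev)
    while (lev < nlev) {
      if (node == 1L) { # free variables below: uniform bits
        row[(lev + 1L):nlev] <- as.integer(stats::runif(nlev - lev) < 0.5)
        lev <- nlev
        break
      }
      i <- match(node, nodes[, "id"])
      nl <- level[i]
      if (lev < nl) { # skipped levels are unconstrained
        row[(lev + 1L):nl] <- as.integer(stats::runif(nl - lev) < 0.5)
        lev <- nl
      }
      w_hi <- child_weight(nodes[i, "hi"], nl)
      w_lo <- child_weight(nodes[i, "lo"], nl)
      take_hi <- stats::runif(1) < w_hi / (w_hi + w_lo)
      row[lev + 1L] <- as.integer(take_hi)
      node <- if (take_hi) nodes[i, "hi"] else nodes[i, "lo"]
      lev <- lev + 1L
    }
    out[s, ] <- row
  }
  out
}

# All satisfying assignments over `vars` as a 0/1 matrix (guard: intended
# for small sets; callers enforce enumeration limits).
bdd_all_models <- function(m, f, vars) {
  vars <- as.integer(vars)
  nlev <- length(vars)
  if (f == bdd_false) return(matrix(0L, nrow = 0, ncol = nlev))
  acc <- list()
  rec <- function(node, lev, prefix) {
    if (node == 0L) return(invisible(NULL))
    if (lev == nlev) {
      acc[[length(acc) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    v <- vars[lev + 1L]
    nv <- if (node >= 2L) bdd_node_var(m, node) else NA_integer_
    if (node == 1L || nv != v) {
      for (b in 0:1) rec(node, lev + 1L, c(prefix, b))
    } else {
      rec(bdd_node_child(m, node, FALSE), lev + 1L, c(prefix, 0L))
      rec(bdd_node_child(m, node, TRUE), lev + 1L, c(prefix, 1L))
    }
  }
  rec(f, 0L, integer(0))
  do.call(rbind, acc)
}
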
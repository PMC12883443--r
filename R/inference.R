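# Inference orchestration: intersect the full colour space with every
# static and dynamic constraint, then count, sample, and summarize the
# surviving candidate set.

#' Run sketch inference
#'
#' Computes the symbolic set of all colours (interpretations of the
#' function symbols) whose induced Boolean network satisfies every
#' constraint of the sketch: the sign/essentiality flags on regulations,
#' the explicit static properties, and the dynamic (HCTL) properties in
#' declaration order.  The report records the exact candidate count after
#' every stage.
#'
#' @param sketch a [new_sketch()] object (validation errors abort).
#' @param arity_cap passed to [build_parameter_space()].
#' @param summarize also compute per-variable update-function variant
#'   counts for the report (see [summarize_variants()]).
#' @return list with `candidates` (a `candidate_set`) and `report` (an
#'   `inference_report`).
#' @examples
#' g <- influence_graph("x", data.frame(source = "x", target = "x"))
#' sk <- new_sketch(new_psbn(g)) # update of x defaults to g_x(x)
#' run_inference(sk)$report$counts$final # 4 interpretations, unconstrained
#' @export
run_inference <- function(sketch, arity_cap = 16L, summarize = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  issues <- validate_sketch(sketch)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop(
      "sketch has validation errors:\n",
      paste(sprintf("  [%s] %s", errs$element, errs$message), collapse = "\n")
    )
  }

  # size the context for the largest dynamic formula
  formulas <- lapply(sketch$dynamic_properties, function(p) {
    tryCatch(build_template(p, sketch$datasets),
      error = function(e) stop(sprintf("property '%s': %s", p$id, conditionMessage(e)))
    )
  })
  n_copies <- if (length(formulas)) {
    max(vapply(formulas, function(f) length(hctl_state_vars(f)), 0L))
  } else {
    0L
  }
  ctx <- new_context(sketch$psbn, n_state_vars = n_copies, arity_cap = arity_cap)
  pbits <- ctx_param_bits(ctx)
  count_now <- function(set) bdd_count(ctx$mgr, set, pbits)

  cand <- bdd_true
  provenance <- character(0)
  counts <- list(initial = count_now(cand))

  # regulation flags act as implicit static constraints
  regs <- sketch$psbn$graph$regulations
  for (i in seq_len(nrow(regs))) {
    if (regs$sign[i] != "unknown") {
      cand <- bdd_and(ctx$mgr, cand, monotonicity_of_regulation(
        ctx, regs$source[i], regs$target[i], regs$sign[i]
      ))
      provenance <- c(provenance, sprintf("regulation_sign:%s->%s", regs$source[i], regs$target[i]))
    }
    if (regs$essential[i] == "true") {
      cand <- bdd_and(ctx$mgr, cand, essentiality_of_regulation(
        ctx, regs$source[i], regs$target[i]
      ))
      provenance <- c(provenance, sprintf("regulation_essential:%s->%s", regs$source[i], regs$target[i]))
    }
  }
  for (p in sketch$static_properties) {
    set <- tryCatch(compile_static_property(ctx, p),
      error = function(e) stop(sprintf("property '%s': %s", p$id, conditionMessage(e)))
    )
    cand <- bdd_and(ctx$mgr, cand, set)
    provenance <- c(provenance, p$id)
  }
  counts$after_static <- count_now(cand)

  counts$after_dynamic <- list()
  for (i in seq_along(sketch$dynamic_properties)) {
    p <- sketch$dynamic_properties[[i]]
    if (cand != bdd_false) { # early emptiness: nothing left to restrict
      res <- tryCatch(hctl_check(ctx, formulas[[i]]),
        error = function(e) stop(sprintf("property '%s': %s", p$id, conditionMessage(e)))
      )
      sup <- bdd_support(ctx$mgr, res)
      if (p$kind == "hctl" && length(intersect(sup, ctx_state_bits(ctx)))) {
        warning(sprintf(
          "property '%s': result depends on the current state; applying the universal-over-states convention",
          p$id
        ))
      }
      col <- bdd_forall(ctx$mgr, res, ctx_state_bits(ctx))
      cand <- bdd_and(ctx$mgr, cand, col)
    }
    provenance <- c(provenance, p$id)
    counts$after_dynamic[[p$id]] <- count_now(cand)
  }
  counts$final <- count_now(cand)

  candidates <- structure(
    list(
      ctx = ctx, colours = cand, provenance = provenance,
      signature = space_signature(sketch$psbn, ctx$space)
    ),
    class = "candidate_set"
  )
  variants <- if (summarize) summarize_variants(candidates) else NULL
  report <- structure(
    list(
      counts = counts, variants = variants,
      n_properties = length(provenance),
      elapsed_s = proc.time()[["elapsed"]] - t0
    ),
    class = "inference_report"
  )
  list(candidates = candidates, report = report)
}

space_signature <- function(psbn, space) {
  list(
    variables = sort(psbn$graph$variables),
    symbols = space$symbols[, c("name", "arity")]
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "Candidate set: %s consistent interpretations over %d parameter bits (%d properties applied)\n",
    as.character(count_candidates(x)), x$ctx$space$total_bits,
    length(x$provenance)
  ))
  invisible(x)
}

#' @export
print.inference_report <- function(x, ...) {
  cat("Inference report\n")
  cat("  consistent with PSBN: ", as.character(x$counts$initial), "\n", sep = "")
  cat("  after static properties: ", as.character(x$counts$after_static), "\n", sep = "")
  for (id in names(x$counts$after_dynamic)) {
    cat(sprintf("  after %s: %s\n", id, as.character(x$counts$after_dynamic[[id]])))
  }
  cat("  final: ", as.character(x$counts$final), "\n", sep = "")
  if (!is.null(x$variants)) {
    cat("  update-function variants per variable:\n")
    for (v in names(x$variants)) {
      cat(sprintf("    %s: %s\n", v, format(x$variants[[v]])))
    }
  }
  cat(sprintf("  elapsed: %.2f s\n", x$elapsed_s))
  invisible(x)
}

#' Exact candidate count
#'
#' Exact number of interpretations (parameter valuations) in the set, as
#' an arbitrary-precision integer: candidate spaces routinely exceed
#' `2^53`.
#'
#' @param set a `candidate_set` from [run_inference()] or
#'   [import_candidate_set()].
#' @return a `bigint`; compare with `==`, or convert with
#'   [as.character()] / [as.numeric()].
#' @export
count_candidates <- function(set) {
  bdd_count(set$ctx$mgr, set$colours, ctx_param_bits(set$ctx))
}

#' Uniformly sample concrete candidate networks
#'
#' Draws colours i.i.d. uniformly over the models of the symbolic set
#' (weighted descent by per-node model counts) and instantiates each into
#' a concrete Boolean network.  Reproducible for a fixed seed.
#'
#' @param set a nonempty `candidate_set`.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return list of `n` `concrete_bn` objects (the sampled colour is in
#'   `$colour`).
#' @export
sample_candidates <- function(set, n, seed = 1L) {
  if (set$colours == bdd_false) stop("no candidates: the set is empty")
  stopifnot(n >= 1)
  set.seed(seed)
  pbits <- ctx_param_bits(set$ctx)
  draws <- bdd_sample_models(set$ctx$mgr, set$colours, pbits, n)
  pn <- param_names(set$ctx$space)
  lapply(seq_len(n), function(i) {
    instantiate_in_ctx(set$ctx, stats::setNames(draws[i, ], pn))
  })
}

#' Per-variable update-function variant counts
#'
#' For each variable, the number of distinct instantiated truth tables
#' its update function takes across the candidate set.  Computed by
#' recursively partitioning the set on the row functions
#' `F_v(row, colour)`; variables whose update depends on more than
#' `cap_bits` parameter bits (or with more than `2^cap_bits` table rows)
#' are reported as `NA` rather than failing.
#'
#' @param set a `candidate_set`.
#' @param cap_bits per-variable tractability cap (default 20).
#' @return named numeric vector: variant count per variable (`NA` where
#'   capped); 0 everywhere when the set is empty.
#' @export
summarize_variants <- function(set, cap_bits = 20L) {
  ctx <- set$ctx
  m <- ctx$mgr
  pbits <- ctx_param_bits(ctx)
  out <- stats::setNames(numeric(length(ctx$vars)), ctx$vars)
  for (v in ctx$vars) {
    relevant <- intersect(bdd_support(m, ctx$fun[[v]]), pbits)
    regs <- regulators_of(ctx$psbn$graph, v)
    k <- length(regs)
    if (length(relevant) > cap_bits || k > cap_bits) {
      out[v] <- NA_real_
      next
    }
    rows <- lapply(seq_len(2L^k) - 1L, function(r) {
      w <- row_word(r, k)
      f <- ctx$fun[[v]]
      for (j in seq_len(k)) f <- bdd_restrict(m, f, ctx$state_pos[[regs[j]]], w[j])
      f
    })
    count_distinct <- function(s, i) {
      if (s == bdd_false) return(0)
      if (i > length(rows)) return(1)
      count_distinct(bdd_and(m, s, rows[[i]]), i + 1L) +
        count_distinct(bdd_and(m, s, bdd_not(m, rows[[i]])), i + 1L)
    }
    out[v] <- count_distinct(set$colours, 1L)
  }
  out
}

## ---- candidate-set container ----------------------------------------------

CANDIDATE_SET_FORMAT <- "bnsketch-candidate-set/1"

#' Export / import the symbolic candidate set
#'
#' Writes the candidate set as a self-contained JSON container: the PSBN,
#' the parameter-space ordering, and the decision diagram (shared-node
#' table).  The round trip is lossless: identical model count and
#' membership.  Import verifies the recorded parameter ordering against
#' the PSBN it rebuilds and refuses mismatches rather than silently
#' misinterpreting bits.
#'
#' @param set a `candidate_set`.
#' @param path file path.
#' @return `import_candidate_set()` returns a `candidate_set`;
#'   `export_candidate_set()` returns `path` invisibly.
#' @export
export_candidate_set <- function(set, path) {
  ctx <- set$ctx
  pbits <- ctx_param_bits(ctx)
  nodes <- if (set$colours >= 2L) bdd_nodes(ctx$mgr, set$colours) else {
    matrix(integer(0), ncol = 4, dimnames = list(NULL, c("id", "var", "lo", "hi")))
  }
  # remap: vars to 0-based parameter indices, ids to dense 2..(n+1)
  id_map <- stats::setNames(seq_len(nrow(nodes)) + 1L, nodes[, "id"])
  remap <- function(x) ifelse(x < 2L, x, id_map[as.character(x)])
  doc <- list(
    format = CANDIDATE_SET_FORMAT,
    psbn = psbn_to_list(ctx$psbn),
    param_names = param_names(ctx$space),
    provenance = set$provenance,
    root = unname(remap(set$colours)),
    nodes = if (nrow(nodes)) {
      cbind(
        var = match(nodes[, "var"], pbits) - 1L,
        lo = unname(remap(nodes[, "lo"])),
        hi = unname(remap(nodes[, "hi"]))
      )
    } else {
      matrix(integer(0), ncol = 3)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_candidate_set
#' @export
import_candidate_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, CANDIDATE_SET_FORMAT)) {
    stop(sprintf(
      "unsupported candidate-set container format '%s'",
      doc$format %||% "<missing>"
    ))
  }
  psbn <- psbn_from_list(doc$psbn)
  ctx <- new_context(psbn)
  stored <- as.character(unlist(doc$param_names))
  rebuilt <- param_names(ctx$space)
  if (!identical(stored, rebuilt)) {
    stop("parameter-space ordering in the file does not match the PSBN; refusing to import")
  }
  pbits <- ctx_param_bits(ctx)
  nodes <- matrix(as.integer(unlist(doc$nodes)), ncol = 3, byrow = TRUE)
  handles <- c(bdd_false, bdd_true)
  for (i in seq_len(nrow(nodes))) {
    vpos <- pbits[nodes[i, 1] + 1L]
    lo <- handles[nodes[i, 2] + 1L]
    hi <- handles[nodes[i, 3] + 1L]
    handles <- c(handles, bdd_ite(ctx$mgr, bdd_v(ctx$mgr, vpos), hi, lo))
  }
  root <- handles[doc$root + 1L]
  structure(
    list(
      ctx = ctx, colours = root,
      provenance = as.character(doc$provenance %||% character(0)),
      signature = space_signature(psbn, ctx$space)
    ),
    class = "candidate_set"
  )
}
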
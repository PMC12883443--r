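# Minimal arbitrary-precision non-negative integers.  Candidate counts
# scale as products of 2^(2^arity) table sizes and overflow doubles well
# before realistic model sizes are reached, so exact counting needs more
# than 53 bits.  Representation: little-endian numeric vector of base-1e9
# digits, class "bigint".

BIG_BASE <- 1e9

big_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1, x >= 0, x == floor(x), x < 2^53)
  digits <- numeric(0)
  repeat {
    digits <- c(digits, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
    if (x == 0) break
  }
  structure(digits, class = "bigint")
}

big_norm <- function(d) {
  carry <- 0
  for (i in seq_along(d)) {
    d[i] <- d[i] + carry
    carry <- floor(d[i] / BIG_BASE)
    d[i] <- d[i] - carry * BIG_BASE
  }
  while (carry > 0) {
    d <- c(d, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  structure(d, class = "bigint")
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(unclass(a), numeric(n - length(a))) +
    c(unclass(b), numeric(n - length(b))))
}

# a * 2^k via repeated multiply-by-small-power; k may be large (parameter
# spaces have one bit per truth-table row).
big_shift <- function(a, k) {
  stopifnot(k >= 0)
  d <- unclass(a)
  while (k > 0) {
    step <- min(k, 20L) # 2^20 * (1e9-1) stays well inside double precision
    d <- unclass(big_norm(d * 2^step))
    k <- k - step
  }
  structure(d, class = "bigint")
}

big_eq_num <- function(a, x) {
  xs <- big_from_num(x)
  length(a) == length(xs) && all(unclass(a) == unclass(xs))
}

big_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

#' @export
as.character.bigint <- function(x, ...) {
  d <- rev(unclass(x))
  paste0(
    format(d[1], scientific = FALSE, trim = TRUE),
    paste(sprintf("%09.0f", d[-1]), collapse = "")
  )
}

#' @export
as.numeric.bigint <- function(x, ...) {
  sum(unclass(x) * BIG_BASE^(seq_along(x) - 1))
}

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
Ops.bigint <- function(e1, e2) {
  if (!.Generic %in% c("==", "!=", "<", ">", "<=", ">=", "+")) {
    stop("operation '", .Generic, "' not supported for bigint")
  }
  to_big <- function(e) if (inherits(e, "bigint")) e else big_from_num(e)
  a <- to_big(e1)
  b <- to_big(e2)
  if (.Generic == "+") return(big_add(a, b))
  cmp <- big_cmp(a, b)
  switch(.Generic,
    "==" = cmp == 0L, "!=" = cmp != 0L, "<" = cmp < 0L,
    ">" = cmp > 0L, "<=" = cmp <= 0L, ">=" = cmp >= 0L
  )
}
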
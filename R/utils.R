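#' @useDynLib polypvit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils modifyList write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library code never perturbs user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-item sub-seed from a master seed
#'
#' Deterministic counter-based stream splitting: each item's seed depends only
#' on (master, counter), so generating item k is independent of generation
#' order.  Result is kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer item counter.
#' @return integer seed.
#' @export
derive_seed <- function(master, counter) {
  m <- as.double(master) %% 2147483647
  as.integer((((m %% 50021) + 1) * 69621 + (as.double(counter) %% 65521) * 7919 + counter) %% 2147483647)
}

stop_config <- function(msg, ...) {
  stop(structure(class = c("polypvit_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("polypvit_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

assert_that <- function(ok, msg, ...) if (!isTRUE(ok)) stop_config(msg, ...)

# Map a function over two parallel nested lists of numeric arrays (params and
# gradients share one skeleton).
nested_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nested_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

nested_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nested_map(f, a[[i]])
    out
  } else f(a)
}

# Zero-filled copy of a nested parameter list.
nested_zeros <- function(a) nested_map(function(x) {
  z <- x
  z[] <- 0
  z
}, a)

# Elementwise a + b over a nested list skeleton.
nested_add <- function(a, b) nested_map2(`+`, a, b)

nested_scale <- function(a, s) nested_map(function(x) x * s, a)

# Flatten the leaves of a nested list (used by the optimizer and tests).
nested_leaves <- function(a, prefix = "") {
  if (!is.list(a)) return(setNames(list(a), prefix))
  out <- list()
  for (i in seq_along(a)) {
    nm <- names(a)[i] %||% as.character(i)
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    out <- c(out, nested_leaves(a[[i]], key))
  }
  out
}

# Separable box blur of a matrix (edge-replicated), n passes; used by the
# synthetic renderer for soft boundaries and low-frequency texture.
box_blur <- function(m, passes = 1L) {
  for (p in seq_len(passes)) {
    up <- m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
    dn <- m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), , drop = FALSE]
    m <- (up + m + dn) / 3
    lf <- m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
    rt <- m[, c(seq_len(ncol(m) - 1) + 1, ncol(m)), drop = FALSE]
    m <- (lf + m + rt) / 3
  }
  m
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
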
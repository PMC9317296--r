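# Seed plumbing and small shared helpers.

.datatable.aware <- TRUE
#
# All randomness in the package flows from one root seed through named
# substreams, so each pipeline stage is reproducible in isolation and
# insensitive to the order in which other stages run.

#' Derive a substream seed from a root seed and a stream name
#'
#' Deterministic hash of `(seed, name)` into a valid 32-bit seed. Used so
#' that each simulation stage (and each GRN target) owns an independent,
#' reproducible random stream.
#'
#' @param seed integer root seed.
#' @param name character scalar naming the substream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 2654435 + h) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# fraction validator
check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 at random.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
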
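# Internal helpers: seeded RNG scoping and seed derivation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.  `seed = NULL` evaluates without seeding.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a root seed
#'
#' Mixes a root integer with a polynomial hash of a stream name so each
#' pipeline stage draws from its own reproducible stream.  Result is always
#' in `[1, 2^31 - 2]`.
#' @noRd
derive_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  mod <- 2147483647           # 2^31 - 1, prime
  h <- root %% mod
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% mod
  as.integer(max(1, h %% (mod - 1)))
}

# x * log(x) with the 0 * log(0) = 0 convention, vectorized
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- x[pos] * log(x[pos])
  out[is.na(x)] <- NA_real_
  dim(out) <- dim(x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
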
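# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that generators are pure
#' functions of (parameters, seed) without perturbing the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage / per-replicate seed derivation. Knuth-style
# multiplicative hash keeps derived seeds < 2^31 and decorrelated, and a
# stage's seed does not depend on which other stages run.
derive_seed <- function(master, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(master) * 2654435761 + h * 97 + 12345) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

# Dirichlet draws (rows sum to 1); used for noisy copy-profile generation.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

is_autosome <- function(chrom) {
  core <- sub("^[Cc]hr", "", as.character(chrom))
  core %in% as.character(1:22)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
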
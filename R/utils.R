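# Internal helpers: seeded evaluation and identifier keys.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded operations never perturb the global random stream.  A
#' `NULL` seed evaluates `expr` with the current stream.
#'
#' @param seed Integer scalar or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive a reproducible sub-seed (kept under 2^31) from a master seed.
derive_seed <- function(seed, step) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + step * 104729) %% 2147483629)
}

# Stable identifier for a stimulus pair.
pair_key <- function(set_id, pair_id) paste(set_id, pair_id, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop0 <- function(...) stop(..., call. = FALSE)
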
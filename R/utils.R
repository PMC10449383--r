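# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generator calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fmt("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_fmt("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_fmt("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Total length of the intersection of interval [a1, a2) with [b1, b2).
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}
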
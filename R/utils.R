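# Internal helpers: argument checks, seeded evaluation, small numerics.

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_scalar_num <- function(x, name, lower = -Inf, strict = FALSE,
                             allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x)))
    stop_domain("'%s' must be a single finite number", name)
  if (strict && x <= lower)
    stop_domain("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict && x < lower)
    stop_domain("'%s' must be >= %g (got %g)", name, lower, x)
  invisible(x)
}

check_num_vec <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x))
    stop_domain("'%s' must be a non-empty numeric vector without NAs", name)
  if (any(x < lower))
    stop_domain("'%s' must be >= %g (offending value %g)", name, lower,
                min(x))
  invisible(x)
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this, so one
# top-level seed determines every draw.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar_num(seed, "seed")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, keeping the
# result a valid 32-bit R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1009) %% 2147483647)
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
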
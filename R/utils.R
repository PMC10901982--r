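# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a master seed, keeping the result
# a valid 32-bit integer.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + stream * 1013) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

# Cheap deterministic content hash (polynomial rolling hash over the
# deparsed object, mod a Mersenne prime) to stamp result bundles.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
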
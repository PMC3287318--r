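# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so simulations never perturb user code.
# seed = NULL means "use the current stream" (non-reproducible).
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for the k-th component of a multi-part computation.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 999983 * as.numeric(k)) %% 2147483647)
}

# Round half away from zero (commercial rounding), the convention used for
# the report tables; base round() rounds half to even.
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
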
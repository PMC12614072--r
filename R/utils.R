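# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so seeded internals never perturb the session stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Member seeds stay valid 32-bit integers for any master seed.
member_seed <- function(seed, m) {
  as.integer((as.numeric(seed) + m) %% (.Machine$integer.max - 1L)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
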
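# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce a numeric matrix/vector to complex storage without copying semantics
# the caller cares about; complex input is returned as-is.
as_complex <- function(x) {
  if (is.complex(x)) return(x)
  storage.mode(x) <- "complex"
  x
}

# Strip an exactly-zero imaginary part (real inputs processed in complex
# arithmetic keep Im == 0 bit-for-bit; we hand back real storage then).
maybe_real <- function(x, inputs_real) {
  if (inputs_real && all(Im(x) == 0)) Re(x) else x
}

frob <- function(x) sqrt(sum(abs(x)^2))

stopifnot_matrix2d <- function(x, what = "input") {
  if (!is.matrix(x)) stop(sprintf("%s must be a 2D matrix", what))
}
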
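# internal helpers shared across modules

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
# Generators take an explicit seed so identical arguments give identical output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# derive reproducible sub-seeds for the components of a compound generator
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
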
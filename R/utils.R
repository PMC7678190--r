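# Internal helpers shared across the package.

# Run code() under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no save/restore).
.withSeed <- function(seed, code) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed))) return(code())
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code()
}

.assertScalarNumber <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a single finite number", call. = FALSE)
  invisible(x)
}
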
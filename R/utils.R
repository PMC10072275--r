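# internal helpers

# evaluate expr with a temporary RNG seed, restoring global state after
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a stream-specific 32-bit sub-seed from a master seed
subSeed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}
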
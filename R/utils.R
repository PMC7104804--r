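# Seeded-RNG helpers.  Training uses several independent streams
# (initialization, shuffling, dropout, augmentation) so that e.g. data
# order can be varied without disturbing weight initialization.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# A resumable RNG stream: evaluates `fn()` under the stream's own
# generator state without disturbing the global stream.
new_rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- NULL
  class(e) <- "rng_stream"
  e
}

stream_eval <- function(stream, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(stream$state)) set.seed(stream$seed)
  else assign(".Random.seed", stream$state, envir = globalenv())
  val <- fn()
  stream$state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  val
}

# Derive a child seed from (seed, index), kept inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 65011 + 1) * 31907 + index) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
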
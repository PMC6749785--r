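#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with a stream label into a new integer seed,
#' so that every randomised stage of the pipeline (textures, leaves, cohort,
#' sessions, bootstrap) draws from its own deterministic substream. Any single
#' stage can then be re-run in isolation from the master seed and its label.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the stream (e.g. `"texture/flat/3"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master %% m)
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% m
  }
  # one multiplicative scramble so labels differing in a final digit diverge
  as.integer((h * 48271) %% m)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Independent RNG stream: a closure that swaps its own .Random.seed in and out
# around each draw, so interleaved streams do not perturb one another.
rng_stream <- function(seed) {
  state <- with_seed(seed, {
    runif(1) # advance once so state exists
    get(".Random.seed", envir = globalenv())
  })
  draw <- function(f) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) outer_state <- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", state, envir = globalenv())
    out <- f()
    state <<- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", outer_state, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    out
  }
  draw
}
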
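# A private RNG stream. Each search owns one; draws never disturb the
# caller's .Random.seed, and a fixed seed gives a reproducible run.

rng_new <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "ucurve_rng"
  e
}

rng_eval <- function(rng, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

# one integer in 1..n
rng_int <- function(rng, n) {
  rng_eval(rng, function() sample.int(n, 1L))
}

rng_shuffle <- function(rng, x) {
  if (length(x) <= 1L) return(x)
  rng_eval(rng, function() x[sample.int(length(x))])
}

rng_runif <- function(rng, n = 1L) {
  rng_eval(rng, function() stats::runif(n))
}

# n draws, each uniform on {0, 1, ..., max}
rng_uint <- function(rng, n, max) {
  rng_eval(rng, function() sample.int(max + 1L, n, replace = TRUE) - 1L)
}

# deterministic child seed (kept below 2^31) for nested searches
rng_child_seed <- function(seed, key) {
  ((as.double(seed) %% 65011) * 32749 + (as.double(key) %% 2147483647) + 97) %%
    2147483647
}
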
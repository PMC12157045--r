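# Seed handling: every sampling entry point takes an explicit seed and leaves
# the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# deterministic sub-stream seeds, kept below 2^31 - 1
derive_seed <- function(seed, ...) {
  k <- as.numeric(seed) %% 2147483647
  for (x in c(...)) k <- (k * 69069 + as.numeric(x) * 2654435 + 1) %% 2147483647
  as.integer(k)
}
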
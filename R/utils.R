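# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# global .Random.seed is untouched. seed = NULL means "use ambient RNG".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed for stage `k` of a run keyed by `seed`.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(k) * 104729) %% 2147483647L)
}

# Draw one 31-bit integer to hand to the compiled PCG stream.
pcg_seed <- function(seed) {
  with_seed(seed, sample.int(2147483646L, 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
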
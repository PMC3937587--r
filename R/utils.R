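# Internal helpers: deterministic seed derivation and small checks.

# Derive a child seed from a parent seed and integer tags. Linear mixing kept
# exact in double precision (products stay far below 2^53) and reduced modulo
# 2^31 - 1 so the result is always a valid R integer seed.
mix_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (v in c(...)) {
    h <- (h * 69069 + as.double(v) + 1) %% m
  }
  as.integer(h)
}

as_group <- function(x) {
  if (is.factor(x)) {
    stopifnot(identical(levels(x), GROUP_LEVELS))
    return(x)
  }
  if (is.numeric(x)) x <- GROUP_LEVELS[x]
  factor(x, levels = GROUP_LEVELS)
}

group_int <- function(g) as.integer(as_group(g))

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("mc_degenerate", "error")))
}
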
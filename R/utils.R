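# Internal helpers shared across modules.

# Derive a child seed from a base seed and a stream of integer counters.
# Splitmix-style integer hash, kept inside [0, 2^31 - 1] so it is always a
# valid R integer seed on every platform.
derive_seed <- function(seed, ...) {
  ctr <- c(seed, ...)
  h <- 0
  for (x in ctr) {
    h <- (h * 2654435761 + (x + 1) * 40503) %% 2147483647
  }
  as.integer(h)
}

# Sample skewness m3 / m2^(3/2); 0 for constant input.
sample_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Shannon entropy of a probability vector, 0 log 0 := 0, natural log.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log(p))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
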
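## Seed plumbing: all randomness in the package flows from one integer seed.
## Each stochastic operation derives a child seed from (seed, tag) so that
## stages are reproducible independently of evaluation order.

child_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

with_child_seed <- function(seed, tag, code) {
  withr::with_seed(child_seed(seed, tag), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
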
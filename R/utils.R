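# Internal helpers shared across modules.

# Gene symbols are compared case-insensitively and stored upper-case
# (HGNC convention); surrounding whitespace is stripped.
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Locale-independent lexicographic sort (C collation via radix method),
# so node indexing and tie-breaks do not depend on the session locale.
sort_c <- function(x) sort(x, method = "radix")

# Derive a per-stage RNG seed from the run seed and a stage label, so each
# pipeline stage consumes an independent, individually reproducible
# substream. Small polynomial string hash folded into [1, 2^31 - 2].
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 7919) %% 2147483646 + 1)
}

# Fractional (average) ranks, ascending or descending.
frank <- function(x, descending = FALSE) {
  if (descending) rank(-x, ties.method = "average") else rank(x, ties.method = "average")
}

# sample() without the length-1 surprise
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
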
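# Shared fixture builders. Everything is generated in code; indices are
# 1-based throughout.

store_from <- function(...) as_exemplar_store(rbind(...))

# A pure bijective store: meaning m maps to signal perm[m] with `tokens`
# exemplars and nothing else.
pure_store <- function(perm, tokens = 3L) {
  n <- length(perm)
  counts <- matrix(0L, n, n)
  counts[cbind(seq_len(n), perm)] <- as.integer(tokens)
  as_exemplar_store(counts)
}

pure_agent <- function(id, perm, tokens = 3L) {
  signaling_agent(id, pure_store(perm, tokens))
}

random_store <- function(n_meanings = 4L, n_signals = 4L, max_count = 5L) {
  as_exemplar_store(matrix(sample.int(max_count + 1L,
                                      n_meanings * n_signals,
                                      replace = TRUE) - 1L,
                           n_meanings, n_signals))
}

basic_mcfg <- function(...) {
  mechanism_config("referential_feedback", ...)
}

# Agents sharing the one-exemplar-per-pair store.
uniform_agents <- function(n = 2L, nm = 5L, ns = 5L) {
  lapply(seq_len(n), function(k) {
    signaling_agent(k, exemplar_store(nm, ns, "one_per_pair"))
  })
}
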
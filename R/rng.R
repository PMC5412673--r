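# Shared random-draw discipline.
#
# Every stochastic operator in the package consumes draws from R's global RNG
# stream through exactly one of the three helpers below. The compiled engine
# (src/engine.cpp) re-implements the same helpers on top of unif_rand(), with
# long-double accumulation mirroring R's sum()/cumsum(), so that a fixed seed
# yields bit-identical trajectories under the R and C++ engines:
#
#   unif_index(n)        -- one uniform; index in 1..n
#   invcdf_normalized(w) -- one uniform; inverse-CDF draw from a normalized
#                           weight vector (cumsum left-to-right, first >= u)
#   invcdf_raw(w)        -- one uniform scaled by sum(w); used for draws over
#                           raw token counts (inhibition, memory deletion)
#
# Draw order within one interaction (engines must agree):
#   1. pairing   (closed: one edge draw; gradual: partner draw [+ role draw])
#   2. context   (only when c < |M|: partial Fisher-Yates, c draws)
#   3. topic     (one normalized inverse-CDF draw over dist restricted to C)
#   4. utterance (one draw: stochastic inverse-CDF or WTA tie-break)
#   5. interpretation (one draw, as above)
#   6. updates, speaker phase then hearer phase; per learning-enabled agent:
#      punishment (no draws), add, anti-homonymy pass (one draw iff minimal
#      with competitors), anti-synonymy pass (same), memory limit (one draw
#      iff the store overflows).
# Agents whose learning is disabled skip their phase entirely (no draws).

unif_index <- function(n) {
  k <- floor(stats::runif(1L) * n) + 1
  if (k > n) k <- n
  as.integer(k)
}

invcdf_normalized <- function(w) {
  u <- stats::runif(1L)
  cs <- cumsum(w)
  p <- which(cs >= u)
  if (length(p) > 0L) p[[1L]] else max(which(w > 0))
}

invcdf_raw <- function(w) {
  w <- as.numeric(w)
  u <- stats::runif(1L) * sum(w)
  cs <- cumsum(w)
  p <- which(cs >= u)
  if (length(p) > 0L) p[[1L]] else max(which(w > 0))
}

# Winner-take-all tie tolerance shared by both engines.
WTA_TOL <- 1e-12
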
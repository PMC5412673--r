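#' Production weights for a topic meaning
#'
#' Computes the normalized weight of each signal for producing the given
#' topic. Under standard weighting the weight of signal `s` is the proportion
#' of the topic urn's tokens carrying `s`. Under obverter weighting the
#' speaker instead asks which signal a standard hearer would most likely map
#' back to the topic: the weight of `s` is the topic's share of all tokens
#' carrying `s` (the standard reception weight with the full meaning set as
#' context), renormalized over signals.
#'
#' If no token supports any signal (an empty urn under standard weighting, or
#' all candidate weights zero under obverter weighting), the uniform
#' distribution over all signals is returned. This innovation fallback is
#' what lets empty-initialized agents coin signals for unseen meanings within
#' a fixed signal inventory.
#'
#' @param store An [exemplar_store()].
#' @param topic Meaning index (1-based).
#' @param weighting `"standard"` or `"obverter"`.
#' @return A `weight_vector` over all signals: a numeric vector of
#'   non-negative entries summing to 1, with attribute `index` giving the
#'   signal index of each entry.
#' @examples
#' st <- as_exemplar_store(rbind(c(2, 3), c(0, 0)))
#' production_weights(st, 1)  # 0.4, 0.6
#' @export
production_weights <- function(store, topic,
                               weighting = c("standard", "obverter")) {
  weighting <- match.arg(weighting)
  check_indices(store, m = topic)
  counts <- store$counts
  ns <- ncol(counts)
  if (weighting == "standard") {
    w <- as.numeric(counts[topic, ])
    tot <- sum(w)
    w <- if (tot > 0) w / tot else rep(1 / ns, ns)
  } else {
    cs <- colSums(counts)
    w <- counts[topic, ] / cs
    w[cs == 0] <- 0
    tot <- sum(w)
    w <- if (tot > 0) w / tot else rep(1 / ns, ns)
  }
  new_weight_vector(w, index = seq_len(ns), domain = "signal")
}

#' Reception weights for an utterance in context
#'
#' Computes the normalized weight of each context meaning as the
#' interpretation of a received utterance. Under standard weighting the
#' weight of meaning `m` is its share of the utterance's tokens among context
#' meanings. Under obverter weighting the hearer asks which context meaning a
#' standard speaker would most likely have produced the utterance for: the
#' weight of `m` is the utterance's share of `m`'s row tokens (the standard
#' production weight), renormalized over the context.
#'
#' An utterance supported by no token in any context meaning yields the
#' uniform distribution over the context.
#'
#' @inheritParams production_weights
#' @param utterance Signal index (1-based).
#' @param context Non-empty integer vector of meaning indices.
#' @return A `weight_vector` over the context meanings (attribute `index`
#'   maps entries back to meaning indices).
#' @export
reception_weights <- function(store, utterance, context,
                              weighting = c("standard", "obverter")) {
  weighting <- match.arg(weighting)
  check_indices(store, s = utterance)
  if (length(context) < 1L) {
    stop("`context` must be a non-empty set of meaning indices.",
         call. = FALSE)
  }
  context <- as.integer(context)
  if (any(context < 1L | context > nrow(store$counts))) {
    stop("context meaning index out of range.", call. = FALSE)
  }
  counts <- store$counts
  k <- length(context)
  if (weighting == "standard") {
    w <- as.numeric(counts[context, utterance])
    tot <- sum(w)
    w <- if (tot > 0) w / tot else rep(1 / k, k)
  } else {
    rs <- rowSums(counts)[context]
    w <- counts[context, utterance] / rs
    w[rs == 0] <- 0
    tot <- sum(w)
    w <- if (tot > 0) w / tot else rep(1 / k, k)
  }
  new_weight_vector(w, index = context, domain = "meaning")
}

new_weight_vector <- function(w, index, domain) {
  structure(as.numeric(w), index = as.integer(index), domain = domain,
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector over %ss>\n", attr(x, "domain")))
  print(stats::setNames(as.numeric(x), attr(x, "index")))
  invisible(x)
}

#' Select an index from a normalized weight vector
#'
#' The sampling step shared by production and reception. `"stochastic"`
#' samples proportionally to the weights; `"wta"` (winner-take-all) draws
#' uniformly among the maximal-weight entries (ties within `1e-12`), so the
#' choice is deterministic when the maximum is unique. One uniform draw is
#' consumed either way.
#'
#' @param weights A `weight_vector` (or normalized non-negative numeric
#'   vector) with at least one positive entry.
#' @param rule `"stochastic"` or `"wta"`.
#' @return The selected index on the weight vector's original index set
#'   (signal or meaning index).
#' @export
select_index <- function(weights, rule = c("stochastic", "wta")) {
  rule <- match.arg(rule)
  w <- as.numeric(weights)
  idx <- attr(weights, "index")
  if (is.null(idx)) idx <- seq_along(w)
  if (any(w < 0) || all(w == 0)) {
    stop("`weights` must be non-negative with at least one positive entry; ",
         "apply the uniform fallback before selection.", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-8) {
    stop("`weights` must be normalized.", call. = FALSE)
  }
  pos <- if (rule == "stochastic") {
    invcdf_normalized(w)
  } else {
    mx <- max(w)
    set <- which(w >= mx - WTA_TOL)
    set[unif_index(length(set))]
  }
  idx[[pos]]
}

# Behavioural distribution induced by a weight vector under a selection rule:
# the weights themselves (stochastic) or the argmax-uniform distribution
# (WTA). Used by the communicative-accuracy metric.
behavioral_dist <- function(w, rule) {
  w <- as.numeric(w)
  if (rule == "stochastic") return(w)
  mx <- max(w)
  set <- w >= mx - WTA_TOL
  out <- numeric(length(w))
  out[set] <- 1 / sum(set)
  out
}

# Full behavioural production matrix P[m, s] = p(s | m) and reception matrix
# R[m, s] = r(m | s, C = M) for one store under a mechanism configuration.
behavioral_matrices <- function(store, mcfg) {
  nm <- nrow(store$counts); ns <- ncol(store$counts)
  P <- matrix(0, nm, ns)
  R <- matrix(0, nm, ns)
  full <- seq_len(nm)
  for (m in full) {
    P[m, ] <- behavioral_dist(
      production_weights(store, m, mcfg$weighting), mcfg$selection)
  }
  for (s in seq_len(ns)) {
    R[, s] <- behavioral_dist(
      reception_weights(store, s, full, mcfg$weighting), mcfg$selection)
  }
  list(P = P, R = R)
}
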
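#' Topic frequency distributions
#'
#' Probability of each meaning being chosen as topic. `"uniform"` gives every
#' meaning equal frequency; `"zipf"` makes the frequency of the rank-`r`
#' meaning proportional to `1/r` (meaning index = frequency rank), the
#' power-law profile of word frequencies in natural language.
#'
#' @param kind `"uniform"` or `"zipf"`.
#' @param n_meanings Number of meanings.
#' @return Numeric probability vector summing to 1.
#' @examples
#' meaning_distribution("zipf", 5)[1]  # 1 / (1 + 1/2 + 1/3 + 1/4 + 1/5)
#' @export
meaning_distribution <- function(kind = c("uniform", "zipf"), n_meanings) {
  kind <- match.arg(kind)
  n_meanings <- as.integer(n_meanings)
  if (is.na(n_meanings) || n_meanings < 1L) {
    stop("`n_meanings` must be at least 1.", call. = FALSE)
  }
  if (kind == "uniform") {
    rep(1 / n_meanings, n_meanings)
  } else {
    w <- 1 / seq_len(n_meanings)
    w / sum(w)
  }
}

#' Sample a context and a topic
#'
#' Draws a context `C` of `c` meanings uniformly over all `c`-subsets, then a
#' topic from `C` with probability proportional to the meaning distribution
#' restricted to `C` (uniform topics under the uniform distribution). When
#' `c` equals the number of meanings the context is the full meaning set and
#' no subset draw is consumed.
#'
#' @param dist Probability vector over meanings (see
#'   [meaning_distribution()]).
#' @param c_size Context size, between 1 and `length(dist)`.
#' @return A list with elements `context` (sorted integer vector) and `topic`
#'   (integer scalar, an element of `context`).
#' @export
sample_context <- function(dist, c_size) {
  nm <- length(dist)
  c_size <- as.integer(c_size)
  if (is.na(c_size) || c_size < 1L || c_size > nm) {
    stop("`c_size` must lie in 1..length(dist).", call. = FALSE)
  }
  if (c_size == nm) {
    ctx <- seq_len(nm)
  } else {
    pool <- seq_len(nm)
    for (j in seq_len(c_size)) {
      r <- unif_index(nm - j + 1L)
      k <- j - 1L + r
      tmp <- pool[j]; pool[j] <- pool[k]; pool[k] <- tmp
    }
    ctx <- sort(pool[seq_len(c_size)])
  }
  w <- dist[ctx]
  wn <- w / sum(w)
  topic <- ctx[invcdf_normalized(wn)]
  list(context = ctx, topic = topic)
}

#' Agents
#'
#' An agent is an id, an exemplar store, a learning flag (established agents
#' in the gradual dynamic have learning disabled), and a birth-order integer
#' used to find the oldest agent at replacement time.
#'
#' @param id Integer id, unique within a population.
#' @param store An [exemplar_store()].
#' @param learning_enabled Whether the agent's store may be modified.
#' @param birth Birth-order integer.
#' @return An object of class `signaling_agent`.
#' @export
signaling_agent <- function(id, store, learning_enabled = TRUE, birth = 0L) {
  structure(list(id = as.integer(id), store = store,
                 learning_enabled = isTRUE(learning_enabled),
                 birth = as.integer(birth)),
            class = "signaling_agent")
}

#' @export
print.signaling_agent <- function(x, ...) {
  cat(sprintf("<agent %d: %d tokens, learning %s>\n", x$id,
              total_exemplars(x$store),
              if (x$learning_enabled) "enabled" else "disabled"))
  invisible(x)
}

#' Run one signaling interaction
#'
#' Samples a context and topic, has the speaker produce an utterance from its
#' production weights and the hearer select an interpretation from its
#' reception weights (each via the configured selection rule), and scores
#' success as topic-interpretation identity. No store is modified; learning
#' is applied separately by [apply_updates()].
#'
#' @param speaker,hearer `signaling_agent`s with matching meaning/signal
#'   spaces.
#' @param mcfg A [mechanism_config()].
#' @param dist Optional precomputed meaning distribution (defaults to
#'   `meaning_distribution(mcfg$meaning_dist, mcfg$n_meanings)`).
#' @return An object of class `interaction_outcome`: a list with `speaker`,
#'   `hearer` (ids), `context`, `topic`, `utterance`, `interpretation`,
#'   `success`.
#' @export
run_interaction <- function(speaker, hearer, mcfg, dist = NULL) {
  if (identical(speaker$id, hearer$id)) {
    stop("speaker and hearer must be distinct agents.", call. = FALSE)
  }
  if (is.null(dist)) {
    dist <- meaning_distribution(mcfg$meaning_dist, mcfg$n_meanings)
  }
  ct <- sample_context(dist, mcfg$context_size)
  pw <- production_weights(speaker$store, ct$topic, mcfg$weighting)
  u <- select_index(pw, mcfg$selection)
  rw <- reception_weights(hearer$store, u, ct$context, mcfg$weighting)
  i <- select_index(rw, mcfg$selection)
  structure(list(speaker = speaker$id, hearer = hearer$id,
                 context = ct$context, topic = ct$topic,
                 utterance = u, interpretation = i,
                 success = identical(ct$topic, i)),
            class = "interaction_outcome")
}

#' @export
print.interaction_outcome <- function(x, ...) {
  cat(sprintf(
    "<interaction: %d -> %d | topic m%d, utterance s%d, interpretation m%d, %s>\n",
    x$speaker, x$hearer, x$topic, x$utterance, x$interpretation,
    if (x$success) "success" else "failure"))
  invisible(x)
}

# Does the regime grant this role a new exemplar for this outcome?
role_adds <- function(role, outcome, mcfg) {
  switch(mcfg$regime,
    reinforcement = ,
    yesno_feedback = outcome$success && role %in% mcfg$learners,
    referential_feedback = role %in% mcfg$learners,
    observational = role == "hearer")
}

# Add a token plus its follow-up operators: lateral inhibition around the
# stored token, then memory-limit enforcement.
learn_exemplar <- function(store, m, s, mcfg) {
  store <- add_exemplar(store, m, s)
  if (mcfg$inhibition_kind != "none") {
    store <- apply_lateral_inhibition(store, c(m, s), mcfg$inhibition_kind,
                                      mcfg$inhibition_strength)
  }
  if (is.finite(mcfg$memory_limit)) {
    store <- enforce_memory_limit(store, mcfg$memory_limit, c(m, s))
  }
  store
}

#' Apply regime-specific learning updates after an interaction
#'
#' Dispatches the learning rule of the configured regime to the two agents.
#' The speaker's phase runs before the hearer's; within each phase,
#' punishment deletions (no randomness) precede the exemplar add, which is
#' followed by lateral inhibition around the stored token and memory-limit
#' enforcement. Agents with learning disabled are untouched.
#'
#' What gets stored: on success all regimes store the used pair `(t, u)` for
#' their learning roles. On failure, referential feedback still stores
#' `(t, u)` (the speaker points at the topic) and observational learning
#' always stores it (the topic is directly observed); reinforcement and
#' Yes/No feedback store nothing and only the configured punishment deletions
#' apply (see [mechanism_config()]).
#'
#' @param speaker,hearer The agents that produced `outcome`.
#' @param outcome An `interaction_outcome` from [run_interaction()].
#' @param mcfg A [mechanism_config()].
#' @return A list with updated `speaker` and `hearer` agents.
#' @export
apply_updates <- function(speaker, hearer, outcome, mcfg) {
  t <- outcome$topic; u <- outcome$utterance; i <- outcome$interpretation
  fb_regime <- mcfg$regime %in% c("yesno_feedback", "referential_feedback")
  sphc <- fb_regime && "speaker_punishes_hearers_association" %in% mcfg$punish

  # Speaker phase.
  if (speaker$learning_enabled) {
    if (!outcome$success) {
      if ("speaker_own" %in% mcfg$punish) {
        speaker$store <- suppress_noop(remove_exemplar(speaker$store, t, u))
      }
      if (sphc && mcfg$sphc_target == "speaker") {
        speaker$store <- suppress_noop(remove_exemplar(speaker$store, i, u))
      }
    }
    if (role_adds("speaker", outcome, mcfg)) {
      speaker$store <- learn_exemplar(speaker$store, t, u, mcfg)
    }
  }

  # Hearer phase.
  if (hearer$learning_enabled) {
    if (!outcome$success) {
      if (sphc && mcfg$sphc_target == "hearer") {
        hearer$store <- suppress_noop(remove_exemplar(hearer$store, i, u))
      }
      if ("hearer_own" %in% mcfg$punish) {
        hearer$store <- suppress_noop(remove_exemplar(hearer$store, i, u))
      }
    }
    if (role_adds("hearer", outcome, mcfg)) {
      hearer$store <- learn_exemplar(hearer$store, t, u, mcfg)
    }
  }

  list(speaker = speaker, hearer = hearer)
}

# Punishment deliberately floors at zero; silence the no-op signal in the
# engine path.
suppress_noop <- function(expr) {
  withCallingHandlers(expr, signalurn_noop_removal = function(c) invisible(NULL))
}
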
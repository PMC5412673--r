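#' Populations of exemplar agents
#'
#' Builds the agent collection and pairing structure for a simulation. In the
#' closed dynamic all agents learn throughout; in the gradual-replacement
#' dynamic the initial established agents have learning disabled and newborn
#' learners (always created with empty stores, relying on the innovation
#' fallback) cycle through the population.
#'
#' @param pcfg A [population_config()].
#' @param mcfg A [mechanism_config()].
#' @return An object of class `population`.
#' @export
init_population <- function(pcfg, mcfg) {
  agents <- lapply(seq_len(pcfg$size), function(k) {
    signaling_agent(
      id = k,
      store = exemplar_store(mcfg$n_meanings, mcfg$n_signals,
                             mcfg$init_scheme),
      learning_enabled = pcfg$dynamic == "closed",
      birth = k - 1L)
  })
  structure(list(
    agents = agents,
    pcfg = pcfg,
    edges = pairing_edges(pcfg),
    learner = NULL,
    learner_done = 0L,
    next_id = pcfg$size + 1L,
    next_birth = pcfg$size,
    interactions = 0L
  ), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population: %d established agents (%s dynamic)%s>\n",
              length(x$agents), x$pcfg$dynamic,
              if (!is.null(x$learner)) {
                sprintf(", active learner %d (%d/%d interactions)",
                        x$learner$id, x$learner_done,
                        x$pcfg$learner_interactions)
              } else ""))
  invisible(x)
}

# Ordered (speaker, hearer) pairs of the interaction graph, as an E x 2
# integer matrix. Complete graphs include every ordered pair; lattice and
# small-world graphs are built with igraph and expanded to ordered pairs.
pairing_edges <- function(pcfg) {
  n <- pcfg$size
  if (pcfg$pairing == "complete") {
    idx <- expand.grid(speaker = seq_len(n), hearer = seq_len(n))
    idx <- idx[idx$speaker != idx$hearer, , drop = FALSE]
    idx <- idx[order(idx$speaker, idx$hearer), , drop = FALSE]
    return(unname(as.matrix(idx)))
  }
  g <- if (pcfg$pairing == "ring_lattice") {
    igraph::sample_smallworld(1, n, pcfg$pairing_k, p = 0)
  } else {
    igraph::sample_smallworld(1, n, pcfg$pairing_k, p = pcfg$pairing_p)
  }
  g <- igraph::simplify(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  out <- rbind(e, e[, 2:1, drop = FALSE])
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  storage.mode(out) <- "integer"
  unname(out)
}

#' One interaction step in a closed population
#'
#' Draws an ordered (speaker, hearer) pair uniformly from the pairing graph's
#' ordered edges, runs the interaction, and applies the learning updates.
#'
#' @param pop A `population` with closed dynamic.
#' @param mcfg A [mechanism_config()].
#' @param dist Optional precomputed meaning distribution.
#' @return A list with the updated `population` and the
#'   `interaction_outcome`.
#' @export
step_closed <- function(pop, mcfg, dist = NULL) {
  stopifnot(pop$pcfg$dynamic == "closed")
  k <- unif_index(nrow(pop$edges))
  sp <- pop$edges[k, 1L]; he <- pop$edges[k, 2L]
  outcome <- run_interaction(pop$agents[[sp]], pop$agents[[he]], mcfg, dist)
  upd <- apply_updates(pop$agents[[sp]], pop$agents[[he]], outcome, mcfg)
  pop$agents[[sp]] <- upd$speaker
  pop$agents[[he]] <- upd$hearer
  pop$interactions <- pop$interactions + 1L
  list(population = pop, outcome = outcome)
}

#' One interaction step under gradual replacement
#'
#' Maintains the learner lifecycle: if no learner is active, a newborn with
#' an empty store is created; it is paired with a uniformly drawn established
#' agent, taking the hearer role (or a fair-coin role under
#' `learner_role = "random"`). Only the learner's store is updated. After
#' `learner_interactions` interactions the learner replaces the oldest
#' established agent and its learning is disabled.
#'
#' @inheritParams step_closed
#' @return A list with the updated `population`, the `interaction_outcome`,
#'   and `replaced` (the id of the agent replaced this step, or `NA`).
#' @export
step_gradual <- function(pop, mcfg, dist = NULL) {
  stopifnot(pop$pcfg$dynamic == "gradual")
  if (is.null(pop$learner)) {
    pop$learner <- signaling_agent(
      id = pop$next_id,
      store = exemplar_store(mcfg$n_meanings, mcfg$n_signals, "empty"),
      learning_enabled = TRUE,
      birth = pop$next_birth)
    pop$next_id <- pop$next_id + 1L
    pop$next_birth <- pop$next_birth + 1L
    pop$learner_done <- 0L
  }
  partner_idx <- unif_index(length(pop$agents))
  partner <- pop$agents[[partner_idx]]
  learner_speaks <- if (pop$pcfg$learner_role == "random") {
    stats::runif(1L) < 0.5
  } else FALSE
  if (learner_speaks) {
    outcome <- run_interaction(pop$learner, partner, mcfg, dist)
    upd <- apply_updates(pop$learner, partner, outcome, mcfg)
    pop$learner <- upd$speaker
  } else {
    outcome <- run_interaction(partner, pop$learner, mcfg, dist)
    upd <- apply_updates(partner, pop$learner, outcome, mcfg)
    pop$learner <- upd$hearer
  }
  pop$learner_done <- pop$learner_done + 1L
  pop$interactions <- pop$interactions + 1L
  replaced <- NA_integer_
  if (pop$learner_done >= pop$pcfg$learner_interactions) {
    births <- vapply(pop$agents, function(a) a$birth, integer(1))
    oldest <- which.min(births)
    replaced <- pop$agents[[oldest]]$id
    pop$learner$learning_enabled <- FALSE
    pop$agents[[oldest]] <- pop$learner
    pop["learner"] <- list(NULL)  # keep the element; `$<- NULL` would drop it
    pop$learner_done <- 0L
  }
  list(population = pop, outcome = outcome, replaced = replaced)
}
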
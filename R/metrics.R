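#' Communicative accuracy between two agents
#'
#' Expected probability that the hearer recovers the speaker's topic,
#' averaged over all contexts of the configured size and over topics within
#' each context:
#' \deqn{CA(a, b) = \frac{1}{c\,|T|} \sum_{C \in T} \sum_{m \in C} \sum_s
#'   p_a(s \mid m, C)\, r_b(m \mid s, C)}
#' where `T` is the set of all `c`-subsets of meanings and `p`, `r` are the
#' behavioural production and reception distributions induced by the
#' configured weighting and selection rules (the raw weight proportions
#' under stochastic selection; degenerate or argmax-uniform distributions
#' under WTA).
#'
#' With the unrestricted context (`c` equal to the number of meanings, the
#' basic framework) `T` has a single element and the sum is exact. For
#' restricted contexts all subsets are enumerated while their number is at
#' most `context_limit`; beyond that a Monte-Carlo estimate over
#' `n_mc_contexts` sampled contexts is returned, flagged with attribute
#' `monte_carlo = TRUE`.
#'
#' @param speaker,hearer `signaling_agent`s sharing meaning/signal spaces.
#' @param mcfg A [mechanism_config()].
#' @param context_limit Maximum number of contexts to enumerate exactly.
#' @param n_mc_contexts Number of contexts sampled in the Monte-Carlo branch.
#' @return Communicative accuracy in `[0, 1]`.
#' @export
pairwise_ca <- function(speaker, hearer, mcfg,
                        context_limit = 2000L, n_mc_contexts = 2000L) {
  nm <- mcfg$n_meanings
  if (nrow(speaker$store$counts) != nrow(hearer$store$counts) ||
      ncol(speaker$store$counts) != ncol(hearer$store$counts) ||
      nrow(speaker$store$counts) != nm) {
    stop("speaker and hearer must share the configured meaning/signal spaces.",
         call. = FALSE)
  }
  cs <- mcfg$context_size
  # Production is context-independent; precompute behavioural rows.
  P <- behavioral_production(speaker$store, mcfg)
  if (cs == nm) {
    R <- behavioral_reception(hearer$store, seq_len(nm), mcfg)
    return(sum(P * R) / nm)
  }
  n_ctx <- choose(nm, cs)
  if (n_ctx <= context_limit) {
    ctxs <- utils::combn(nm, cs)
    acc <- 0
    for (j in seq_len(ncol(ctxs))) {
      acc <- acc + context_ca_term(P, hearer$store, ctxs[, j], mcfg)
    }
    acc / (cs * n_ctx)
  } else {
    acc <- 0
    for (j in seq_len(n_mc_contexts)) {
      ctx <- sort(sample.int(nm, cs))
      acc <- acc + context_ca_term(P, hearer$store, ctx, mcfg)
    }
    structure(acc / (cs * n_mc_contexts), monte_carlo = TRUE)
  }
}

# Sum over m in C, s of p(s|m) r(m|s,C) for one context.
context_ca_term <- function(P, hearer_store, ctx, mcfg) {
  acc <- 0
  for (s in seq_len(mcfg$n_signals)) {
    rw <- behavioral_dist(
      reception_weights(hearer_store, s, ctx, mcfg$weighting),
      mcfg$selection)
    acc <- acc + sum(P[ctx, s] * rw)
  }
  acc
}

behavioral_production <- function(store, mcfg) {
  nm <- nrow(store$counts); ns <- ncol(store$counts)
  P <- matrix(0, nm, ns)
  for (m in seq_len(nm)) {
    P[m, ] <- behavioral_dist(
      production_weights(store, m, mcfg$weighting), mcfg$selection)
  }
  P
}

behavioral_reception <- function(store, ctx, mcfg) {
  nm <- nrow(store$counts); ns <- ncol(store$counts)
  R <- matrix(0, nm, ns)
  for (s in seq_len(ns)) {
    R[ctx, s] <- behavioral_dist(
      reception_weights(store, s, ctx, mcfg$weighting), mcfg$selection)
  }
  R
}

#' Population communicative accuracy
#'
#' Mean of [pairwise_ca()] over all ordered pairs of distinct agents, each
#' agent serving as both speaker and hearer.
#'
#' @param pop A `population`, or a list of `signaling_agent`s (at least 2).
#' @param mcfg A [mechanism_config()].
#' @param ... Passed to [pairwise_ca()].
#' @return Mean communicative accuracy in `[0, 1]`.
#' @export
population_ca <- function(pop, mcfg, ...) {
  agents <- if (inherits(pop, "population")) pop$agents else pop
  n <- length(agents)
  if (n < 2L) stop("population CA needs at least 2 agents.", call. = FALSE)
  acc <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b) acc <- acc + pairwise_ca(agents[[a]], agents[[b]], mcfg, ...)
    }
  }
  acc / (n * (n - 1L))
}

#' Monte-Carlo communicative accuracy
#'
#' Empirical success frequency over simulated interactions with learning
#' switched off; an unbiased estimator of [pairwise_ca()] and the package's
#' independent oracle for it. Contexts and topics are drawn uniformly to
#' match the definition of communicative accuracy (the configured topic
#' distribution is not used).
#'
#' @inheritParams pairwise_ca
#' @param n_trials Number of simulated interactions.
#' @return Empirical accuracy in `[0, 1]`.
#' @export
ca_monte_carlo <- function(speaker, hearer, mcfg, n_trials = 10000L) {
  if (n_trials < 1L) stop("`n_trials` must be at least 1.", call. = FALSE)
  dist <- meaning_distribution("uniform", mcfg$n_meanings)
  hits <- 0L
  for (k in seq_len(n_trials)) {
    out <- run_interaction(speaker, hearer, mcfg, dist)
    if (out$success) hits <- hits + 1L
  }
  hits / n_trials
}

#' Test a population for optimal signaling
#'
#' A population signals optimally when its communicative accuracy is exactly
#' 1: a completely unambiguous meaning-signal mapping shared by every agent.
#' Two independent checks are computed and must agree:
#' \itemize{
#'   \item numeric: full-context population CA equals 1 within `1e-9`;
#'   \item structural: every agent's behavioural production map is
#'     deterministic, identical across agents, and injective, and every
#'     agent deterministically interprets each used signal as its source
#'     meaning.
#' }
#' Optimality is context-independent, so the numeric check always uses the
#' unrestricted context regardless of the configured context size (for any
#' context size of 2 or more the two notions coincide; singleton contexts
#' make the restricted-context CA vacuously 1). When signals outnumber
#' meanings, optimal systems with perfect synonym sets need not have
#' deterministic production, so the structural check and its agreement
#' assertion apply only when `n_signals <= n_meanings`.
#'
#' @inheritParams population_ca
#' @return `TRUE` or `FALSE`.
#' @export
is_optimal <- function(pop, mcfg) {
  agents <- if (inherits(pop, "population")) pop$agents else pop
  full_cfg <- mcfg
  full_cfg$context_size <- mcfg$n_meanings
  numeric_opt <- abs(population_ca(agents, full_cfg) - 1) <= 1e-9
  if (mcfg$n_signals <= mcfg$n_meanings) {
    structural_opt <- structural_optimality(agents, mcfg)
    if (numeric_opt != structural_opt) {
      stop("internal consistency failure: numeric and structural optimality ",
           "checks disagree.", call. = FALSE)
    }
  }
  numeric_opt
}

structural_optimality <- function(agents, mcfg) {
  nm <- mcfg$n_meanings
  ref_map <- NULL
  for (ag in agents) {
    P <- behavioral_production(ag$store, mcfg)
    # Deterministic production: one unit entry per row.
    if (!all(abs(apply(P, 1, max) - 1) <= 1e-9)) return(FALSE)
    map <- apply(P, 1, which.max)
    if (anyDuplicated(map) > 0L) return(FALSE)  # injectivity
    if (is.null(ref_map)) ref_map <- map
    else if (!identical(map, ref_map)) return(FALSE)
    R <- behavioral_reception(ag$store, seq_len(nm), mcfg)
    for (m in seq_len(nm)) {
      if (abs(R[m, map[[m]]] - 1) > 1e-9) return(FALSE)
    }
  }
  TRUE
}

#' Convergence curve over a batch of runs
#'
#' Fraction of runs that had reached optimality by each grid iteration.
#'
#' @param results List of `simulation_result`s sharing a configuration.
#' @param grid Increasing integer vector of iteration checkpoints.
#' @return A `data.frame` with columns `iteration` and
#'   `proportion_converged`, and attribute `n_runs`.
#' @export
convergence_curve <- function(results, grid) {
  if (length(results) < 1L) stop("`results` must be non-empty.", call. = FALSE)
  iters <- vapply(results, function(r) {
    if (isTRUE(r$converged)) r$convergence_iteration else Inf
  }, numeric(1))
  grid <- sort(as.numeric(grid))
  prop <- vapply(grid, function(g) mean(iters <= g), numeric(1))
  structure(data.frame(iteration = grid, proportion_converged = prop),
            n_runs = length(results))
}

#' Distribution of final communicative accuracy scores
#'
#' Bins the final CA of each run; the stable end-state profile of a batch.
#'
#' @param results List of `simulation_result`s.
#' @param bin_width Histogram bin width on `[0, 1]`.
#' @return A `data.frame` with columns `bin_lower`, `bin_upper`, `count`.
#' @export
final_ca_distribution <- function(results, bin_width = 0.05) {
  if (length(results) < 1L) stop("`results` must be non-empty.", call. = FALSE)
  ca <- vapply(results, function(r) r$final_ca, numeric(1))
  breaks <- round(seq(0, 1, by = bin_width), 10)  # exact decimal bin edges
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- graphics::hist(ca, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  data.frame(bin_lower = breaks[-length(breaks)],
             bin_upper = breaks[-1],
             count = counts)
}
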
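#' Run one simulation to convergence or an interaction budget
#'
#' The top-level loop: initializes a population, iterates the step function
#' of the configured dynamic, and every `check_interval` interactions tests
#' the (established) population for optimal signaling via its full-context
#' communicative accuracy. The run stops at the first check that finds
#' CA = 1 (within `1e-9`) or after `max_interactions`.
#'
#' Two engines produce bit-identical results for a given seed: the default
#' compiled engine (`"cpp"`) and a pure-R reference engine (`"reference"`)
#' built directly from [step_closed()] / [step_gradual()]. Both consume R's
#' global RNG stream under the same draw discipline; the reference engine is
#' orders of magnitude slower and exists as the readable specification and
#' cross-check of the compiled path.
#'
#' @param pcfg A [population_config()].
#' @param mcfg A [mechanism_config()].
#' @param max_interactions Interaction budget (at least 1).
#' @param check_interval Interactions between convergence checks; the
#'   reported convergence iteration has this granularity.
#' @param seed Integer seed; all randomness derives from it.
#' @param engine `"cpp"` or `"reference"`.
#' @param return_population If `TRUE`, the final population is attached to
#'   the result.
#' @return An object of class `simulation_result`: a list with `converged`,
#'   `convergence_iteration` (`NA` if not converged), `final_ca`,
#'   `ca_trajectory` (data.frame of checkpoint CA values), `n_interactions`,
#'   `seed`, `engine`, and the two configurations.
#' @examples
#' cfgs <- preset("biased_hom")
#' run_simulation(cfgs$pcfg, cfgs$mcfg, max_interactions = 500,
#'                check_interval = 100, seed = 1)
#' @export
run_simulation <- function(pcfg, mcfg, max_interactions = 20000L,
                           check_interval = 100L, seed = 1L,
                           engine = c("cpp", "reference"),
                           return_population = FALSE) {
  engine <- match.arg(engine)
  max_interactions <- as.integer(max_interactions)
  check_interval <- as.integer(check_interval)
  if (is.na(max_interactions) || max_interactions < 1L) {
    stop("`max_interactions` must be at least 1.", call. = FALSE)
  }
  if (is.na(check_interval) || check_interval < 1L) {
    stop("`check_interval` must be at least 1.", call. = FALSE)
  }
  mcfg <- validate_config(mcfg)
  set.seed(as.integer(seed))
  pop <- init_population(pcfg, mcfg)
  dist <- meaning_distribution(mcfg$meaning_dist, mcfg$n_meanings)
  res <- if (engine == "cpp") {
    run_engine_compiled(pop, pcfg, mcfg, dist, max_interactions,
                        check_interval)
  } else {
    run_engine_reference(pop, pcfg, mcfg, dist, max_interactions,
                         check_interval)
  }
  out <- structure(list(
    converged = res$converged,
    convergence_iteration = if (res$converged) res$convergence_iteration
                            else NA_integer_,
    final_ca = res$final_ca,
    ca_trajectory = data.frame(iteration = res$traj_iteration,
                               ca = res$traj_ca),
    n_interactions = res$n_interactions,
    seed = as.integer(seed),
    engine = engine,
    pcfg = pcfg,
    mcfg = mcfg
  ), class = "simulation_result")
  if (return_population) out$population <- res$population
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %s after %d interactions, final CA %.3f>\n",
              if (x$converged) {
                sprintf("converged at %d", x$convergence_iteration)
              } else "not converged",
              x$n_interactions, x$final_ca))
  invisible(x)
}

# Pure-R reference engine. Mirrors src/engine.cpp draw for draw.
run_engine_reference <- function(pop, pcfg, mcfg, dist, max_interactions,
                                 check_interval) {
  step_fun <- if (pcfg$dynamic == "closed") step_closed else step_gradual
  traj_it <- integer(0)
  traj_ca <- numeric(0)
  converged <- FALSE
  conv_iter <- NA_integer_
  ca <- NA_real_
  full_cfg <- mcfg
  full_cfg$context_size <- mcfg$n_meanings
  it <- 0L
  while (it < max_interactions) {
    st <- step_fun(pop, mcfg, dist)
    pop <- st$population
    it <- it + 1L
    if (it %% check_interval == 0L || it == max_interactions) {
      ca <- population_ca(pop$agents, full_cfg)
      traj_it <- c(traj_it, it)
      traj_ca <- c(traj_ca, ca)
      if (ca >= 1 - 1e-9) {
        converged <- TRUE
        conv_iter <- it
        break
      }
    }
  }
  list(converged = converged, convergence_iteration = conv_iter,
       final_ca = ca, traj_iteration = traj_it, traj_ca = traj_ca,
       n_interactions = it, population = pop)
}

# Marshal to the compiled engine and back.
run_engine_compiled <- function(pop, pcfg, mcfg, dist, max_interactions,
                                check_interval) {
  stores <- lapply(pop$agents, function(a) a$store$counts)
  params <- list(
    n_meanings = mcfg$n_meanings,
    n_signals = mcfg$n_signals,
    regime = match(mcfg$regime, c("reinforcement", "yesno_feedback",
                                  "referential_feedback", "observational")) - 1L,
    weighting = match(mcfg$weighting, c("standard", "obverter")) - 1L,
    selection = match(mcfg$selection, c("stochastic", "wta")) - 1L,
    learn_speaker = "speaker" %in% mcfg$learners,
    learn_hearer = "hearer" %in% mcfg$learners,
    pun_speaker_own = "speaker_own" %in% mcfg$punish,
    pun_hearer_own = "hearer_own" %in% mcfg$punish,
    pun_sphc = "speaker_punishes_hearers_association" %in% mcfg$punish,
    sphc_target = match(mcfg$sphc_target, c("speaker", "hearer")) - 1L,
    inh_kind = match(mcfg$inhibition_kind, c("none", "anti_homonymy",
                                             "anti_synonymy", "both")) - 1L,
    inh_strength = match(mcfg$inhibition_strength,
                         c("minimal", "broad", "maximal")) - 1L,
    memory_limit = if (is.finite(mcfg$memory_limit)) {
      as.integer(mcfg$memory_limit)
    } else 0L,
    context_size = mcfg$context_size,
    dist = dist,
    dynamic = match(pcfg$dynamic, c("closed", "gradual")) - 1L,
    learner_interactions = pcfg$learner_interactions,
    learner_role = match(pcfg$learner_role, c("hearer_only", "random")) - 1L,
    edges = pop$edges,
    max_interactions = max_interactions,
    check_interval = check_interval
  )
  res <- run_engine_cpp(stores, params)
  # Rebuild the final population from the engine's agent bookkeeping.
  for (k in seq_along(pop$agents)) {
    pop$agents[[k]] <- signaling_agent(
      id = res$ids[k],
      store = new_exemplar_store(res$stores[[k]]),
      learning_enabled = res$learning[k],
      birth = res$births[k])
  }
  if (pcfg$dynamic == "gradual") {
    pop$next_id <- res$next_id
    pop$next_birth <- res$next_birth
    if (res$learner_active) {
      pop$learner <- signaling_agent(
        id = res$learner_id,
        store = new_exemplar_store(res$learner_store),
        learning_enabled = TRUE,
        birth = res$learner_birth)
      pop$learner_done <- res$learner_done
    }
  }
  pop$interactions <- res$n_interactions
  list(converged = res$converged,
       convergence_iteration = res$convergence_iteration,
       final_ca = res$final_ca,
       traj_iteration = res$traj_iteration,
       traj_ca = res$traj_ca,
       n_interactions = res$n_interactions,
       population = pop)
}
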
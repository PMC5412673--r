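#' Run a Monte-Carlo batch of simulations for a preset
#'
#' Runs `n_runs` independent simulations of a named preset with seeds
#' `base_seed, base_seed + 1, ...`, and aggregates convergence statistics.
#' Results depend only on the seeds, never on `workers` (runs are executed
#' sequentially; the argument exists for interface stability).
#'
#' @param preset_name A name from [preset_names()].
#' @param n_runs Number of independent runs.
#' @param max_interactions Interaction budget per run.
#' @param base_seed First seed; run `k` uses `base_seed + k - 1`.
#' @param workers Ignored (sequential execution); results are defined to be
#'   independent of it.
#' @param check_interval Convergence-check granularity per run.
#' @param engine Simulation engine, see [run_simulation()].
#' @param overrides Optional named list applied over the preset's
#'   configurations before running: entries `size`, `dynamic`,
#'   `learner_interactions` patch the population config; any
#'   `mechanism_config` field name patches the mechanism config.
#'   `memory_limit` overrides are taken as given (callers scale them when
#'   resizing the meaning/signal space).
#' @return An object of class `batch_result`: preset name, configs, the list
#'   of `simulation_result`s, `converged_fraction`, `mean_convergence`
#'   (mean convergence iteration among converged runs), a convergence curve,
#'   and a final-CA histogram.
#' @export
run_batch <- function(preset_name, n_runs, max_interactions = 20000L,
                      base_seed = 1L, workers = 1L, check_interval = 100L,
                      engine = "cpp", overrides = NULL) {
  if (n_runs < 1L) stop("`n_runs` must be at least 1.", call. = FALSE)
  cfgs <- preset_with(preset_name, overrides)
  t0 <- proc.time()[["elapsed"]]
  results <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    results[[k]] <- run_simulation(cfgs$pcfg, cfgs$mcfg,
                                   max_interactions = max_interactions,
                                   check_interval = check_interval,
                                   seed = base_seed + k - 1L,
                                   engine = engine)
  }
  conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  iters <- vapply(results, function(r) {
    if (isTRUE(r$converged)) as.numeric(r$convergence_iteration) else NA_real_
  }, numeric(1))
  grid <- unique(round(seq(check_interval, max_interactions,
                           length.out = 50L)))
  structure(list(
    preset = preset_name,
    pcfg = cfgs$pcfg,
    mcfg = cfgs$mcfg,
    n_runs = n_runs,
    base_seed = as.integer(base_seed),
    max_interactions = as.integer(max_interactions),
    check_interval = as.integer(check_interval),
    results = results,
    converged_fraction = mean(conv),
    mean_convergence = if (any(conv)) mean(iters[conv]) else NA_real_,
    curve = convergence_curve(results, grid),
    ca_hist = final_ca_distribution(results),
    wall_time = proc.time()[["elapsed"]] - t0
  ), class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result: %s, %d runs x <= %d interactions>\n",
              x$preset, x$n_runs, x$max_interactions))
  cat(sprintf("  converged: %.1f%%%s\n", 100 * x$converged_fraction,
              if (!is.na(x$mean_convergence)) {
                sprintf(" (mean convergence iteration %.0f)",
                        x$mean_convergence)
              } else ""))
  invisible(x)
}

# Apply overrides on top of a preset's configuration pair.
preset_with <- function(preset_name, overrides = NULL) {
  cfgs <- preset(preset_name)
  if (is.null(overrides) || length(overrides) == 0L) return(cfgs)
  pop_fields <- c("size", "dynamic", "learner_interactions", "pairing",
                  "pairing_k", "pairing_p", "learner_role")
  for (nm in names(overrides)) {
    if (nm %in% pop_fields) {
      cfgs$pcfg[[nm]] <- overrides[[nm]]
    } else if (nm %in% names(cfgs$mcfg)) {
      cfgs$mcfg[[nm]] <- overrides[[nm]]
    } else {
      stop(sprintf("unknown override field \"%s\".", nm), call. = FALSE)
    }
  }
  if (!"context_size" %in% names(overrides) &&
      "n_meanings" %in% names(overrides)) {
    cfgs$mcfg$context_size <- as.integer(overrides$n_meanings)
  }
  cfgs$pcfg <- do.call(population_config, cfgs$pcfg[pop_fields])
  cfgs$mcfg <- validate_config(cfgs$mcfg)
  cfgs
}

#' Convergence-time scaling under doubling
#'
#' Measures how the mean number of interactions to convergence grows when
#' the population, or the meaning-and-signal inventory, is successively
#' doubled. For the population axis, sizes are `10 * 2^k`; for the meanings
#' axis, `|M| = |S| = 5 * 2^k` (with any finite memory limit scaled
#' proportionally to `|M| x |S|`, preserving the limit's relation to the
#' space it must cover). Every run must converge; a non-converging
#' configuration aborts with a diagnostic.
#'
#' @param base_preset A reliably converging preset; the default is the
#'   hearer-only minimal model with inhibition of both homonyms and
#'   synonyms, which converges quickly and remains reliable under skewed
#'   topic distributions and resized inventories (homonym-only inhibition
#'   can let a frequent meaning permanently occupy two synonymous signals,
#'   starving the rarest meaning).
#' @param axis `"population"` or `"meanings_and_signals"`.
#' @param doublings Number of doublings beyond the base size.
#' @param n_reps Runs per size.
#' @param base_seed First seed (consecutive seeds across all runs).
#' @param max_interactions Per-run budget.
#' @param check_interval Convergence-check granularity.
#' @param engine Simulation engine.
#' @return A `data.frame` with columns `size`, `mean_convergence`, and
#'   `ratio` (mean relative to the previous size; `NA` for the first row).
#' @export
scaling_study <- function(base_preset = "biased_both",
                          axis = c("population", "meanings_and_signals"),
                          doublings = 1L, n_reps = 10L, base_seed = 1L,
                          max_interactions = 200000L, check_interval = 25L,
                          engine = "cpp") {
  axis <- match.arg(axis)
  base_mcfg <- preset(base_preset)$mcfg
  sizes <- if (axis == "population") {
    10L * 2L^(0:doublings)
  } else {
    5L * 2L^(0:doublings)
  }
  means <- numeric(length(sizes))
  seed <- as.integer(base_seed)
  for (j in seq_along(sizes)) {
    overrides <- if (axis == "population") {
      list(size = sizes[j])
    } else {
      ov <- list(n_meanings = sizes[j], n_signals = sizes[j])
      if (is.finite(base_mcfg$memory_limit)) {
        scale <- (sizes[j] * sizes[j]) /
          (base_mcfg$n_meanings * base_mcfg$n_signals)
        ov$memory_limit <- as.integer(round(base_mcfg$memory_limit * scale))
      }
      ov
    }
    cfgs <- preset_with(base_preset, overrides)
    iters <- numeric(n_reps)
    for (k in seq_len(n_reps)) {
      r <- run_simulation(cfgs$pcfg, cfgs$mcfg,
                          max_interactions = max_interactions,
                          check_interval = check_interval,
                          seed = seed, engine = engine)
      seed <- seed + 1L
      if (!r$converged) {
        stop(sprintf(paste0("scaling study aborted: preset \"%s\" did not ",
                            "converge at %s = %d within %d interactions ",
                            "(seed %d)."),
                     base_preset, axis, sizes[j], max_interactions, r$seed),
             call. = FALSE)
      }
      iters[k] <- r$convergence_iteration
    }
    means[j] <- mean(iters)
  }
  data.frame(size = sizes,
             mean_convergence = means,
             ratio = c(NA, means[-1] / means[-length(means)]))
}

#' Convergence slowdown under Zipf-distributed topics
#'
#' Compares mean convergence times when topics are presented with Zipf
#' (1/rank) frequencies against uniform presentation, at a given
#' meaning/signal inventory size. The same seed set is used for both
#' conditions (paired comparison).
#'
#' @inheritParams scaling_study
#' @param n_meanings Meaning and signal inventory size (`|M| = |S|`).
#' @param n_reps Runs per condition.
#' @return An object of class `zipf_result`: list with `ratio`
#'   (zipf / uniform mean convergence iterations), `mean_uniform`,
#'   `mean_zipf`, and the per-run iteration vectors.
#' @export
zipf_slowdown <- function(base_preset = "biased_both",
                          n_meanings = 5L, n_reps = 20L, base_seed = 1L,
                          max_interactions = 200000L, check_interval = 25L,
                          engine = "cpp") {
  run_cond <- function(dist_kind) {
    overrides <- list(n_meanings = as.integer(n_meanings),
                      n_signals = as.integer(n_meanings),
                      meaning_dist = dist_kind)
    cfgs <- preset_with(base_preset, overrides)
    vapply(seq_len(n_reps), function(k) {
      r <- run_simulation(cfgs$pcfg, cfgs$mcfg,
                          max_interactions = max_interactions,
                          check_interval = check_interval,
                          seed = base_seed + k - 1L, engine = engine)
      if (!r$converged) {
        stop(sprintf(paste0("zipf study aborted: preset \"%s\" (%s topics) ",
                            "did not converge within %d interactions ",
                            "(seed %d)."),
                     base_preset, dist_kind, max_interactions, r$seed),
             call. = FALSE)
      }
      as.numeric(r$convergence_iteration)
    }, numeric(1))
  }
  uni <- run_cond("uniform")
  zpf <- run_cond("zipf")
  structure(list(ratio = mean(zpf) / mean(uni),
                 mean_uniform = mean(uni),
                 mean_zipf = mean(zpf),
                 iterations_uniform = uni,
                 iterations_zipf = zpf,
                 n_meanings = as.integer(n_meanings),
                 n_reps = as.integer(n_reps),
                 base_preset = base_preset),
            class = "zipf_result")
}

#' @export
print.zipf_result <- function(x, ...) {
  cat(sprintf(
    "<zipf_result: |M| = |S| = %d, %d reps/condition>\n  zipf/uniform convergence-time ratio: %.3f (%.0f / %.0f iterations)\n",
    x$n_meanings, x$n_reps, x$ratio, x$mean_zipf, x$mean_uniform))
  invisible(x)
}
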
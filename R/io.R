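#' Load a simulation configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration and returns
#' validated configuration objects, defaulted to the basic framework. The
#' schema has up to four top-level keys:
#' \describe{
#'   \item{preset}{optional preset name supplying the baseline configs;}
#'   \item{mechanism}{named fields of [mechanism_config()] to set;}
#'   \item{population}{named fields of [population_config()] to set;}
#'   \item{run}{optional `max_interactions`, `check_interval`, `seed`.}
#' }
#' Unknown keys raise an error naming the offending key. The mechanism
#' field `memory_limit` accepts the string `"unlimited"` (or `null`) for
#' unlimited memory.
#'
#' @param path Path to the configuration file.
#' @return A list with `pcfg`, `mcfg`, and `run` (list of run settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0L) {
    stop("empty configuration: provide at least one of the keys ",
         "preset, mechanism, population, run.", call. = FALSE)
  }
  known <- c("preset", "mechanism", "population", "run")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown configuration key(s): %s (known keys: %s).",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$preset)) {
    cfgs <- preset(raw$preset)
  } else {
    if (is.null(raw$mechanism) || is.null(raw$mechanism$regime)) {
      stop("a configuration without `preset` must set mechanism$regime ",
           "(plus any non-default mechanism/population fields).",
           call. = FALSE)
    }
    cfgs <- list(pcfg = population_config(),
                 mcfg = mechanism_config(raw$mechanism$regime,
                                         validate = FALSE))
  }
  mech <- raw$mechanism
  if (!is.null(mech)) {
    if ("memory_limit" %in% names(mech)) {
      ml <- mech$memory_limit
      mech$memory_limit <- if (is.null(ml) || identical(ml, "unlimited")) {
        Inf
      } else as.numeric(ml)
    }
    bad <- setdiff(names(mech), names(cfgs$mcfg))
    if (length(bad) > 0L) {
      stop(sprintf("unknown mechanism field(s): %s.",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (nm in names(mech)) cfgs$mcfg[[nm]] <- mech[[nm]]
    if (!"context_size" %in% names(mech) && "n_meanings" %in% names(mech)) {
      cfgs$mcfg$context_size <- as.integer(mech$n_meanings)
    }
    cfgs$mcfg$n_meanings <- as.integer(cfgs$mcfg$n_meanings)
    cfgs$mcfg$n_signals <- as.integer(cfgs$mcfg$n_signals)
    cfgs$mcfg$context_size <- as.integer(cfgs$mcfg$context_size)
  }
  pop <- raw$population
  if (!is.null(pop)) {
    pop_fields <- c("size", "dynamic", "learner_interactions", "pairing",
                    "pairing_k", "pairing_p", "learner_role")
    bad <- setdiff(names(pop), pop_fields)
    if (length(bad) > 0L) {
      stop(sprintf("unknown population field(s): %s.",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (nm in names(pop)) cfgs$pcfg[[nm]] <- pop[[nm]]
    cfgs$pcfg <- do.call(population_config,
                         unclass(cfgs$pcfg)[pop_fields])
  }
  cfgs$mcfg <- validate_config(cfgs$mcfg)
  run <- raw$run
  run_defaults <- list(max_interactions = 20000L, check_interval = 100L,
                       seed = 1L)
  if (!is.null(run)) {
    bad <- setdiff(names(run), names(run_defaults))
    if (length(bad) > 0L) {
      stop(sprintf("unknown run field(s): %s.", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    run_defaults[names(run)] <- run
  }
  list(pcfg = cfgs$pcfg, mcfg = cfgs$mcfg,
       run = lapply(run_defaults, as.integer))
}

#' Write batch results to disk
#'
#' Emits the standard result files for a [run_batch()] result into
#' `out_dir` (created if missing):
#' \describe{
#'   \item{runs.csv}{one row per run: `preset`, `seed`, `converged`,
#'     `convergence_iteration`, `final_ca`, `wall_time` (batch-level,
#'     informational);}
#'   \item{curve.csv}{`iteration`, `proportion_converged`;}
#'   \item{ca_hist.csv}{`bin_lower`, `bin_upper`, `count`;}
#'   \item{config.json}{a JSON snapshot of both configurations and the batch
#'     settings.}
#' }
#' Output bytes are a pure function of the batch object, so rewriting the
#' same batch reproduces identical files.
#'
#' @param batch A `batch_result`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(batch, out_dir) {
  if (!inherits(batch, "batch_result")) {
    stop("`batch` must be a batch_result.", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- data.frame(
    preset = batch$preset,
    seed = vapply(batch$results, function(r) r$seed, integer(1)),
    converged = vapply(batch$results, function(r) r$converged, logical(1)),
    convergence_iteration = vapply(batch$results, function(r) {
      if (isTRUE(r$converged)) as.integer(r$convergence_iteration)
      else NA_integer_
    }, integer(1)),
    final_ca = vapply(batch$results, function(r) r$final_ca, numeric(1)),
    wall_time = batch$wall_time
  )
  paths <- c(runs = file.path(out_dir, "runs.csv"),
             curve = file.path(out_dir, "curve.csv"),
             ca_hist = file.path(out_dir, "ca_hist.csv"),
             config = file.path(out_dir, "config.json"))
  utils::write.csv(runs, paths[["runs"]], row.names = FALSE)
  utils::write.csv(batch$curve, paths[["curve"]], row.names = FALSE)
  utils::write.csv(batch$ca_hist, paths[["ca_hist"]], row.names = FALSE)
  snapshot <- list(
    preset = batch$preset,
    n_runs = batch$n_runs,
    base_seed = batch$base_seed,
    max_interactions = batch$max_interactions,
    check_interval = batch$check_interval,
    population = config_to_list(batch$pcfg),
    mechanism = config_to_list(batch$mcfg)
  )
  jsonlite::write_json(snapshot, paths[["config"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$memory_limit) && is.infinite(out$memory_limit)) {
    out$memory_limit <- "unlimited"
  }
  out
}

#' Reload a written configuration snapshot
#'
#' Counterpart of the `config.json` emitted by [write_results()]; returns
#' configurations equal to the ones that produced it.
#'
#' @param path Path to a `config.json`.
#' @return A list with `pcfg` and `mcfg`.
#' @export
read_config_snapshot <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  mech <- snap$mechanism
  if (identical(mech$memory_limit, "unlimited")) mech$memory_limit <- Inf
  mcfg <- mechanism_config(
    regime = mech$regime, weighting = mech$weighting,
    selection = mech$selection, learners = mech$learners,
    punish = if (length(mech$punish) > 0) mech$punish else character(),
    inhibition_kind = mech$inhibition_kind,
    inhibition_strength = mech$inhibition_strength,
    memory_limit = mech$memory_limit, init_scheme = mech$init_scheme,
    n_meanings = mech$n_meanings, n_signals = mech$n_signals,
    context_size = mech$context_size, meaning_dist = mech$meaning_dist,
    sphc_target = mech$sphc_target)
  pop <- snap$population
  pcfg <- population_config(
    size = pop$size, dynamic = pop$dynamic,
    learner_interactions = pop$learner_interactions, pairing = pop$pairing,
    pairing_k = pop$pairing_k, pairing_p = pop$pairing_p,
    learner_role = pop$learner_role)
  list(pcfg = pcfg, mcfg = mcfg)
}

#' Serialize an exemplar store
#'
#' Writes the dense count matrix (rows = meanings, columns = signals) as
#' CSV or JSON for checkpointing and fixtures; [read_store()] reverses it.
#'
#' @param store An [exemplar_store()].
#' @param path Output path; format by extension (`.csv` or `.json`).
#' @return Invisibly, `path`.
#' @export
write_store <- function(store, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(n_meanings = nrow(store$counts),
                              n_signals = ncol(store$counts),
                              counts = store$counts),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(store$counts, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    as_exemplar_store(matrix(as.integer(obj$counts), nrow = obj$n_meanings,
                             ncol = obj$n_signals))
  } else {
    as_exemplar_store(as.matrix(utils::read.csv(path, header = FALSE)))
  }
}
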
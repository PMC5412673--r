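#' Mechanism configuration: the model switchboard
#'
#' Bundles every mechanism choice that defines one model family: the learning
#' regime, weighting and selection rules, who learns, punishment options,
#' lateral inhibition, memory limit, initialization, context size, and the
#' meaning (topic) frequency distribution.
#'
#' Regimes:
#' \describe{
#'   \item{reinforcement}{Roth-Erev reinforcement. On success every learning
#'     agent stores the used pair; on failure the configured punishment
#'     deletions apply.}
#'   \item{yesno_feedback}{As reinforcement, but the hearer points at its
#'     interpretation, so the speaker may additionally punish the hearer's
#'     failed association (`"speaker_punishes_hearers_association"`).}
#'   \item{referential_feedback}{The speaker reveals the topic after every
#'     interaction (confirming on success, pointing on failure), so learning
#'     agents store the intended pair regardless of success.}
#'   \item{observational}{Hearers observe full meaning-signal pairs and store
#'     them; success plays no role, only hearers learn, and punishment is
#'     unavailable.}
#' }
#'
#' @param regime One of `"reinforcement"`, `"yesno_feedback"`,
#'   `"referential_feedback"`, `"observational"`.
#' @param weighting `"standard"` or `"obverter"` (see
#'   [production_weights()]).
#' @param selection `"stochastic"` or `"wta"` (see [select_index()]).
#' @param learners Subset of `c("speaker", "hearer")`: which interaction
#'   roles store new exemplars.
#' @param punish Subset of `c("speaker_own", "hearer_own",
#'   "speaker_punishes_hearers_association")`: deletions applied after a
#'   failed interaction. `speaker_own` deletes the speaker's used pair
#'   `(t, u)` from the speaker's store; `hearer_own` deletes the hearer's
#'   interpreted pair `(i, u)` from the hearer's store;
#'   `speaker_punishes_hearers_association` deletes the hearer's pointed pair
#'   `(i, u)` from the store named by `sphc_target`.
#' @param inhibition_kind `"none"`, `"anti_homonymy"`, `"anti_synonymy"`, or
#'   `"both"`; applied around every newly stored exemplar.
#' @param inhibition_strength `"minimal"`, `"broad"`, or `"maximal"`.
#' @param memory_limit Positive count, or `Inf` for unlimited memory.
#' @param init_scheme `"empty"` or `"one_per_pair"` (see
#'   [exemplar_store()]).
#' @param n_meanings,n_signals Sizes of the meaning and signal inventories.
#' @param context_size Context size `c`, between 1 and `n_meanings`; the
#'   basic framework uses the unrestricted context `c = n_meanings`.
#' @param meaning_dist `"uniform"` or `"zipf"` topic frequency distribution
#'   (see [meaning_distribution()]).
#' @param sphc_target `"speaker"` (default) or `"hearer"`: whose store the
#'   `speaker_punishes_hearers_association` deletion is applied to. The
#'   default reads the speaker as the agent acting on the hearer's pointing;
#'   the alias supports the alternative reading for sensitivity checks.
#' @param validate If `TRUE`, the configuration is checked with
#'   [validate_config()] before being returned.
#'
#' @return An object of class `mechanism_config`.
#' @export
mechanism_config <- function(regime = c("reinforcement", "yesno_feedback",
                                        "referential_feedback",
                                        "observational"),
                             weighting = c("standard", "obverter"),
                             selection = c("stochastic", "wta"),
                             learners = c("speaker", "hearer"),
                             punish = character(),
                             inhibition_kind = c("none", "anti_homonymy",
                                                 "anti_synonymy", "both"),
                             inhibition_strength = c("minimal", "broad",
                                                     "maximal"),
                             memory_limit = Inf,
                             init_scheme = c("empty", "one_per_pair"),
                             n_meanings = 5L,
                             n_signals = 5L,
                             context_size = n_meanings,
                             meaning_dist = c("uniform", "zipf"),
                             sphc_target = c("speaker", "hearer"),
                             validate = TRUE) {
  cfg <- structure(list(
    regime = match.arg(regime),
    weighting = match.arg(weighting),
    selection = match.arg(selection),
    learners = unique(as.character(learners)),
    punish = unique(as.character(punish)),
    inhibition_kind = match.arg(inhibition_kind),
    inhibition_strength = match.arg(inhibition_strength),
    memory_limit = memory_limit,
    init_scheme = match.arg(init_scheme),
    n_meanings = as.integer(n_meanings),
    n_signals = as.integer(n_signals),
    context_size = as.integer(context_size),
    meaning_dist = match.arg(meaning_dist),
    sphc_target = match.arg(sphc_target)
  ), class = "mechanism_config")
  if (validate) cfg <- validate_config(cfg) else cfg
}

#' Validate a mechanism configuration
#'
#' Checks a configuration against the combinations the framework rules out
#' and returns it normalized. All violations are reported together. Maximal
#' lateral inhibition is allowed but triggers a warning, since it guarantees
#' one-to-one mappings by construction and so trivializes the ambiguity
#' problem.
#'
#' @param cfg A `mechanism_config`.
#' @return The validated configuration (invisibly unchanged apart from
#'   normalization).
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "mechanism_config")) {
    stop("`cfg` must be a mechanism_config.", call. = FALSE)
  }
  errs <- character()
  roles <- c("speaker", "hearer")
  pun_opts <- c("speaker_own", "hearer_own",
                "speaker_punishes_hearers_association")
  if (length(cfg$learners) < 1L || !all(cfg$learners %in% roles)) {
    errs <- c(errs, "`learners` must be a non-empty subset of {speaker, hearer}.")
  }
  if (!all(cfg$punish %in% pun_opts)) {
    errs <- c(errs, sprintf("unknown punish option(s): %s.",
                            paste(setdiff(cfg$punish, pun_opts),
                                  collapse = ", ")))
  }
  if (cfg$regime == "observational") {
    if (!identical(sort(cfg$learners), "hearer")) {
      errs <- c(errs, "observational learning updates hearers only; set learners = \"hearer\".")
    }
    if (length(cfg$punish) > 0L) {
      errs <- c(errs, "observational learning is success-blind; punishment options are unavailable.")
    }
  }
  if (cfg$regime == "reinforcement" &&
      "speaker_punishes_hearers_association" %in% cfg$punish) {
    errs <- c(errs, paste0("reinforcement provides no interpretive feedback; ",
                           "the hearer's association is not observable to the speaker."))
  }
  if (is.na(cfg$n_meanings) || cfg$n_meanings < 1L ||
      is.na(cfg$n_signals) || cfg$n_signals < 1L) {
    errs <- c(errs, "`n_meanings` and `n_signals` must be positive.")
  }
  if (is.na(cfg$context_size) || cfg$context_size < 1L ||
      cfg$context_size > cfg$n_meanings) {
    errs <- c(errs, "`context_size` must lie in 1..n_meanings.")
  }
  if (!(is.infinite(cfg$memory_limit) ||
        (cfg$memory_limit >= 1 && cfg$memory_limit == round(cfg$memory_limit)))) {
    errs <- c(errs, "`memory_limit` must be a positive integer or Inf.")
  }
  if (length(errs) > 0L) {
    stop("invalid mechanism configuration:\n",
         paste0("  - ", errs, collapse = "\n"), call. = FALSE)
  }
  if (cfg$inhibition_kind != "none" && cfg$inhibition_strength == "maximal") {
    warning("maximal inhibition guarantees one-to-one mappings by ",
            "construction; it removes the ambiguity problem rather than ",
            "solving it.", call. = FALSE)
  }
  cfg$learners <- intersect(roles, cfg$learners)  # canonical order
  cfg$punish <- intersect(pun_opts, cfg$punish)
  cfg
}

#' @export
print.mechanism_config <- function(x, ...) {
  cat("<mechanism_config>\n")
  cat(sprintf("  regime: %s | weighting: %s | selection: %s\n",
              x$regime, x$weighting, x$selection))
  cat(sprintf("  learners: {%s} | punish: {%s}\n",
              paste(x$learners, collapse = ", "),
              paste(x$punish, collapse = ", ")))
  cat(sprintf("  inhibition: %s/%s | memory limit: %s | init: %s\n",
              x$inhibition_kind, x$inhibition_strength,
              ifelse(is.infinite(x$memory_limit), "unlimited",
                     format(x$memory_limit)),
              x$init_scheme))
  cat(sprintf("  meanings: %d | signals: %d | context size: %d | topics: %s\n",
              x$n_meanings, x$n_signals, x$context_size, x$meaning_dist))
  invisible(x)
}

#' Population configuration
#'
#' @param size Number of agents (at least 2); the basic framework uses 10.
#' @param dynamic `"closed"` (no turnover; every agent keeps learning) or
#'   `"gradual"` (newborn learners interact `learner_interactions` times with
#'   the established population, then replace its oldest member; established
#'   agents do not learn).
#' @param learner_interactions Interactions per newborn before replacement
#'   (gradual dynamic; the basic framework uses 35).
#' @param pairing Interaction graph: `"complete"`, `"ring_lattice"` (each
#'   agent linked to its `pairing_k` nearest neighbours per side), or
#'   `"small_world"` (Watts-Strogatz rewiring of the ring lattice with
#'   probability `pairing_p`).
#' @param pairing_k Lattice neighbourhood radius.
#' @param pairing_p Small-world rewiring probability.
#' @param learner_role Role of the newborn in gradual-dynamic interactions:
#'   `"hearer_only"` (observational presets) or `"random"` (a fair coin each
#'   interaction; used by reinforcement presets where learners must sometimes
#'   speak to be reinforced or punished).
#' @return An object of class `population_config`.
#' @export
population_config <- function(size = 10L,
                              dynamic = c("closed", "gradual"),
                              learner_interactions = 35L,
                              pairing = c("complete", "ring_lattice",
                                          "small_world"),
                              pairing_k = 2L,
                              pairing_p = 0.1,
                              learner_role = c("hearer_only", "random")) {
  size <- as.integer(size)
  learner_interactions <- as.integer(learner_interactions)
  if (is.na(size) || size < 2L) stop("`size` must be at least 2.", call. = FALSE)
  if (is.na(learner_interactions) || learner_interactions < 1L) {
    stop("`learner_interactions` must be at least 1.", call. = FALSE)
  }
  structure(list(
    size = size,
    dynamic = match.arg(dynamic),
    learner_interactions = learner_interactions,
    pairing = match.arg(pairing),
    pairing_k = as.integer(pairing_k),
    pairing_p = pairing_p,
    learner_role = match.arg(learner_role)
  ), class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("<population_config: %d agents, %s dynamic, %s pairing>\n",
              x$size, x$dynamic, x$pairing))
  if (x$dynamic == "gradual") {
    cat(sprintf("  learner: %d interactions, role %s\n",
                x$learner_interactions, x$learner_role))
  }
  invisible(x)
}
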
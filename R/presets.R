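#' Named replication presets
#'
#' Ready-made configurations for the model families the framework
#' replicates. Every preset starts from the basic framework — 10 agents, 5
#' meanings, 5 signals, unrestricted context, stochastic production and
#' reception, closed population, no punishment, inhibition, or memory limit —
#' and switches on only the mechanisms that define the source model.
#'
#' Reinforcement family (closed-group presets initialize with one exemplar
#' per association to avoid the reinforcement lock-in effect):
#' \describe{
#'   \item{skyrms_pure}{pure Roth-Erev reinforcement: both roles store the
#'     used pair after success, nothing else.}
#'   \item{barrett_memory35}{pure reinforcement plus a 35-exemplar memory
#'     limit with random forgetting.}
#'   \item{barrett_punish_both}{reinforcement with both roles also deleting
#'     their failed association.}
#'   \item{barrett_punish_hearer}{only the hearer updates, by reinforcement
#'     and punishment.}
#'   \item{reinforce_gradual[_punish_speaker|_punish_hearer|_punish_both]}{
#'     reinforcement under gradual population turnover (newborns interact 35
#'     times, in randomly assigned roles, then replace the oldest agent).}
#' }
#'
#' Naming Game family (empty initialization; agents innovate through the
#' uniform fallback):
#' \describe{
#'   \item{naminggame_full}{the full Naming Game: Yes/No feedback with
#'     interpretation pointing, winner-take-all production/reception,
#'     punishment of both own associations and of the hearer's pointed
#'     association, and minimal inhibition of homonyms and synonyms.}
#'   \item{yesno_punish_interpretive}{Yes/No feedback where the speaker
#'     punishes only the hearer's pointed association.}
#'   \item{yesno_punish_speaker, yesno_punish_hearer}{Yes/No feedback with
#'     own-association punishment by one role.}
#'   \item{yesno_inhibition}{Yes/No feedback with no punishment but minimal
#'     inhibition of homonyms and synonyms.}
#'   \item{referential_none/syn/hom/both}{referential feedback (both roles
#'     store the topic-utterance pair every interaction) under the four
#'     lateral-inhibition settings.}
#'   \item{referential_hearer_hom}{the minimal Naming Game: referential
#'     feedback, hearer-only learning, minimal anti-homonymy inhibition.}
#' }
#'
#' Observational family:
#' \describe{
#'   \item{biased_none/syn/hom/both}{closed-group observational (biased)
#'     learners under the four inhibition settings.}
#'   \item{obverter_gradual_wta, obverter_gradual_stoch}{obverter
#'     production/reception with gradual turnover (newborn hearers).}
#'   \item{obverter_closed[_mem35], obverter_closed_stoch[_mem35]}{obverter
#'     learners in closed groups, with and without a 35-exemplar memory
#'     limit.}
#' }
#'
#' @param name Preset identifier; see `preset_names()`.
#' @return A list with elements `pcfg` ([population_config()]) and `mcfg`
#'   ([mechanism_config()]).
#' @examples
#' preset("skyrms_pure")$mcfg
#' @export
preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown preset \"%s\"; available presets:\n  %s",
                 name, paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[name]]()
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_registry())

#' @rdname preset
#' @return `comparison_quartet()` returns the names of the four minimal
#'   model instantiations whose convergence behaviour the framework compares
#'   head-to-head: hearer-punished reinforcement, the minimal referential
#'   Naming Game, memory-limited obverters, and homonym-inhibiting biased
#'   learners.
#' @export
comparison_quartet <- function() {
  c("barrett_punish_hearer", "referential_hearer_hom",
    "obverter_closed_stoch_mem35", "biased_hom")
}

basic_pcfg <- function(...) population_config(...)

preset_registry <- function() {
  reinf <- function(...) {
    list(pcfg = basic_pcfg(),
         mcfg = mechanism_config("reinforcement", init_scheme = "one_per_pair",
                                 ...))
  }
  reinf_grad <- function(punish = character()) {
    list(pcfg = basic_pcfg(dynamic = "gradual", learner_role = "random"),
         mcfg = mechanism_config("reinforcement", init_scheme = "empty",
                                 punish = punish))
  }
  yesno <- function(...) {
    list(pcfg = basic_pcfg(),
         mcfg = mechanism_config("yesno_feedback", init_scheme = "empty", ...))
  }
  referential <- function(...) {
    list(pcfg = basic_pcfg(),
         mcfg = mechanism_config("referential_feedback",
                                 init_scheme = "empty", ...))
  }
  biased <- function(...) {
    list(pcfg = basic_pcfg(),
         mcfg = mechanism_config("observational", learners = "hearer",
                                 init_scheme = "empty", ...))
  }
  obverter_closed <- function(...) {
    list(pcfg = basic_pcfg(),
         mcfg = mechanism_config("observational", learners = "hearer",
                                 weighting = "obverter", init_scheme = "empty",
                                 ...))
  }
  obverter_grad <- function(...) {
    list(pcfg = basic_pcfg(dynamic = "gradual", learner_role = "hearer_only"),
         mcfg = mechanism_config("observational", learners = "hearer",
                                 weighting = "obverter", init_scheme = "empty",
                                 ...))
  }
  list(
    skyrms_pure = function() reinf(),
    barrett_memory35 = function() reinf(memory_limit = 35),
    barrett_punish_both = function() {
      reinf(punish = c("speaker_own", "hearer_own"))
    },
    barrett_punish_hearer = function() {
      reinf(learners = "hearer", punish = "hearer_own")
    },
    reinforce_gradual = function() reinf_grad(),
    reinforce_gradual_punish_speaker = function() reinf_grad("speaker_own"),
    reinforce_gradual_punish_hearer = function() reinf_grad("hearer_own"),
    reinforce_gradual_punish_both = function() {
      reinf_grad(c("speaker_own", "hearer_own"))
    },
    naminggame_full = function() {
      yesno(selection = "wta",
            punish = c("speaker_own", "hearer_own",
                       "speaker_punishes_hearers_association"),
            inhibition_kind = "both", inhibition_strength = "minimal")
    },
    yesno_punish_interpretive = function() {
      yesno(punish = "speaker_punishes_hearers_association")
    },
    yesno_punish_speaker = function() yesno(punish = "speaker_own"),
    yesno_punish_hearer = function() yesno(punish = "hearer_own"),
    yesno_inhibition = function() {
      yesno(inhibition_kind = "both", inhibition_strength = "minimal")
    },
    referential_none = function() referential(),
    referential_syn = function() {
      referential(inhibition_kind = "anti_synonymy")
    },
    referential_hom = function() {
      referential(inhibition_kind = "anti_homonymy")
    },
    referential_both = function() referential(inhibition_kind = "both"),
    referential_hearer_hom = function() {
      referential(learners = "hearer", inhibition_kind = "anti_homonymy")
    },
    biased_none = function() biased(),
    biased_syn = function() biased(inhibition_kind = "anti_synonymy"),
    biased_hom = function() biased(inhibition_kind = "anti_homonymy"),
    biased_both = function() biased(inhibition_kind = "both"),
    obverter_gradual_wta = function() obverter_grad(selection = "wta"),
    obverter_gradual_stoch = function() obverter_grad(),
    obverter_closed = function() obverter_closed(selection = "wta"),
    obverter_closed_mem35 = function() {
      obverter_closed(selection = "wta", memory_limit = 35)
    },
    obverter_closed_stoch = function() obverter_closed(),
    obverter_closed_stoch_mem35 = function() {
      obverter_closed(memory_limit = 35)
    }
  )
}
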
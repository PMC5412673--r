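test_that("meaning distributions are uniform or 1/rank", {
  expect_equal(meaning_distribution("uniform", 5), rep(0.2, 5))
  z <- meaning_distribution("zipf", 5)
  expect_equal(z[1], 1 / (1 + 1 / 2 + 1 / 3 + 1 / 4 + 1 / 5))  # 60/137
  expect_equal(sum(z), 1)
  expect_true(all(diff(z) < 0))
  expect_equal(meaning_distribution("zipf", 1), 1)
})

test_that("context sampling respects size and topic distribution", {
  d5 <- meaning_distribution("uniform", 5)
  set.seed(8)
  # full context is forced
  ct <- sample_context(d5, 5)
  expect_equal(ct$context, 1:5)
  expect_true(ct$topic %in% ct$context)

  # singleton context pins the topic
  ct1 <- sample_context(d5, 1)
  expect_equal(ct1$context, ct1$topic)

  # restricted contexts always contain the topic, subsets are size c
  for (k in 1:200) {
    ct <- sample_context(d5, 3)
    expect_length(ct$context, 3)
    expect_true(all(ct$context %in% 1:5))
    expect_true(ct$topic %in% ct$context)
    expect_false(is.unsorted(ct$context))
  }

  # zipf topic frequency at full context ~ 60/137
  z <- meaning_distribution("zipf", 5)
  set.seed(9)
  hits <- mean(replicate(4000, sample_context(z, 5)$topic) == 1L)
  p <- 60 / 137
  expect_lt(abs(hits - p), 4 * sqrt(p * (1 - p) / 4000))

  expect_error(sample_context(d5, 0), "c_size")
  expect_error(sample_context(d5, 6), "c_size")
})

test_that("interactions succeed exactly when interpretation matches topic", {
  cfg <- basic_mcfg(selection = "wta")
  a <- pure_agent(1, 1:5)
  b <- pure_agent(2, 1:5)
  set.seed(10)
  for (k in 1:20) {
    out <- run_interaction(a, b, cfg)
    expect_true(out$success)
    expect_equal(out$interpretation, out$topic)
    expect_equal(out$utterance, out$topic)  # identity mapping
  }

  # mismatched pure systems never succeed: hearer maps every signal to the
  # "next" meaning
  b2 <- pure_agent(2, c(2, 3, 4, 5, 1))
  for (k in 1:20) expect_false(run_interaction(a, b2, cfg)$success)

  # uninformative stores: empirical success ~ 1/5
  cfgs <- basic_mcfg()
  ua <- uniform_agents(2)
  set.seed(11)
  succ <- mean(replicate(3000, run_interaction(ua[[1]], ua[[2]], cfgs)$success))
  expect_lt(abs(succ - 0.2), 4 * sqrt(0.16 / 3000))

  expect_error(run_interaction(a, a, cfg), "distinct")
})

test_that("regime updates store and punish the documented associations", {
  mk <- function(regime, ...) mechanism_config(regime, n_meanings = 3,
                                               n_signals = 3, ...)
  out <- structure(list(speaker = 1L, hearer = 2L, context = 1:3, topic = 1L,
                        utterance = 2L, interpretation = 1L, success = TRUE),
                   class = "interaction_outcome")
  fail <- out; fail$interpretation <- 3L; fail$success <- FALSE

  sp <- signaling_agent(1, exemplar_store(3, 3, "one_per_pair"))
  he <- signaling_agent(2, exemplar_store(3, 3, "one_per_pair"))

  # reinforcement success: both learners store (t, u)
  up <- apply_updates(sp, he, out, mk("reinforcement"))
  expect_equal(up$speaker$store$counts[1, 2], 2L)
  expect_equal(up$hearer$store$counts[1, 2], 2L)

  # reinforcement failure with hearer punishment: hearer loses (i, u)
  up <- apply_updates(sp, he, fail, mk("reinforcement", learners = "hearer",
                                       punish = "hearer_own"))
  expect_equal(up$speaker$store$counts, sp$store$counts)
  expect_equal(up$hearer$store$counts[3, 2], 0L)
  expect_equal(total_exemplars(up$hearer$store), 8)

  # punishment floors at zero
  he0 <- signaling_agent(2, exemplar_store(3, 3, "empty"))
  up <- apply_updates(sp, he0, fail, mk("reinforcement", learners = "hearer",
                                        punish = "hearer_own"))
  expect_equal(total_exemplars(up$hearer$store), 0)

  # yes/no feedback: the speaker punishes the hearer's pointed association
  # in its own store
  up <- apply_updates(sp, he, fail,
                      mk("yesno_feedback",
                         punish = "speaker_punishes_hearers_association"))
  expect_equal(up$speaker$store$counts[3, 2], 0L)
  expect_equal(up$hearer$store$counts, he$store$counts)

  # ... or in the hearer's store under the alias reading
  up <- apply_updates(sp, he, fail,
                      mk("yesno_feedback",
                         punish = "speaker_punishes_hearers_association",
                         sphc_target = "hearer"))
  expect_equal(up$speaker$store$counts, sp$store$counts)
  expect_equal(up$hearer$store$counts[3, 2], 0L)

  # referential feedback: hearer stores the topic pair even on failure
  up <- apply_updates(sp, he, fail, mk("referential_feedback"))
  expect_equal(up$speaker$store$counts[1, 2], 2L)
  expect_equal(up$hearer$store$counts[1, 2], 2L)

  # observational: hearer stores (t, u) regardless of success, speaker never
  up <- apply_updates(sp, he, fail, mk("observational", learners = "hearer"))
  expect_equal(up$speaker$store$counts, sp$store$counts)
  expect_equal(up$hearer$store$counts[1, 2], 2L)

  # learning-disabled agents are untouched
  he_frozen <- he; he_frozen$learning_enabled <- FALSE
  up <- apply_updates(sp, he_frozen, fail, mk("observational",
                                              learners = "hearer"))
  expect_equal(up$hearer$store$counts, he$store$counts)
})

test_that("failed-interaction information flow differs by regime", {
  # On failure (t != i), the hearer's store may only be touched at the
  # interpreted pair (i, u) in reinforcement/yes-no, but is updated at the
  # topic pair (t, u) under referential/observational learning.
  fail <- structure(list(speaker = 1L, hearer = 2L, context = 1:3,
                         topic = 1L, utterance = 2L, interpretation = 3L,
                         success = FALSE),
                    class = "interaction_outcome")
  sp <- signaling_agent(1, exemplar_store(3, 3, "one_per_pair"))
  he <- signaling_agent(2, exemplar_store(3, 3, "one_per_pair"))
  mk <- function(regime, ...) mechanism_config(regime, n_meanings = 3,
                                               n_signals = 3, ...)

  for (regime in c("reinforcement", "yesno_feedback")) {
    up <- apply_updates(sp, he, fail, mk(regime, punish = "hearer_own"))
    delta <- up$hearer$store$counts - he$store$counts
    expect_equal(delta[1, 2], 0L)       # topic row untouched
    expect_equal(delta[3, 2], -1L)      # interpreted pair punished
  }
  for (regime in c("referential_feedback", "observational")) {
    cfg <- if (regime == "observational") mk(regime, learners = "hearer")
           else mk(regime)
    up <- apply_updates(sp, he, fail, cfg)
    delta <- up$hearer$store$counts - he$store$counts
    expect_equal(delta[1, 2], 1L)       # topic pair stored
    expect_equal(delta[3, 2], 0L)
  }
})

test_that("updates compose add, inhibition, and memory enforcement", {
  cfg <- mechanism_config("observational", learners = "hearer",
                          n_meanings = 3, n_signals = 3,
                          inhibition_kind = "anti_homonymy",
                          inhibition_strength = "broad", memory_limit = 9)
  sp <- signaling_agent(1, exemplar_store(3, 3, "one_per_pair"))
  he <- signaling_agent(2, exemplar_store(3, 3, "one_per_pair"))
  out <- structure(list(speaker = 1L, hearer = 2L, context = 1:3, topic = 1L,
                        utterance = 2L, interpretation = 1L, success = TRUE),
                   class = "interaction_outcome")
  set.seed(21)
  up <- apply_updates(sp, he, out, cfg)
  # add (1,2); broad anti-homonymy removes one token each from (2,2), (3,2);
  # total 9 - 1 = 8 <= memory limit, so no forgetting
  expect_equal(up$hearer$store$counts[1, 2], 2L)
  expect_equal(up$hearer$store$counts[2, 2], 0L)
  expect_equal(up$hearer$store$counts[3, 2], 0L)
  expect_equal(total_exemplars(up$hearer$store), 8)
})
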
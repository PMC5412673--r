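test_that("population initialization follows the dynamic and init scheme", {
  p <- init_population(population_config(),
                       preset("skyrms_pure")$mcfg)
  expect_length(p$agents, 10)
  expect_true(all(vapply(p$agents, function(a) total_exemplars(a$store),
                         numeric(1)) == 25))
  expect_true(all(vapply(p$agents, function(a) a$learning_enabled,
                         logical(1))))
  expect_equal(anyDuplicated(vapply(p$agents, function(a) a$id, integer(1))),
               0L)

  o <- init_population(population_config(),
                       preset("biased_hom")$mcfg)
  expect_true(all(vapply(o$agents, function(a) total_exemplars(a$store),
                         numeric(1)) == 0))

  g <- init_population(population_config(dynamic = "gradual"),
                       preset("reinforce_gradual")$mcfg)
  expect_false(any(vapply(g$agents, function(a) a$learning_enabled,
                          logical(1))))
  expect_null(g$learner)

  dyad <- init_population(population_config(size = 2),
                          preset("biased_hom")$mcfg)
  expect_length(dyad$agents, 2)
  expect_error(population_config(size = 1), "at least 2")
})

test_that("closed-dynamic pairing draws ordered pairs from the graph", {
  mcfg <- preset("biased_hom")$mcfg
  # dyad: both orders appear with ~equal frequency
  pop <- init_population(population_config(size = 2), mcfg)
  set.seed(40)
  roles <- replicate(2000, step_closed(pop, mcfg)$outcome$speaker)
  expect_lt(abs(mean(roles == 1L) - 0.5), 4 * sqrt(0.25 / 2000))

  # complete graph on 10: each ordered pair ~1/90
  pop10 <- init_population(population_config(), mcfg)
  expect_equal(nrow(pop10$edges), 90)
  set.seed(41)
  pair_ids <- replicate(9000, {
    o <- step_closed(pop10, mcfg)$outcome
    (o$speaker - 1L) * 10L + o$hearer
  })
  freq <- table(pair_ids)
  expect_equal(length(freq), 90L)
  expect_lt(max(abs(freq / 9000 - 1 / 90)), 4 * sqrt((1 / 90) / 9000))

  # ring lattice: non-neighbours are never paired
  set.seed(42)
  lat <- init_population(population_config(size = 10,
                                           pairing = "ring_lattice",
                                           pairing_k = 2), mcfg)
  dist_ring <- function(a, b) min(abs(a - b), 10 - abs(a - b))
  expect_true(all(apply(lat$edges, 1, function(e) dist_ring(e[1], e[2]) <= 2)))
  for (k in 1:200) {
    o <- step_closed(lat, mcfg)$outcome
    expect_lte(dist_ring(o$speaker, o$hearer), 2)
  }
})

test_that("gradual replacement maintains the learner lifecycle", {
  cfgs <- preset("obverter_gradual_wta")
  set.seed(43)
  pop <- init_population(cfgs$pcfg, cfgs$mcfg)
  original_ids <- vapply(pop$agents, function(a) a$id, integer(1))
  snapshots <- lapply(pop$agents, function(a) a$store$counts)

  for (it in 1:35) {
    st <- step_gradual(pop, cfgs$mcfg)
    pop <- st$population
    # learner is always the hearer under hearer_only
    expect_equal(st$outcome$hearer, 11L)
    expect_true(st$outcome$speaker %in% original_ids)
    if (it < 35) {
      expect_length(pop$agents, 10)
      expect_true(is.na(st$replaced))
    }
  }
  # replacement happened exactly at interaction 35: oldest (id 1) replaced
  expect_equal(st$replaced, 1L)
  ids_now <- vapply(pop$agents, function(a) a$id, integer(1))
  expect_false(1L %in% ids_now)
  expect_true(11L %in% ids_now)
  expect_length(pop$agents, 10)
  expect_null(pop$learner)

  # established stores were never modified
  for (k in 2:10) {
    idx <- which(ids_now == k)
    expect_equal(pop$agents[[idx]]$store$counts, snapshots[[k]])
  }
  # the new member no longer learns
  idx11 <- which(ids_now == 11L)
  expect_false(pop$agents[[idx11]]$learning_enabled)
})

test_that("simulations are reproducible and monotone in their budget", {
  cfgs <- preset("biased_both")
  r1 <- run_simulation(cfgs$pcfg, cfgs$mcfg, 3000, 50, seed = 5)
  r2 <- run_simulation(cfgs$pcfg, cfgs$mcfg, 3000, 50, seed = 5)
  expect_identical(r1$ca_trajectory, r2$ca_trajectory)
  expect_identical(r1$convergence_iteration, r2$convergence_iteration)

  # converged => final CA is 1 and iteration set; budgets beyond the
  # convergence point report the same iteration
  expect_true(r1$converged)
  expect_equal(r1$final_ca, 1)
  r3 <- run_simulation(cfgs$pcfg, cfgs$mcfg, 20000, 50, seed = 5)
  expect_identical(r3$convergence_iteration, r1$convergence_iteration)

  # a budget below the convergence point leaves the run unconverged
  short <- run_simulation(cfgs$pcfg, cfgs$mcfg,
                          max(50, r1$convergence_iteration - 100), 50,
                          seed = 5)
  expect_false(short$converged)
})

test_that("optimality is absorbing for success-adding regimes", {
  cfgs <- preset("biased_hom")
  r <- run_simulation(cfgs$pcfg, cfgs$mcfg, 20000, 100, seed = 6,
                      return_population = TRUE)
  expect_true(r$converged)
  pop <- r$population
  expect_true(is_optimal(pop, cfgs$mcfg))
  # keep interacting well past convergence: optimality persists
  for (k in 1:300) {
    pop <- step_closed(pop, cfgs$mcfg)$population
    if (k %% 100 == 0) expect_true(is_optimal(pop, cfgs$mcfg))
  }
})
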
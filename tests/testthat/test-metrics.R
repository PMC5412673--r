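test_that("pairwise communicative accuracy matches hand enumeration", {
  cfg <- basic_mcfg()
  # identical pure bijections: perfect system
  expect_equal(pairwise_ca(pure_agent(1, 1:5), pure_agent(2, 1:5), cfg), 1)

  # uninformative one-per-pair stores: chance level 1/5
  ua <- uniform_agents(2)
  expect_equal(pairwise_ca(ua[[1]], ua[[2]], cfg), 0.2)

  # partial pooling in a 3x3 system: meanings 1,2 pool on signal 1,
  # meaning 3 maps to signal 3; enumeration gives 2/3
  cfg3 <- basic_mcfg(n_meanings = 3, n_signals = 3)
  pool <- store_from(c(2, 0, 0), c(2, 0, 0), c(0, 0, 2))
  a <- signaling_agent(1, pool); b <- signaling_agent(2, pool)
  expect_equal(pairwise_ca(a, b, cfg3), 2 / 3)

  # mismatched spaces rejected
  expect_error(pairwise_ca(pure_agent(1, 1:3), pure_agent(2, 1:3), cfg),
               "spaces")
})

test_that("restricted-context CA enumerates all contexts", {
  # c = 2 of 3 meanings; hand enumeration over the 3 contexts for the
  # pooling system above: pooled meanings fail only when both are in
  # context; the informative meaning always succeeds.
  cfg3 <- basic_mcfg(n_meanings = 3, n_signals = 3, context_size = 2)
  pool <- store_from(c(2, 0, 0), c(2, 0, 0), c(0, 0, 2))
  a <- signaling_agent(1, pool); b <- signaling_agent(2, pool)
  # contexts {1,2}: terms 1/2 + 1/2; {1,3}: 1 + 1; {2,3}: 1 + 1
  expected <- (1 + 2 + 2) / (2 * 3)
  expect_equal(pairwise_ca(a, b, cfg3), expected)

  # Monte-Carlo fallback is flagged and near the exact value
  set.seed(30)
  mc <- pairwise_ca(a, b, cfg3, context_limit = 1L, n_mc_contexts = 4000L)
  expect_true(isTRUE(attr(mc, "monte_carlo")))
  expect_lt(abs(as.numeric(mc) - expected), 0.05)
})

test_that("population CA averages ordered pairs", {
  cfg <- basic_mcfg()
  opt <- lapply(1:4, function(k) pure_agent(k, c(3, 1, 4, 2, 5)))
  expect_equal(population_ca(opt, cfg), 1)

  ua <- uniform_agents(5)
  expect_equal(population_ca(ua, cfg), 0.2)

  # two sub-groups with disjoint bijections: 40 within-group pairs score 1,
  # 50 cross pairs score 0 -> 4/9
  g1 <- lapply(1:5, function(k) pure_agent(k, 1:5))
  g2 <- lapply(6:10, function(k) pure_agent(k, c(2, 3, 4, 5, 1)))
  expect_equal(population_ca(c(g1, g2), cfg), 4 / 9)

  expect_error(population_ca(g1[1], cfg), "at least 2")
})

test_that("analytic CA agrees with the Monte-Carlo oracle", {
  set.seed(31)
  for (cfg in list(basic_mcfg(n_meanings = 4, n_signals = 4),
                   basic_mcfg(n_meanings = 4, n_signals = 4,
                              selection = "wta"),
                   basic_mcfg(n_meanings = 4, n_signals = 4,
                              weighting = "obverter"))) {
    for (rep in 1:3) {
      a <- signaling_agent(1, random_store(4, 4))
      b <- signaling_agent(2, random_store(4, 4))
      exact <- pairwise_ca(a, b, cfg)
      n <- 20000L
      mc <- ca_monte_carlo(a, b, cfg, n)
      se <- sqrt(max(exact * (1 - exact), 1e-4) / n)
      expect_lt(abs(mc - exact), 4 * se)
    }
  }

  # degenerate cases are exact
  cfg5 <- basic_mcfg()
  expect_equal(ca_monte_carlo(pure_agent(1, 1:5), pure_agent(2, 1:5),
                              cfg5, 200), 1)
  expect_equal(ca_monte_carlo(pure_agent(1, 1:5),
                              pure_agent(2, c(2, 3, 4, 5, 1)), cfg5, 200), 0)
})

test_that("optimality requires a shared, deterministic, injective system", {
  cfg <- basic_mcfg()
  opt <- lapply(1:3, function(k) pure_agent(k, c(2, 1, 3, 5, 4)))
  expect_true(is_optimal(opt, cfg))

  # one agent deviating in one meaning's mapping
  dev <- c(opt[1:2], list(pure_agent(3, c(2, 1, 3, 4, 5))))
  expect_false(is_optimal(dev, cfg))

  # a single residual competing token breaks strict optimality
  near <- opt
  near[[2]]$store <- add_exemplar(near[[2]]$store, 1, 1)
  expect_false(is_optimal(near, cfg))

  # under WTA the same residual token is outvoted and the system stays
  # behaviourally optimal
  expect_true(is_optimal(near, basic_mcfg(selection = "wta")))
})

test_that("numeric and structural optimality checks agree on random populations", {
  set.seed(33)
  n_checked <- 0L
  for (rep in 1:400) {
    kind <- rep %% 4
    agents <- if (kind == 0) {
      perm <- sample.int(4)
      lapply(1:3, function(k) pure_agent(k, perm, tokens = sample.int(3, 1)))
    } else if (kind == 1) {
      lapply(1:3, function(k) pure_agent(k, sample.int(4)))
    } else {
      lapply(1:3, function(k) signaling_agent(k, random_store(4, 4)))
    }
    cfg <- basic_mcfg(n_meanings = 4, n_signals = 4,
                      selection = if (rep %% 2 == 0) "stochastic" else "wta")
    # is_optimal() itself asserts numeric/structural agreement
    expect_error(res <- is_optimal(agents, cfg), NA)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 400L)
})

test_that("convergence curves and CA histograms summarize run batches", {
  mk_res <- function(converged, iter, ca) {
    structure(list(converged = converged, convergence_iteration = iter,
                   final_ca = ca), class = "simulation_result")
  }
  all100 <- lapply(1:4, function(k) mk_res(TRUE, 100L, 1))
  cc <- convergence_curve(all100, c(50, 150))
  expect_equal(cc$proportion_converged, c(0, 1))

  none <- lapply(1:4, function(k) mk_res(FALSE, NA, 0.2))
  expect_equal(convergence_curve(none, c(50, 150))$proportion_converged,
               c(0, 0))

  mixed <- c(lapply(1:2, function(k) mk_res(TRUE, 10L, 1)),
             lapply(1:2, function(k) mk_res(FALSE, NA, 0.6)))
  expect_equal(convergence_curve(mixed, 20)$proportion_converged, 0.5)
  # monotone non-decreasing on any grid
  cc <- convergence_curve(mixed, c(5, 10, 15, 20000))
  expect_true(all(diff(cc$proportion_converged) >= 0))

  h <- final_ca_distribution(mixed)
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[h$bin_lower == 0.95], 2)
  expect_equal(h$count[h$bin_lower == 0.55], 2)

  expect_error(convergence_curve(list(), 10), "non-empty")
})
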
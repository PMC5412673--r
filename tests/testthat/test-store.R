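test_that("initialization schemes produce the documented token layouts", {
  s <- exemplar_store(5, 5, "one_per_pair")
  expect_equal(total_exemplars(s), 25)
  expect_true(all(s$counts == 1L))

  expect_equal(total_exemplars(exemplar_store(5, 5, "empty")), 0)
  expect_equal(total_exemplars(exemplar_store(2, 3, "one_per_pair")), 6)

  expect_error(exemplar_store(0, 5), "positive")
  expect_error(exemplar_store(5, -1), "positive")
})

test_that("add and remove change totals by exactly one, flooring at zero", {
  s <- exemplar_store(3, 3, "empty")
  s <- add_exemplar(s, 1, 1)
  expect_equal(s$counts[1, 1], 1L)
  expect_equal(total_exemplars(s), 1)
  s <- add_exemplar(s, 1, 1)
  expect_equal(s$counts[1, 1], 2L)

  s <- remove_exemplar(s, 1, 1)
  expect_equal(s$counts[1, 1], 1L)

  # removal from an empty cell is a signalled no-op
  noop_seen <- FALSE
  withCallingHandlers(
    s2 <- remove_exemplar(s, 2, 2),
    signalurn_noop_removal = function(c) noop_seen <<- TRUE)
  expect_true(noop_seen)
  expect_equal(s2$counts, s$counts)

  expect_error(add_exemplar(s, 4, 1), "out of range")
  expect_error(add_exemplar(s, 1, 0), "out of range")

  s3 <- remove_exemplar(exemplar_store(5, 5, "one_per_pair"), 2, 2)
  expect_equal(total_exemplars(s3), 24)
})

test_that("memory limit enforcement forgets exactly one older token", {
  set.seed(1)
  # 36 tokens, limit 35: exactly one deletion, never below the limit
  s <- exemplar_store(5, 5, "one_per_pair")
  for (k in 1:11) s <- add_exemplar(s, 1, 1)  # total 36
  out <- enforce_memory_limit(s, 35, c(1, 1))
  expect_equal(total_exemplars(out), 35)
  expect_equal(sum(s$counts - out$counts), 1)

  # at capacity: unchanged
  expect_equal(enforce_memory_limit(out, 35, c(1, 1))$counts, out$counts)

  # single token type: the protected instance shields one copy, the rest are
  # eligible, so the cell just decrements
  s1 <- exemplar_store(1, 1, "empty")
  for (k in 1:36) s1 <- add_exemplar(s1, 1, 1)
  expect_equal(enforce_memory_limit(s1, 35, c(1, 1))$counts[1, 1], 35L)

  # bulk insertion violates the single-token contract
  s2 <- s
  s2 <- add_exemplar(s2, 2, 2)  # total 37 > limit + 1
  expect_error(enforce_memory_limit(s2, 35, c(2, 2)), "limit \\+ 1")

  # the protected token is shielded: with the only other token elsewhere,
  # deletion always hits the unprotected one
  s3 <- exemplar_store(2, 2, "empty")
  s3 <- add_exemplar(s3, 1, 1)
  s3 <- add_exemplar(s3, 2, 2)
  out3 <- enforce_memory_limit(s3, 1, c(2, 2))
  expect_equal(out3$counts[2, 2], 1L)
  expect_equal(out3$counts[1, 1], 0L)
})

test_that("memory limit holds across random update sequences", {
  set.seed(42)
  for (rep in 1:20) {
    s <- exemplar_store(4, 4, "empty")
    for (k in 1:60) {
      m <- sample.int(4, 1); sg <- sample.int(4, 1)
      s <- add_exemplar(s, m, sg)
      s <- enforce_memory_limit(s, 12, c(m, sg))
      expect_lte(total_exemplars(s), 12)
    }
  }
})

test_that("lateral inhibition strengths delete the documented competitors", {
  base <- store_from(c(1, 0, 0),
                     c(2, 0, 0),
                     c(1, 0, 0))  # focal (1, 1); competitors m2 (2), m3 (1)

  # broad: one token per competing type
  b <- apply_lateral_inhibition(base, c(1, 1), "anti_homonymy", "broad")
  expect_equal(b$counts[, 1], c(1L, 1L, 0L))

  # maximal: all competing tokens removed, focal untouched
  m <- apply_lateral_inhibition(base, c(1, 1), "anti_homonymy", "maximal")
  expect_equal(m$counts[, 1], c(1L, 0L, 0L))

  # minimal: uniform over competing tokens; m2 should lose with prob 2/3.
  # Oracle: the draw is over 3 competing tokens, 2 of them m2's.
  set.seed(99)
  losses_m2 <- 0L
  n <- 3000L
  for (k in seq_len(n)) {
    out <- apply_lateral_inhibition(base, c(1, 1), "anti_homonymy", "minimal")
    expect_equal(total_exemplars(out), 3)
    if (out$counts[2, 1] == 1L) losses_m2 <- losses_m2 + 1L
  }
  p_hat <- losses_m2 / n
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(p_hat - 2 / 3), 4 * se)

  # no competitors: no change, no draw consumed
  lone <- store_from(c(2, 0), c(0, 0))
  set.seed(7); r1 <- runif(1)
  set.seed(7)
  out <- apply_lateral_inhibition(lone, c(1, 1), "both", "minimal")
  expect_equal(out$counts, lone$counts)
  expect_equal(runif(1), r1)
})

test_that("kind = both runs the homonym pass before the synonym pass", {
  # focal (1,1); homonym competitor (2,1); synonym competitor (1,2)
  s <- store_from(c(1, 1), c(1, 0))
  set.seed(5)
  out <- apply_lateral_inhibition(s, c(1, 1), "both", "maximal")
  expect_equal(out$counts, rbind(c(1L, 0L), c(0L, 0L)))
})

test_that("stores round-trip through CSV and JSON serialization", {
  s <- random_store(3, 4)
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_store(s, fc)
  write_store(s, fj)
  expect_equal(read_store(fc)$counts, s$counts)
  expect_equal(read_store(fj)$counts, s$counts)
})
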
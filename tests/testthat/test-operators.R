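test_that("sequential grouping forms contiguous blocks of the rounded size", {
  expect_equal(sequential_groups(6, 3), list(1:2, 3:4, 5:6))
  expect_equal(sequential_groups(6, 1), list(1:6))
  # d/k = 2.5 rounds half up: sizes (3, 2)
  expect_equal(sequential_groups(5, 2), list(1:3, 4:5))
  expect_error(sequential_groups(4, 5), "\\[1, d\\]")
  # partition property on assorted shapes
  for (dk in list(c(10, 3), c(17, 4), c(120, 10), c(7, 7))) {
    g <- sequential_groups(dk[1], dk[2])
    expect_length(g, dk[2])
    expect_equal(sort(unlist(g)), seq_len(dk[1]))
    expect_true(all(vapply(g, function(b) all(diff(b) == 1L), logical(1))))
  }
})

test_that("sparse initialization is deterministic and respects the encoding", {
  sc <- score_vector(fixture_montage16(), R = 1.0)
  set.seed(5)
  pop1 <- sparse_init(10, sc)
  set.seed(5)
  pop2 <- sparse_init(10, sc)
  expect_identical(pop1, pop2)
  for (ind in pop1) {
    expect_true(all(ind$dec >= 0 & ind$dec <= 1))
    expect_true(all(ind$mask %in% c(0L, 1L)))
    expect_length(ind$dec, n_pairs(16))
  }
  expect_error(sparse_init(1, sc), "pop_size")
})

test_that("initialization activates high-score pairs preferentially", {
  # two-pair toy: with scores (0.9, 0.1), pair 1 wins every tournament,
  # so it is active whenever at least one pair is, pair 2 only when both are
  counts <- c(0L, 0L)
  set.seed(8)
  for (i in 1:2000) {
    ind <- sparse_init(2, c(0.9, 0.1))[[1]]
    counts <- counts + ind$mask
  }
  expect_gt(counts[1], counts[2] * 1.5)
  # equal scores: activation frequency uniform over pairs
  set.seed(9)
  tot <- integer(6)
  for (i in 1:2000) tot <- tot + sparse_init(2, rep(1, 6))[[1]]$mask
  chi <- suppressWarnings(chisq.test(tot))
  expect_gt(chi$p.value, 1e-3)
  # inverted bias flips the preference
  set.seed(10)
  counts_inv <- c(0L, 0L)
  for (i in 1:2000) {
    counts_inv <- counts_inv +
      sparse_init(2, c(0.9, 0.1), score_bias = "zero_high_score")[[1]]$mask
  }
  expect_gt(counts_inv[2], counts_inv[1] * 1.5)
})

test_that("mask crossover flips at most one bit, drawn from parent differences", {
  sc <- c(0.1, 0.9, 0.5, 0.3, 0.7, 0.2)
  g <- sequential_groups(6, 2)
  p <- individual(rep(0.5, 6), c(1L, 1L, 0L, 0L, 1L, 0L))
  q <- individual(rep(0.5, 6), c(1L, 1L, 0L, 0L, 1L, 0L))
  set.seed(1)
  expect_identical(score_mask_crossover(p, q, sc, g), p$mask)
  p0 <- individual(rep(0.5, 6), rep(0L, 6))
  q1 <- individual(rep(0.5, 6), rep(1L, 6))
  set.seed(2)
  flips_up <- 0L
  for (i in 1:200) {
    off <- score_mask_crossover(p0, q1, sc, g)
    expect_true(all(off >= p0$mask))         # only 0->1 moves possible
    expect_lte(sum(off != p0$mask), 1L)
    flips_up <- flips_up + sum(off)
  }
  expect_gt(flips_up, 50L)                   # the 0->1 branch does fire
  # the 1->0 branch removes low-score actives from p \ q
  p1 <- individual(rep(0.5, 6), rep(1L, 6))
  q0 <- individual(rep(0.5, 6), rep(0L, 6))
  set.seed(3)
  for (i in 1:200) {
    off <- score_mask_crossover(p1, q0, sc, g)
    expect_true(all(off <= p1$mask))
    expect_lte(sum(off != p1$mask), 1L)
  }
})

test_that("mask crossover flip sites follow the score ordering", {
  # group of 3 candidate sites with distinct scores; 0->1 flips should
  # prefer high scores under binary tournament: freq(high) > freq(low)
  sc <- c(0.9, 0.5, 0.1)
  g <- sequential_groups(3, 1)
  p0 <- individual(rep(0.5, 3), rep(0L, 3))
  q1 <- individual(rep(0.5, 3), rep(1L, 3))
  tot <- integer(3)
  set.seed(12)
  for (i in 1:2000) tot <- tot + score_mask_crossover(p0, q1, sc, g)
  expect_gt(tot[1], tot[2])
  expect_gt(tot[2], tot[3])
})

test_that("mask mutation changes at most one bit and honors empty candidate sets", {
  sc <- c(0.4, 0.8, 0.2, 0.6)
  g <- sequential_groups(4, 2)
  all_one <- individual(rep(0.5, 4), rep(1L, 4))
  all_zero <- individual(rep(0.5, 4), rep(0L, 4))
  set.seed(4)
  saw_down <- FALSE
  for (i in 1:100) {
    mut <- score_mask_mutation(all_one, sc, g)
    expect_lte(sum(mut != all_one$mask), 1L)
    expect_true(all(mut <= all_one$mask))    # only 1->0 possible
    if (any(mut == 0L)) saw_down <- TRUE
    mut0 <- score_mask_mutation(all_zero, sc, g)
    expect_true(all(mut0 >= all_zero$mask))  # only 0->1 possible
    expect_lte(sum(mut0), 1L)
  }
  expect_true(saw_down)
  # uniform scores: flip sites uniform over the (single) group
  set.seed(6)
  tot <- integer(4)
  for (i in 1:2000) {
    tot <- tot + (score_mask_mutation(all_zero, rep(1, 4),
                                      sequential_groups(4, 1)) == 1L)
  }
  chi <- suppressWarnings(chisq.test(tot))
  expect_gt(chi$p.value, 1e-3)
})

test_that("score-based real mutation drifts toward high-score thresholds", {
  o <- individual(rep(0.5, 2), rep(1L, 2))
  expect_identical(score_dec_mutation(o, c(0.3, 0.9), alpha = 0),
                   o$dec)
  expect_error(score_dec_mutation(o, c(0.3, 0.9), alpha = 1.5), "alpha")
  # min-max normalized scores: index 2 has shat = 1 (always up),
  # index 1 has shat = 0 (always down) when selected
  set.seed(13)
  drift <- c(0, 0)
  n_hit <- c(0, 0)
  for (i in 1:4000) {
    mut <- score_dec_mutation(o, c(0.3, 0.9), alpha = 0.1)
    moved <- mut != o$dec
    drift <- drift + (mut - o$dec)
    n_hit <- n_hit + moved
  }
  expect_gt(n_hit[1], 0)
  expect_lt(drift[1], 0)      # low score: strictly downward
  expect_gt(drift[2], 0)      # high score: strictly upward
  # intermediate normalized scores drift with the stated probabilities
  set.seed(14)
  d3 <- c(0, 0, 0)
  o3 <- individual(rep(0.5, 3), rep(1L, 3))
  for (i in 1:6000) {
    d3 <- d3 + score_dec_mutation(o3, c(0, 0.8, 1), alpha = 0.1) - o3$dec
  }
  expect_lt(d3[1], 0)
  expect_gt(d3[2], 0)         # shat = 0.8: mean step 0.05*(0.8 - 0.2) > 0
  expect_gt(d3[3], d3[2] - 1e-9)
})

test_that("simulated binary crossover respects bounds and parent symmetry", {
  set.seed(15)
  p <- runif(30); q <- runif(30)
  expect_identical(sbx_crossover(p, p, prob = 1)[[1]], p)
  for (i in 1:50) {
    off <- sbx_crossover(p, q, eta = 20, prob = 1)
    expect_true(all(off[[1]] >= 0 & off[[1]] <= 1))
    expect_true(all(off[[2]] >= 0 & off[[2]] <= 1))
    # where no clipping occurred the offspring preserve the parent mean
    interior <- off[[1]] > 0 & off[[1]] < 1 & off[[2]] > 0 & off[[2]] < 1
    expect_equal((off[[1]] + off[[2]])[interior], (p + q)[interior],
                 tolerance = 1e-9)
  }
})

test_that("simulated binary crossover matches the textbook spread distribution", {
  # the spread factor beta = |c2 - c1| / |q - p| follows the polynomial
  # density: P(beta <= 1) = 0.5 and median of the contracting branch at
  # u = 0.25 -> beta = 0.5^(1/(eta+1))
  set.seed(16)
  p <- rep(0.5, 1); q <- rep(0.50001, 1)
  betas <- replicate(4000, {
    off <- sbx_crossover(p, q, eta = 20, prob = 1)
    abs(off[[2]] - off[[1]]) / abs(q - p)
  })
  betas <- betas[betas != 1]          # drop the no-crossover coordinates
  expect_equal(mean(betas <= 1), 0.5, tolerance = 0.05)
  expect_equal(median(betas[betas <= 1]), 0.5^(1 / 21), tolerance = 0.02)
})

test_that("polynomial mutation respects bounds and the mutation probability", {
  dec <- withr::with_seed(17, runif(50))
  expect_identical(polynomial_mutation(dec, prob = 0), dec)
  set.seed(18)
  n_changed <- 0L
  for (i in 1:200) {
    mut <- polynomial_mutation(dec, eta = 20, prob = 1 / 50)
    expect_true(all(mut >= 0 & mut <= 1))
    n_changed <- n_changed + sum(mut != dec)
  }
  # about one coordinate mutates per call
  expect_gt(n_changed, 100L)
  expect_lt(n_changed, 400L)
  # small eta = wide steps, large eta = tight steps around the parent
  set.seed(19)
  step_wide <- mean(abs(polynomial_mutation(rep(0.5, 5000), eta = 2,
                                            prob = 1) - 0.5))
  step_tight <- mean(abs(polynomial_mutation(rep(0.5, 5000), eta = 100,
                                             prob = 1) - 0.5))
  expect_gt(step_wide, step_tight)
})

test_that("binary tournament prefers rank then crowding", {
  mk <- function(rank, crowd) {
    ind <- stub_individual(c(1, 1))
    ind$rank <- rank; ind$crowding <- crowd
    ind
  }
  pop <- list(mk(1, 0.2), mk(2, Inf))
  set.seed(20)
  sel <- binary_tournament(pop, 500)
  contested <- sel[seq_along(sel)]
  expect_true(all(contested == 1L | contested == 2L))
  # rank 1 must win every mixed contest: index 2 only appears via (2,2) draws
  expect_lt(mean(sel == 2L), 0.4)
  pop2 <- list(mk(1, Inf), mk(1, 0.5))
  set.seed(21)
  sel2 <- binary_tournament(pop2, 500)
  expect_lt(mean(sel2 == 2L), 0.4)
  # fully tied population: selection uniform
  pop3 <- replicate(4, mk(1, Inf), simplify = FALSE)
  set.seed(22)
  sel3 <- binary_tournament(pop3, 4000)
  chi <- suppressWarnings(chisq.test(tabulate(sel3, 4)))
  expect_gt(chi$p.value, 1e-3)
  pop_bad <- list(stub_individual(c(1, 1)), stub_individual(c(2, 2)))
  expect_error(binary_tournament(pop_bad), "metadata")
})
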
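test_that("transition table is stochastic, symmetric, with second eigenvalue lam", {
  for (lam in c(-1, -0.5, 0, 0.5, 1)) {
    p <- transition_probabilities(lam)
    expect_equal(rowSums(p), c("+" = 1, "-" = 1))
    expect_equal(p[1, 1], p[2, 2])  # statistical neutrality
    expect_equal(sort(eigen(p)$values), sort(c(1, lam)))
  }
  expect_equal(unname(transition_probabilities(0)),
               matrix(0.5, 2, 2))
  expect_equal(unname(transition_probabilities(-1)),
               matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(transition_probabilities(0.5)[1, 1], 0.75)
  expect_error(transition_probabilities(1.2), "must lie in")
})

test_that("blockiness follows (1+lam)/(1-lam), is monotone, diverges at 1", {
  expect_identical(blockiness(-1), 0)
  expect_identical(blockiness(0), 1)
  expect_equal(blockiness(0.5), 3)
  lams <- seq(-1, 0.99, length.out = 50)
  expect_true(all(diff(blockiness(lams)) > 0))
  expect_warning(L1 <- blockiness(1), "diverges")
  expect_identical(L1, Inf)
  expect_equal(lambda_from_blockiness(blockiness(0.37)), 0.37)
})

test_that("run-length oracle: mean block charge converges to 1 + Lambda", {
  # ensemble mean same-sign run length of simulated sequences -> 2/(1-lam)
  for (lam in c(-0.9, -0.5, 0, 0.5, 0.9)) {
    lens <- unlist(lapply(1:3, function(i) {
      s <- generate_sequence(markov_spec(2e5, 1, lam, seed = 100 * i + 7))
      decompose_blocks(s)$block_lengths
    }))
    target <- 1 + blockiness(lam)
    se <- sd(lens) / sqrt(length(lens))
    expect_lt(abs(mean(lens) - target), max(3 * se, 0.01 * target))
  }
})

test_that("generated sequences honor spec limits and determinism", {
  # strict alternation at lam = -1
  s <- generate_sequence(markov_spec(8, 1, -1, seed = 5))
  expect_true(all(abs(diff(as.integer(s))) == 2))
  # iid limit: P(+ after +) = 0.5 +- 0.01
  s0 <- generate_sequence(markov_spec(1e5, 1, 0, seed = 42))
  x <- as.integer(s0)
  after_plus <- x[-1][x[-length(x)] == 1]
  expect_lt(abs(mean(after_plus == 1) - 0.5), 0.01)
  # mean block charge at lam = 0.5 is 4 +- 0.05
  s5 <- generate_sequence(markov_spec(1e6, 1, 0.5, seed = 9))
  expect_lt(abs(mean(decompose_blocks(s5)$block_lengths) - 4), 0.05)
  # reproducibility
  spec <- markov_spec(500, 0.5, 0.3, seed = 77)
  expect_identical(as.integer(generate_sequence(spec)),
                   as.integer(generate_sequence(spec)))
})

test_that("neutral monomers sit between equidistant ionic sites", {
  spec <- markov_spec(64, 0.25, 0, seed = 1)
  s <- as.integer(generate_sequence(spec))
  ionic <- which(s != 0L)
  expect_length(ionic, 16L)
  expect_true(all(diff(ionic) == 4L))
  expect_error(markov_spec(10, 0.33, 0), "not an integer")
})

test_that("block decomposition is an exact run-length encoding", {
  b <- decompose_blocks(charge_sequence(c(1, 1, -1, -1, -1)))
  expect_equal(b$block_lengths, c(2L, 3L))
  expect_equal(b$block_signs, c(1L, -1L))
  alt <- generate_sequence(markov_spec(10, 1, -1, seed = 2))
  balt <- decompose_blocks(alt)
  expect_equal(balt$block_lengths, rep(1L, 10))
  expect_true(all(abs(diff(balt$block_signs)) == 2))
  s <- generate_sequence(markov_spec(400, 0.5, 0.6, seed = 3))
  bs <- decompose_blocks(s)
  expect_equal(sum(bs$block_lengths), 200L)  # covers all ionic monomers
  expect_error(decompose_blocks(charge_sequence(c(0, 0))), "no ionic")
})

test_that("net-charge variance matches exhaustive enumeration to machine precision", {
  for (lam in c(-0.5, 0.3, 0.8)) {
    for (n in c(5, 10, 13)) {
      expect_equal(net_charge_moments(lam, 1, n)$var,
                   enumerate_var_q(lam, n), tolerance = 1e-12)
    }
  }
  expect_equal(net_charge_moments(0, 1, 100)$var, 100)     # iid signs
  expect_equal(net_charge_moments(-1, 1, 100)$var, 0)      # even alternation
  expect_equal(net_charge_moments(-1, 1, 101)$var, 1)      # odd alternation
  # asymptotics: Var(Q)/(f N) -> Lambda
  expect_equal(net_charge_moments(0.5, 1, 1e6)$var / 1e6, blockiness(0.5),
               tolerance = 1e-4)
})

test_that("characteristic charge interpolates from 0 to fN", {
  expect_identical(characteristic_charge(1, 100, lam = -1), 0)
  expect_equal(characteristic_charge(1, 100, lam = 0), 10)
  expect_equal(characteristic_charge(0.5, 200, Lambda = 0.5 * 200), 100)
  expect_equal(characteristic_charge(1, 100, Lambda = 1e6), 100)  # capped
})

test_that("lambda estimator recovers the generator parameter", {
  alt <- generate_sequence(markov_spec(50, 1, -1, seed = 1))
  expect_equal(estimate_lambda(alt)$lam_hat, -1)
  s <- generate_sequence(markov_spec(1e5, 1, 0.5, seed = 13))
  est <- estimate_lambda(s)
  expect_lt(abs(est$lam_hat - 0.5), max(3 * est$se, 0.01))
  expect_false(est$degenerate)
  expect_warning(deg <- estimate_lambda(charge_sequence(rep(1L, 10))),
                 "degenerate")
  expect_equal(deg$lam_hat, 1)
  expect_true(deg$degenerate)
})

test_that("conditioned ensemble fixes Q exactly and perturbs statistics weakly", {
  spec <- markov_spec(1024, 1, 0, seed = 21)
  seqs <- conditioned_ensemble(spec, 40, 30)
  expect_true(all(vapply(seqs, net_charge, 0L) == 40L))
  expect_gt(attr(seqs, "acceptance_rate"), 1e-4)
  lam_hats <- vapply(seqs, function(s) estimate_lambda(s)$lam_hat, 0)
  expect_lt(abs(mean(lam_hats) - 0), 0.05)
  expect_error(conditioned_ensemble(spec, 41, 1), "parity")
  expect_error(conditioned_ensemble(spec, 2000, 1), "exceeds")
})
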
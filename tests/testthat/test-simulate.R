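test_that("generators are bit-deterministic given a seed and leave the RNG alone", {
  set.seed(999)
  before <- .Random.seed
  a1 <- simulate_cuticle_image(30, 20, c(150, 100, 100), seed = 11)
  a2 <- simulate_cuticle_image(30, 20, c(150, 100, 100), seed = 11)
  expect_identical(a1, a2)
  s1 <- simulate_alignment("((A:0.1,B:0.05):0,O:0.2);", length = 200, seed = 3)
  s2 <- simulate_alignment("((A:0.1,B:0.05):0,O:0.2);", length = 200, seed = 3)
  expect_identical(s1, s2)
  c1 <- simulate_composition_sequences(c(0.3, 0.2, 0.2, 0.3), 100, 2, seed = 5)
  expect_identical(c1, simulate_composition_sequences(c(0.3, 0.2, 0.2, 0.3), 100, 2, seed = 5))
  w1 <- simulate_weights(10, 0.9, 0.05, seed = 7)
  expect_identical(w1, simulate_weights(10, 0.9, 0.05, seed = 7))
  expect_identical(before, .Random.seed)
})

test_that("cuticle image generator honours base colour, fractions and pixel bookkeeping", {
  # uniform gray, no noise, no extremes
  g <- simulate_cuticle_image(10, 10, c(120, 120, 120), noise_sd = 0,
                              highlight_frac = 0, shadow_frac = 0, seed = 1)
  expect_true(all(unclass(g$image) == 120L))
  expect_equal(g$truth$redness, 0)
  # analytic ground truth from the index formula
  r <- simulate_cuticle_image(5, 5, c(200, 100, 100), noise_sd = 0,
                              highlight_frac = 0, shadow_frac = 0, seed = 1)
  expect_equal(r$truth$redness, 200 - 400 / 3)
  # pixel-count conservation across many seeds
  for (s in 1:10) {
    sim <- simulate_cuticle_image(40, 30, c(150, 100, 100), noise_sd = 8,
                                  highlight_frac = 0.07, shadow_frac = 0.04,
                                  seed = s)
    expect_identical(sim$truth$n_highlight + sim$truth$n_shadow +
                       sim$truth$n_body, 40L * 30L)
  }
  expect_error(simulate_cuticle_image(10, 10, c(300, 0, 0)), "\\[0, 255\\]")
  expect_error(simulate_cuticle_image(10, 10, c(100, 100, 100),
                                      highlight_frac = 0.6, shadow_frac = 0.5),
               "highlight_frac")
})

test_that("downstream masked redness recovers the simulated base-colour redness", {
  sim <- simulate_cuticle_image(200, 200, c(150, 100, 100), noise_sd = 8,
                                highlight_frac = 0.05, shadow_frac = 0.05,
                                seed = 1)
  r <- score_image(sim$image, c(0, 0, 200, 200))
  expect_lt(abs(r$index - sim$truth$redness), 1)
})

test_that("alignment simulation reproduces its generating distances", {
  # zero evolution: all leaves identical to the root draw
  aln0 <- simulate_alignment("((A:0,B:0):0,C:0);", length = 50, seed = 2)
  expect_identical(unclass(aln0)["A", ], unclass(aln0)["B", ])
  expect_identical(unclass(aln0)["A", ], unclass(aln0)["C", ])
  # two leaves, total path 0.1 under JC69: estimate within 3 analytic SE
  L <- 100000
  aln <- simulate_alignment("(A:0.05,B:0.05);", model = "jc69",
                            length = L, seed = 7)
  code <- beetlesym:::nt_codes(aln)
  pq <- p_q_counts(code[1, ], code[2, ])
  d_hat <- jc69_distance(pq$P + pq$Q)
  p_true <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sqrt(p_true * (1 - p_true) / (L * (1 - 4 * p_true / 3)^2))
  expect_lt(abs(d_hat - 0.1), 3 * se)
  expect_error(simulate_alignment("(A:-0.1,B:0.05);", length = 10),
               "negative branch length")
})

test_that("simulated JC69 distances are unbiased across replicate seeds", {
  L <- 4000
  d_hats <- vapply(1:50, function(s) {
    aln <- simulate_alignment("(A:0.05,B:0.05);", model = "jc69",
                              length = L, seed = s)
    code <- beetlesym:::nt_codes(aln)
    pq <- p_q_counts(code[1, ], code[2, ])
    jc69_distance(pq$P + pq$Q)
  }, numeric(1))
  mc_se <- sd(d_hats) / sqrt(length(d_hats))
  expect_lt(abs(mean(d_hats) - 0.1), 2 * mc_se)
})

test_that("K2P simulation with rate asymmetry yields the designed K1/K2", {
  aln <- simulate_alignment("((L1:0.10,L2:0.05):0,O:0.20);", model = "k2p",
                            kappa = 2, length = 50000, seed = 5)
  res <- relative_rate_test(aln, "L1", "L2", "O", model = "k2p",
                            n_bootstrap = 100, seed = 5)
  expect_gt(res$ratio, 1.5)
  expect_lt(res$ratio, 2.6)
})

test_that("composition sequences hit their target AT content", {
  expect_equal(at_content(simulate_composition_sequences(
    c(1, 0, 0, 0), 200, seed = 1)[[1]])$at_content, 100)
  seqs <- simulate_composition_sequences(c(0.3, 0.2, 0.2, 0.3), 100000, seed = 3)
  expect_lt(abs(at_content(seqs[[1]])$at_content - 60), 0.5)
  # symmetry: uniform frequencies approach 50%
  u <- simulate_composition_sequences(c(0.25, 0.25, 0.25, 0.25), 50000, seed = 4)
  expect_lt(abs(at_content(u[[1]])$at_content - 50), 1)
  expect_error(simulate_composition_sequences(c(0.5, 0.5, 0.5, 0.5), 10),
               "summing to 1")
})

test_that("weight samples respect mean, truncation and degenerate sd", {
  expect_identical(simulate_weights(5, 0.9, 0, seed = 1), rep(0.9, 5))
  w <- simulate_weights(1000, 1.0, 0.1, seed = 2)
  expect_lt(abs(mean(w) - 1.0), 0.01)  # 3 * SE bound
  expect_true(all(simulate_weights(500, 0.05, 0.2, seed = 3) >= 0))
  expect_error(simulate_weights(0, 1, 0.1), "n must be")
  expect_error(simulate_weights(5, 1, -1), "sd must be")
})

test_that("two simulated cohorts at the designed effect size separate by Welch test", {
  a <- simulate_weights(30, 0.9, 0.05, seed = 11)
  b <- simulate_weights(30, 0.8, 0.05, seed = 12)
  expect_lt(welch_t_test(a, b)$p_two_sided, 0.01)
})
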
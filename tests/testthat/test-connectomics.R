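test_that("relation graphs encode wire sharing, excluding power and ground", {
  # two inverters in series: out1 is both C1 of T0 and gate of T1
  nl <- empty_netlist()
  nl <- add_wire(nl, "a", role = "input")
  nl <- add_wire(nl, "out1")
  nl <- add_wire(nl, "out2", role = "output")
  nl <- add_gate(nl, "not", "a", "out1")
  nl <- add_gate(nl, "not", "out1", "out2")
  rg <- build_relations(nl)
  expect_equal(rg$relations$C1_G[1, 2], 1L)
  expect_equal(rg$relations$G_C1[2, 1], 1L)
  # everything else is rail-mediated (excluded) or absent
  others <- sum(vapply(rg$relations, sum, double(1)))
  expect_equal(others, 2)

  # no shared signal wires -> all-zero relations
  iso <- empty_netlist()
  iso <- add_wire(iso, "i1", role = "input")
  iso <- add_wire(iso, "o1")
  iso <- add_wire(iso, "i2")
  iso <- add_wire(iso, "o2")
  iso <- add_gate(iso, "not", "i1", "o1")
  iso <- add_gate(iso, "not", "i2", "o2")
  rg0 <- build_relations(iso)
  expect_true(all(vapply(rg0$relations, sum, double(1)) == 0))
})

test_that("channel relations are mutually transposed", {
  nl <- make_fixture("adder4")$netlist
  rg <- build_relations(nl)
  expect_equal(rg$relations$C1_C2, t(rg$relations$C2_C1))
  expect_equal(rg$relations$G_C1, t(rg$relations$C1_G))
  expect_true(all(diag(rg$relations$G_C1) == 0))
})

test_that("the joint posterior is permutation-invariant and exact for K = 1", {
  g <- gen_planted_sbm(c(6, 6), p_in = 0.5, p_out = 0.2, seed = 2)
  z <- g$labels
  lp1 <- sbm_log_posterior(g$graphs, z, 2)
  lp2 <- sbm_log_posterior(g$graphs, 3 - z, 2) # swap labels
  expect_equal(lp1, lp2, tolerance = 1e-10)

  # K = 1 closed form: one Beta-Bernoulli cell per relation
  n <- length(z)
  ref <- sum(vapply(g$graphs, function(A) {
    e <- sum(A)
    lbeta(1 + e, 1 + n * (n - 1) - e) - lbeta(1, 1)
  }, double(1)))
  expect_equal(sbm_log_posterior(g$graphs, rep(1L, n), 1), ref,
               tolerance = 1e-10)
  fit1 <- sbm_fit(g$graphs, K = 1, seed = 1, sweeps = 2)
  expect_equal(fit1$log_posterior, ref, tolerance = 1e-10)
  expect_true(all(fit1$labels$cluster == 1L))
})

test_that("gibbs inference recovers planted blocks and tracks the best posterior", {
  g <- gen_planted_sbm(c(20, 20, 20), p_in = 0.6, p_out = 0.05, seed = 7)
  fit <- sbm_fit(g$graphs, K = 3, seed = 2, sweeps = 15, restarts = 3)
  expect_equal(adjusted_rand_index(fit$labels$cluster, g$labels), 1)
  expect_true(all(diff(fit$trace) >= 0)) # best-so-far never decreases
  expect_gte(fit$log_posterior, sbm_log_posterior(g$graphs, fit$labels$cluster, 3) - 1e-6)
  # diagonal blocks dense, off-diagonal sparse
  ep <- fit$edge_probability[[1]]
  expect_gt(min(diag(ep)), 0.5)
  expect_lt(max(ep[upper.tri(ep)], ep[lower.tri(ep)]), 0.15)
  expect_error(sbm_fit(g$graphs, K = 100, seed = 1), "exceeds")
})

test_that("six replicated relations give the same partition as one", {
  g <- gen_planted_sbm(c(15, 15), p_in = 0.8, p_out = 0.05, seed = 4,
                       n_relations = 1)
  one <- sbm_fit(g$graphs, K = 2, seed = 3, sweeps = 20, restarts = 4)
  six <- sbm_fit(rep(g$graphs, 6), K = 2, seed = 3, sweeps = 20, restarts = 4)
  # the likelihood factorizes over relations, so replication changes only
  # the scale of the posterior, not its argmax
  expect_equal(adjusted_rand_index(one$labels$cluster, g$labels), 1)
  expect_equal(adjusted_rand_index(six$labels$cluster, g$labels), 1)
})

test_that("the internal ARI agrees with mclust on random labelings", {
  skip_if_not_installed("mclust")
  silicophys:::withr_seed(10, {
    for (i in 1:5) {
      a <- sample(4, 60, replace = TRUE)
      b <- sample(3, 60, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
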